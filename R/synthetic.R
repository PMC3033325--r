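#' Build a parameterized two-layer forest for simulation studies
#'
#' Constructs an `fhlc_forest` with known parameters to sample from: each tree
#' has one layer-2 root over `clusters_per_tree` layer-1 latent variables,
#' each subsuming `snps_per_cluster` observed markers. Conditional probability
#' tables are "deterministic-leaning": given the parent state, each child
#' takes a state-specific mode value with probability `fidelity` and spreads
#' the remainder uniformly; mode assignments differ across children so sibling
#' signatures are distinguishable. With `clusters_per_tree = 1` the trees
#' collapse to single-layer latent class models.
#'
#' @param n_trees number of independent trees.
#' @param clusters_per_tree layer-1 latent variables per tree.
#' @param snps_per_cluster observed children per layer-1 latent (>= 2).
#' @param latent_card cardinality of every latent variable (>= 2).
#' @param fidelity probability mass on the mode of each leaf conditional
#'   distribution, in (1/card, 1\].
#' @param latent_fidelity mode mass of each layer-1-given-root conditional;
#'   kept moderate by default so sibling clusters stay distinguishable.
#' @param coding observed-variable coding (`"haplotype_01"` markers have 2
#'   states, `"genotype_012"` 3).
#' @return An `fhlc_forest` with full parameters and no imputed data.
#' @export
make_two_layer_forest <- function(n_trees = 2L, clusters_per_tree = 2L,
                                  snps_per_cluster = 5L, latent_card = 3L,
                                  fidelity = 0.95, latent_fidelity = 0.6,
                                  coding = c("haplotype_01", "genotype_012")) {
  coding <- match.arg(coding)
  obs_card <- length(snp_domain(coding))
  stopifnot(is_count(n_trees), is_count(clusters_per_tree),
            is_count(snps_per_cluster, 2L), is_count(latent_card, 2L),
            fidelity > 1 / latent_card, fidelity <= 1)
  nodes <- list()
  edges <- list()
  priors <- list()
  cpts <- list()
  snp_i <- 0L
  h1_i <- 0L
  # deterministic-leaning CPT: given parent state k, child j's mode is the
  # j-th base-`nrow_card` digit of (k - 1) (cyclically, with an offset), so a
  # run of children jointly identifies every parent state
  leaning_cpt <- function(nrow_card, parent_card, j, mode_mass) {
    digits <- max(1L, ceiling(log(parent_card) / log(nrow_card) - 1e-9))
    pos <- (j - 1L) %% digits
    shift <- (j - 1L) %/% digits
    cpt <- matrix((1 - mode_mass) / (nrow_card - 1L), nrow_card, parent_card)
    for (k in seq_len(parent_card)) {
      mode <- ((k - 1L) %/% nrow_card^pos + shift) %% nrow_card
      cpt[mode + 1L, k] <- mode_mass
    }
    cpt
  }
  for (tr in seq_len(n_trees)) {
    single <- clusters_per_tree == 1L
    root_layer <- if (single) 1L else 2L
    root <- sprintf("H%d_%d", root_layer, tr)
    nodes[[length(nodes) + 1L]] <- tibble(
      id = root, type = "latent", layer = root_layer,
      cardinality = latent_card, window = tr
    )
    priors[[root]] <- rep(1 / latent_card, latent_card)
    for (cl in seq_len(clusters_per_tree)) {
      if (single) {
        h1 <- root
      } else {
        h1_i <- h1_i + 1L
        h1 <- sprintf("H1_%d", h1_i)
        nodes[[length(nodes) + 1L]] <- tibble(
          id = h1, type = "latent", layer = 1L,
          cardinality = latent_card, window = tr
        )
        edges[[length(edges) + 1L]] <- tibble(
          parent = root, child = h1, scaled_mi = NA_real_
        )
        cpts[[h1]] <- leaning_cpt(latent_card, latent_card, cl, latent_fidelity)
      }
      for (s in seq_len(snps_per_cluster)) {
        snp_i <- snp_i + 1L
        id <- paste0("SNP", snp_i)
        nodes[[length(nodes) + 1L]] <- tibble(
          id = id, type = "observed", layer = 0L,
          cardinality = obs_card, window = tr
        )
        edges[[length(edges) + 1L]] <- tibble(
          parent = h1, child = id, scaled_mi = NA_real_
        )
        cpts[[id]] <- leaning_cpt(obs_card, latent_card, s, fidelity)
      }
    }
  }
  f <- new_fhlc_forest(
    bind_rows(nodes), bind_rows(edges), priors, cpts,
    matrix(integer(0), 0, 0), 0L,
    config = list(coding = coding)
  )
  validate_forest(f)
  f
}

#' Sample individuals from a fully parameterized forest
#'
#' Exact ancestral sampling: each root is drawn from its prior, then children
#' are drawn from their conditional probability tables given the parent state,
#' top-down to the observed leaves.
#'
#' @param forest an `fhlc_forest` with priors and CPTs (e.g. from
#'   [make_two_layer_forest()] or [cfhlc()]).
#' @param n number of individuals to draw.
#' @param seed integer seed; sampling is bit-reproducible.
#' @param coding coding to stamp on the observed matrix; defaults to the
#'   forest's recorded coding, falling back to the maximal observed
#'   cardinality.
#' @return A list with `data` (an [snp_matrix()] of the observed nodes, in
#'   node order) and `latents` (integer matrix of the true latent draws).
#' @export
sample_fhlcm <- function(forest, n, seed = 1L, coding = NULL) {
  stopifnot(inherits(forest, "fhlc_forest"), is_count(n))
  for (r in intersect(forest_roots(forest), names(forest$priors))) {
    if (abs(sum(forest$priors[[r]]) - 1) > 1e-6) abort("invalid prior")
  }
  if (is.null(coding)) {
    coding <- forest$config$coding
    if (is.null(coding)) {
      coding <- if (max(forest$nodes$cardinality[forest$nodes$type ==
        "observed"]) > 2L) "genotype_012" else "haplotype_01"
    }
  }
  ord <- arrange(forest$nodes, dplyr::desc(.data$layer))$id # parents first
  pm <- parent_map(forest)
  draws <- with_seed(seed, {
    out <- list()
    for (id in ord) {
      if (!(id %in% names(pm))) {
        pr <- forest$priors[[id]]
        if (is.null(pr)) abort(sprintf("root %s has no prior", id))
        out[[id]] <- sample.int(length(pr), n, replace = TRUE, prob = pr) - 1L
      } else {
        cpt <- forest$cpts[[id]]
        if (is.null(cpt)) abort(sprintf("node %s has no CPT", id))
        if (any(abs(colSums(cpt) - 1) > 1e-6)) abort("invalid CPT")
        parent_vals <- out[[pm[[id]]]]
        v <- integer(n)
        for (k in seq_len(ncol(cpt))) {
          sel <- parent_vals == (k - 1L)
          if (any(sel)) {
            v[sel] <- sample.int(nrow(cpt), sum(sel), replace = TRUE,
                                 prob = cpt[, k]) - 1L
          }
        }
        out[[id]] <- v
      }
    }
    out
  })
  obs_ids <- forest$nodes$id[forest$nodes$type == "observed"]
  lat_ids <- forest$nodes$id[forest$nodes$type == "latent"]
  data <- do.call(cbind, draws[obs_ids])
  colnames(data) <- obs_ids
  latents <- if (length(lat_ids)) {
    m <- do.call(cbind, draws[lat_ids])
    colnames(m) <- lat_ids
    m
  } else {
    matrix(integer(0), nrow = n, ncol = 0)
  }
  list(
    data = snp_matrix(data, coding = coding, marker_names = obs_ids),
    latents = latents
  )
}

#' Simulate block-structured LD data
#'
#' Emulates haplotype data with a block LD structure: each block carries a
#' small pool of distinct ancestral haplotypes; every sampled haplotype copies
#' one pool member and then flips each allele independently with probability
#' `(1 - fidelity) / 2`. Blocks are mutually independent. Genotype coding sums
#' two independently sampled haplotypes per individual (random mating). This
#' is a desk-scale surrogate for coalescent simulators, not a model of
#' recombination.
#'
#' @param n_individuals individuals (haplotype coding yields this many
#'   haplotype rows; genotype coding uses two haplotypes per individual).
#' @param blocks data frame with columns `n_snps`, `n_haplotypes`, `fidelity`
#'   (one row per block; `fidelity` in \[0, 1\]).
#' @param coding `"genotype_012"` (default) or `"haplotype_01"`.
#' @param seed integer seed.
#' @return A list with `data` (an [snp_matrix()]), `block_labels` (integer
#'   block index per marker) and `ancestry` (integer matrix of sampled
#'   ancestral-haplotype indices, rows = sampled haplotypes, one column per
#'   block).
#' @export
generate_block_ld <- function(n_individuals, blocks,
                              coding = c("genotype_012", "haplotype_01"),
                              seed = 1L) {
  coding <- match.arg(coding)
  blocks <- as.data.frame(blocks)
  stopifnot(all(c("n_snps", "n_haplotypes", "fidelity") %in% colnames(blocks)),
            all(blocks$n_snps >= 1L), all(blocks$n_haplotypes >= 1L),
            all(blocks$fidelity >= 0 & blocks$fidelity <= 1),
            is_count(n_individuals))
  n_hap <- if (coding == "genotype_012") 2L * n_individuals else n_individuals
  with_seed(seed, {
    hap_cols <- list()
    anc <- matrix(0L, n_hap, nrow(blocks))
    labels <- integer(0)
    for (b in seq_len(nrow(blocks))) {
      ns <- blocks$n_snps[b]
      nh <- blocks$n_haplotypes[b]
      # distinct ancestral haplotypes, uniform over {0,1}^n_snps
      if (nh > 2^ns) abort("more ancestral haplotypes than distinct sequences")
      repeat {
        pool <- matrix(as.integer(runif(nh * ns) < 0.5), nh, ns)
        if (nh == 1L || anyDuplicated(pool) == 0L) break
      }
      idx <- sample.int(nh, n_hap, replace = TRUE)
      haps <- pool[idx, , drop = FALSE]
      flip <- matrix(runif(n_hap * ns) < (1 - blocks$fidelity[b]) / 2,
                     n_hap, ns)
      haps[flip] <- 1L - haps[flip]
      hap_cols[[b]] <- haps
      anc[, b] <- idx
      labels <- c(labels, rep(b, ns))
    }
    haps <- do.call(cbind, hap_cols)
    vals <- if (coding == "genotype_012") {
      haps[seq(1L, n_hap, 2L), , drop = FALSE] +
        haps[seq(2L, n_hap, 2L), , drop = FALSE]
    } else {
      haps
    }
    colnames(vals) <- paste0("SNP", seq_len(ncol(vals)))
    list(
      data = snp_matrix(vals, coding = coding),
      block_labels = labels,
      ancestry = anc
    )
  })
}

#' Collapse haplotype rows into genotype dosages
#'
#' Rows `2i - 1` and `2i` (the two haplotypes of individual `i`) are summed
#' per marker, turning 0/1 haplotypes into 0/1/2 genotypes. Column allele
#' counts are conserved.
#'
#' @param haps an [snp_matrix()] with `haplotype_01` coding and an even number
#'   of rows.
#' @return An [snp_matrix()] with `genotype_012` coding and half the rows.
#' @export
haplotypes_to_genotypes <- function(haps) {
  stopifnot(inherits(haps, "snp_matrix"))
  if (attr(haps, "coding") != "haplotype_01") {
    abort("haplotypes_to_genotypes expects haplotype_01 coding")
  }
  if (nrow(haps) %% 2L != 0L) abort("odd number of haplotype rows")
  m <- unclass(haps)
  g <- m[seq(1L, nrow(m), 2L), , drop = FALSE] +
    m[seq(2L, nrow(m), 2L), , drop = FALSE]
  snp_matrix(g, coding = "genotype_012", marker_names = colnames(haps),
             positions = attr(haps, "positions"),
             chromosome = attr(haps, "chromosome"))
}
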