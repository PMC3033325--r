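#' Dimension reduction rate of a forest
#'
#' Number of roots divided by the number of observed markers: each tree's
#' information is synthesized by its root, so the roots are the reduced
#' variable set. 1 means no reduction (every marker isolated).
#'
#' @param forest an `fhlc_forest`.
#' @return A value in (0, 1\].
#' @export
dimension_reduction_rate <- function(forest) {
  p <- sum(forest$nodes$type == "observed")
  if (p == 0L) abort("forest has no observed markers")
  length(forest_roots(forest)) / p
}

#' Number of trees (connected components) in a forest
#'
#' Equals the number of roots; isolated observed markers count as single-node
#' trees.
#'
#' @param forest an `fhlc_forest`.
#' @return Integer count.
#' @export
tree_count <- function(forest) {
  length(forest_roots(forest))
}

# plug-in joint entropy of observed value-tuples (no structure assumed)
joint_entropy_bits <- function(data) {
  keys <- do.call(paste, c(as.data.frame(data), sep = "\r"))
  entropy_bits(keys)
}

#' Entropy compression rate of a marker grouping
#'
#' Ratio of the sum of within-cluster joint entropies to the sum of marginal
#' marker entropies (the entropy assuming no structure). By subadditivity the
#' rate is at most 1, with equality when every cluster's members are mutually
#' independent in-sample; strong within-cluster LD drives it toward 0.
#'
#' @param grouping either an `fhlc_forest` (clusters are then the observed
#'   leaf sets of its trees) or a list of marker-name/index vectors covering
#'   all markers.
#' @param data the [snp_matrix()] the grouping refers to.
#' @return A positive value `<= 1`.
#' @export
entropy_compression_rate <- function(grouping, data) {
  data <- as.matrix(data)
  if (inherits(grouping, "fhlc_forest")) {
    grouping <- lapply(forest_roots(grouping), function(r) {
      subtree_leaves(grouping, r)
    })
  }
  members <- unlist(grouping, use.names = FALSE)
  idx <- if (is.character(members)) match(members, colnames(data)) else members
  if (anyNA(idx) || length(unique(idx)) != ncol(data)) {
    abort("grouping must cover every marker of the data exactly once")
  }
  marginal <- sum(vapply(seq_len(ncol(data)),
                         function(j) entropy_bits(data[, j]), numeric(1)))
  if (marginal <= 0) abort("all markers are constant; ECR undefined")
  joint <- sum(vapply(grouping, function(g) {
    gi <- if (is.character(g)) match(g, colnames(data)) else g
    joint_entropy_bits(data[, gi, drop = FALSE])
  }, numeric(1)))
  joint / marginal
}

#' Most-recent-common-ancestor level matrix
#'
#' For every pair of observed markers in the same tree, the layer of their
#' lowest common ancestor node; pairs in different trees get `NA` (written as
#' the sentinel `N` by [write_mrca_matrix()]). Low levels indicate strong LD
#' captured near the leaves.
#'
#' @param forest an `fhlc_forest`.
#' @return A symmetric integer matrix (markers x markers) with zero diagonal
#'   and `NA` for cross-tree pairs, of class `mrca_matrix`.
#' @export
mrca_levels <- function(forest) {
  obs <- forest$nodes$id[forest$nodes$type == "observed"]
  layer <- setNames(forest$nodes$layer, forest$nodes$id)
  pm <- parent_map(forest)
  paths <- lapply(obs, function(id) {
    path <- id
    while (id %in% names(pm)) {
      id <- pm[[id]]
      path <- c(path, id)
    }
    path
  })
  names(paths) <- obs
  p <- length(obs)
  out <- matrix(NA_integer_, p, p, dimnames = list(obs, obs))
  diag(out) <- 0L
  for (i in seq_len(p - 1L)) {
    for (j in (i + 1L):p) {
      common <- intersect(paths[[i]], paths[[j]])
      if (length(common)) {
        lev <- min(layer[common]) # lowest common ancestor = lowest layer
        out[i, j] <- out[j, i] <- as.integer(lev)
      }
    }
  }
  class(out) <- c("mrca_matrix", class(out))
  out
}

#' Write an MRCA-level matrix as TSV with sentinel N
#'
#' @param m a matrix from [mrca_levels()].
#' @param path output path.
#' @export
write_mrca_matrix <- function(m, path) {
  chr <- matrix(as.character(unclass(m)), nrow(m), dimnames = dimnames(m))
  chr[is.na(chr)] <- "N"
  write.table(chr, path, sep = "\t", quote = FALSE, row.names = TRUE,
              col.names = NA)
  invisible(path)
}

#' Pairwise r-squared against MRCA level
#'
#' One row per marker pair: the squared correlation of the two marker columns
#' and the layer of their most recent common ancestor (`NA` for cross-tree
#' pairs). Constant markers are dropped. The layered structure models LD
#' faithfully when median r-squared decreases as the MRCA level rises.
#'
#' @param forest an `fhlc_forest`.
#' @param data the [snp_matrix()] the forest was learned from.
#' @return A tibble with columns `marker_a`, `marker_b`, `mrca_level`, `r2`.
#' @export
mrca_r2_table <- function(forest, data) {
  m <- mrca_levels(forest)
  obs <- rownames(m)
  keep <- obs[vapply(obs, function(id) stats::var(as.matrix(data)[, id]) > 0,
                     logical(1))]
  pairs <- which(upper.tri(m[keep, keep, drop = FALSE]), arr.ind = TRUE)
  tibble(
    marker_a = keep[pairs[, 1]],
    marker_b = keep[pairs[, 2]],
    mrca_level = as.integer(m[keep, keep][pairs]),
    r2 = vapply(seq_len(nrow(pairs)), function(r) {
      r_squared(as.matrix(data)[, keep[pairs[r, 1]]],
                as.matrix(data)[, keep[pairs[r, 2]]])
    }, numeric(1))
  )
}

#' Haplotype diversity of a marker set
#'
#' The number of most common haplotypes: distinct observed value-tuples are
#' sorted by decreasing frequency (ties broken lexicographically) and the
#' smallest prefix whose cumulative frequency reaches `coverage` is counted.
#'
#' @param leaf_data matrix of the observed leaf columns of one subtree (rows =
#'   individuals or haplotypes).
#' @param coverage required cumulative sample fraction (default 0.75).
#' @return Integer: the size of the smallest covering haplotype set.
#' @export
most_common_haplotypes <- function(leaf_data, coverage = 0.75) {
  leaf_data <- as.matrix(leaf_data)
  if (nrow(leaf_data) == 0L) abort("empty data")
  keys <- do.call(paste, c(as.data.frame(leaf_data), sep = " "))
  tab <- table(keys)
  ord <- order(-as.vector(tab), names(tab))
  freq <- as.vector(tab)[ord] / length(keys)
  as.integer(which(cumsum(freq) >= coverage - 1e-12)[1])
}

#' Haplotype diversity per latent variable
#'
#' Applies [most_common_haplotypes()] to the observed leaf set of every latent
#' variable's subtree, giving the diversity-versus-level profile of a learned
#' forest.
#'
#' @param forest an `fhlc_forest`.
#' @param data the [snp_matrix()] the forest was learned from.
#' @param coverage cumulative coverage threshold (default 0.75).
#' @return A tibble with columns `latent`, `layer`, `n_leaves`,
#'   `n_common_haplotypes`.
#' @export
haplotype_diversity <- function(forest, data, coverage = 0.75) {
  lat <- forest$nodes %>% filter(.data$type == "latent")
  if (nrow(lat) == 0L) {
    return(tibble(latent = character(), layer = integer(),
                  n_leaves = integer(), n_common_haplotypes = integer()))
  }
  rows <- lapply(seq_len(nrow(lat)), function(i) {
    leaves <- subtree_leaves(forest, lat$id[i])
    tibble(
      latent = lat$id[i], layer = lat$layer[i], n_leaves = length(leaves),
      n_common_haplotypes = most_common_haplotypes(
        as.matrix(data)[, leaves, drop = FALSE], coverage
      )
    )
  })
  bind_rows(rows)
}

#' Per-layer variable counts and information retention
#'
#' Counts the variables on each layer and averages the scaled mutual
#' information of the edges whose parent sits on that layer (how much child
#' information the layer's latent variables retain). Layer 0 holds the
#' observed markers and has no incoming edges.
#'
#' @param forest an `fhlc_forest`.
#' @return A tibble with columns `layer`, `n_variables`, `mean_scaled_mi`
#'   (`NA` for layer 0).
#' @export
layer_statistics <- function(forest) {
  counts <- forest$nodes %>%
    group_by(.data$layer) %>%
    summarise(n_variables = dplyr::n(), .groups = "drop")
  if (nrow(forest$edges)) {
    lay <- setNames(forest$nodes$layer, forest$nodes$id)
    mi <- tibble(layer = lay[forest$edges$parent],
                 scaled_mi = forest$edges$scaled_mi) %>%
      group_by(.data$layer) %>%
      summarise(mean_scaled_mi = mean(.data$scaled_mi), .groups = "drop")
    counts <- left_join(counts, mi, by = "layer")
  } else {
    counts$mean_scaled_mi <- NA_real_
  }
  arrange(counts, .data$layer)
}
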