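# Small fixtures built in code.

# A hand-built 3-layer forest over 6 markers:
#           H3_1 (layer 3)
#          /    \
#      H2_1      \
#      /  \       \
#   H1_1   SNP5   H1_2      SNP7 isolated
#   /  \          /  \
# SNP1 SNP2   SNP3 SNP4     (SNP6 under H2_1)
toy_forest <- function(n = 8L) {
  nodes <- tibble::tibble(
    id = c("SNP1", "SNP2", "SNP3", "SNP4", "SNP5", "SNP6", "SNP7",
           "H1_1", "H1_2", "H2_1", "H3_1"),
    type = c(rep("observed", 7), rep("latent", 4)),
    layer = c(rep(0L, 7), 1L, 1L, 2L, 3L),
    cardinality = c(rep(2L, 7), 2L, 2L, 2L, 2L),
    window = 1L
  )
  edges <- tibble::tibble(
    parent = c("H1_1", "H1_1", "H1_2", "H1_2", "H2_1", "H2_1", "H2_1",
               "H3_1", "H3_1"),
    child = c("SNP1", "SNP2", "SNP3", "SNP4", "H1_1", "SNP5", "SNP6",
              "H2_1", "H1_2"),
    scaled_mi = c(0.9, 0.85, 0.8, 0.8, 0.6, 0.55, 0.55, 0.4, 0.35)
  )
  unif_cpt <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2)
  cpts <- setNames(
    rep(list(unif_cpt), nrow(edges)), edges$child
  )
  priors <- list(H3_1 = c(0.5, 0.5), SNP7 = c(0.7, 0.3))
  f <- fhlcforest:::new_fhlc_forest(
    nodes, edges, priors, cpts,
    imputed = matrix(
      sample(0:1, n * 4L, replace = TRUE), n, 4L,
      dimnames = list(NULL, c("H1_1", "H1_2", "H2_1", "H3_1"))
    ),
    n_individuals = n,
    config = list(coding = "haplotype_01")
  )
  fhlcforest:::validate_forest(f)
  f
}

# random categorical matrix, 0-based codes
random_cat_matrix <- function(n, p, k = 2L) {
  matrix(sample(0:(k - 1L), n * p, replace = TRUE), n, p,
         dimnames = list(NULL, paste0("V", seq_len(p))))
}

# random undirected 0/1 similarity matrix with unit diagonal
random_similarity <- function(m, density = 0.3) {
  s <- matrix(0L, m, m)
  up <- which(upper.tri(s))
  s[up] <- as.integer(runif(length(up)) < density)
  s <- s + t(s)
  diag(s) <- 1L
  colnames(s) <- rownames(s) <- paste0("V", seq_len(m))
  s
}

# random forest over ids as parent map (each node at most one parent, acyclic
# by construction: parents always have larger index in the latent ordering)
random_parent_forest <- function(n_obs, n_lat, p_link = 0.7) {
  obs <- paste0("X", seq_len(n_obs))
  lat <- if (n_lat > 0L) paste0("L", seq_len(n_lat)) else character(0)
  parents <- list()
  layers <- setNames(rep(0L, n_obs), obs)
  for (i in seq_along(lat)) layers[lat[i]] <- NA_integer_
  # children of latent i can be observed nodes or latents with smaller index
  for (i in seq_along(lat)) {
    cand <- c(obs, lat[seq_len(i - 1L)])
    cand <- cand[!(cand %in% names(parents))]
    take <- cand[runif(length(cand)) < p_link]
    if (length(take) >= 2L) {
      for (ch in take) parents[[ch]] <- lat[i]
      layers[lat[i]] <- 1L + max(layers[take])
    }
  }
  keep_lat <- lat[lat %in% unlist(parents)]
  list(
    parents = parents,
    layers = layers[c(obs, keep_lat)],
    obs = obs, lat = keep_lat
  )
}

# wrap a parent-map forest into an fhlc_forest (structure only)
forest_from_parent_map <- function(pf, n = 4L) {
  ids <- c(pf$obs, pf$lat)
  nodes <- tibble::tibble(
    id = ids,
    type = c(rep("observed", length(pf$obs)), rep("latent", length(pf$lat))),
    layer = as.integer(pf$layers[ids]),
    cardinality = 2L,
    window = 1L
  )
  edges <- if (length(pf$parents)) {
    tibble::tibble(
      parent = unlist(pf$parents),
      child = names(pf$parents),
      scaled_mi = 0.5
    )
  } else {
    tibble::tibble(parent = character(), child = character(),
                   scaled_mi = numeric())
  }
  f <- fhlcforest:::new_fhlc_forest(
    nodes, edges, priors = list(), cpts = list(),
    imputed = matrix(integer(0), n, 0), n_individuals = n
  )
  f
}
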