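#' Configuration for forest construction
#'
#' Defaults follow the reference parameter set used throughout the package's
#' analyses: `a = 0.2`, `b = 2`, `card_max = 20`, `t_cast = 0.95`,
#' `mi_quantile = 0.95`, `t = 0.3`, window size 100.
#'
#' @param window_size number of contiguous markers per window (>= 2). Windows
#'   are defined over marker index; the last window absorbs the remainder.
#' @param t validation threshold in \[0, 1\] on the information-decay
#'   criterion C: a candidate latent variable is kept only if it captures on
#'   average at least this fraction of its children's information.
#' @param a,b,card_max affine cardinality rule, see [latent_cardinality()].
#' @param t_cast CAST affinity threshold in (0, 1\].
#' @param mi_quantile quantile of the current MI matrix used as the
#'   binarization threshold `t_MI`, recomputed at every agglomerative step.
#' @param imputation `"map"` (deterministic posterior argmax; default) or
#'   `"sample"` (posterior draw).
#' @param em EM settings from [em_control()].
#' @param seed master seed; every stochastic sub-step derives its own stream
#'   from it, so any window is reproducible in isolation.
#' @return A `cfhlc_config` list.
#' @export
cfhlc_config <- function(window_size = 100L, t = 0.3, a = 0.2, b = 2,
                         card_max = 20L, t_cast = 0.95, mi_quantile = 0.95,
                         imputation = c("map", "sample"), em = em_control(),
                         seed = 1L) {
  imputation <- match.arg(imputation)
  if (!is_count(window_size, 2L)) abort("window_size must be an integer >= 2")
  if (t < 0 || t > 1) abort("t must lie in [0, 1]")
  if (t_cast <= 0 || t_cast > 1) abort("t_cast must lie in (0, 1]")
  if (mi_quantile < 0 || mi_quantile > 1) abort("mi_quantile must lie in [0, 1]")
  structure(list(
    window_size = as.integer(window_size), t = t, a = a, b = b,
    card_max = as.integer(card_max), t_cast = t_cast,
    mi_quantile = mi_quantile, imputation = imputation, em = em,
    seed = as.integer(seed)
  ), class = "cfhlc_config")
}

#' Split markers into contiguous windows
#'
#' Non-overlapping index ranges of `s` markers; the last window holds the
#' remainder (possibly fewer than `s` markers).
#'
#' @param x an [snp_matrix()] or a marker count.
#' @param s window size (>= 2).
#' @return A tibble with columns `window`, `from`, `to` (column indices).
#' @examples
#' split_windows(103, 100) # 1..100 and 101..103
#' @export
split_windows <- function(x, s) {
  if (!is_count(s, 2L)) abort("window size must be an integer >= 2")
  p <- if (inherits(x, "snp_matrix") || is.matrix(x)) ncol(x) else as.integer(x)
  if (!is_count(p, 1L)) abort("need at least one marker")
  nbw <- ceiling(p / s)
  from <- (seq_len(nbw) - 1L) * as.integer(s) + 1L
  tibble(window = seq_len(nbw), from = from, to = pmin(from + as.integer(s) - 1L, p))
}

# Agglomerative construction within one window. Returns node/edge/parameter
# fragments plus imputed latent columns and a step log.
build_window <- function(data, ids, window_index, config, counter) {
  n <- nrow(data)
  W <- data # working matrix: current layer's columns
  w_ids <- ids
  w_layers <- setNames(rep(0L, length(ids)), ids)
  nodes <- tibble(
    id = ids, type = "observed", layer = 0L,
    cardinality = unname(apply(data, 2, function(v) length(unique(v)))),
    window = window_index
  )
  edges <- tibble(parent = character(), child = character(),
                  scaled_mi = numeric())
  priors <- list()
  cpts <- list()
  imputed_cols <- list()
  log <- list(steps = 0L, lv_created = 0L, lv_rejected = 0L)

  step <- 1L
  repeat {
    if (ncol(W) < 2L) break
    mi <- pairwise_mi_matrix(W)
    t_mi <- mi_quantile_threshold(mi, config$mi_quantile)
    sim <- binarize_similarity(mi, t_mi)
    colnames(sim) <- rownames(sim) <- w_ids
    clusters <- cast_partition(sim, config$t_cast)
    log$steps <- step
    if (all(lengths(clusters) == 1L)) break

    big <- clusters[lengths(clusters) > 1L]
    n_valid <- 0L
    for (k in seq_along(big)) {
      members <- big[[k]]
      cols <- match(members, w_ids)
      card <- latent_cardinality(length(members), config$a, config$b,
                                 config$card_max)
      sub_seed <- derive_seed(config$seed, window_index, step, k)
      child_data <- W[, cols, drop = FALSE]
      model <- em_learn(child_data, card, control = config$em, seed = sub_seed)
      hvals <- impute_latent(model, child_data, mode = config$imputation,
                             seed = derive_seed(sub_seed, 271L))
      C <- criterion_c(child_data, hvals)
      if (C >= config$t) {
        n_valid <- n_valid + 1L
        lv_layer <- 1L + max(w_layers[members])
        lv_id <- next_latent_id(counter, lv_layer)
        per_edge <- vapply(seq_along(cols), function(j) {
          scaled_mutual_information(child_data[, j], hvals)
        }, numeric(1))
        nodes <- bind_rows(nodes, tibble(
          id = lv_id, type = "latent", layer = lv_layer,
          cardinality = model$cardinality, window = window_index
        ))
        edges <- bind_rows(edges, tibble(
          parent = lv_id, child = members, scaled_mi = per_edge
        ))
        priors[[lv_id]] <- model$prior
        for (j in seq_along(members)) {
          cpts[[members[j]]] <- model$child_cpts[[j]]
        }
        imputed_cols[[lv_id]] <- hvals
        # replace children by the latent column in the working set
        keep <- setdiff(seq_along(w_ids), cols)
        W <- cbind(W[, keep, drop = FALSE], hvals)
        w_ids <- c(w_ids[keep], lv_id)
        colnames(W) <- w_ids
        w_layers <- c(w_layers[keep], setNames(lv_layer, lv_id))
        log$lv_created <- log$lv_created + 1L
      } else {
        log$lv_rejected <- log$lv_rejected + 1L
      }
    }
    if (n_valid == 0L) break
    step <- step + 1L
  }
  list(nodes = nodes, edges = edges, priors = priors, cpts = cpts,
       imputed = imputed_cols, log = log)
}

# per-layer latent counter ("H<layer>_<i>" ids), shared across windows
new_lv_counter <- function() new.env(parent = emptyenv())
next_latent_id <- function(counter, layer) {
  key <- as.character(layer)
  i <- if (is.null(counter[[key]])) 1L else counter[[key]] + 1L
  counter[[key]] <- i
  sprintf("H%d_%d", layer, i)
}

#' Learn a forest of hierarchical latent class models
#'
#' Splits the markers into contiguous windows and, within each window, runs an
#' agglomerative loop: the pairwise mutual-information matrix of the current
#' working set is thresholded at its `mi_quantile` quantile, the binarized
#' similarity graph is partitioned by CAST, and every cluster of two or more
#' variables is offered to a latent class model fitted by EM. A candidate
#' latent variable is validated only if its information-decay criterion C
#' reaches `t`; validated latents replace their children in the working set
#' (their imputed values become next-step observations) while members of
#' rejected clusters stay isolated for the next step. The loop stops when all
#' clusters are singletons or no cluster validates. Windows are processed one
#' at a time and assumed mutually independent, so the final forest is the
#' union of the per-window forests.
#'
#' @param x a complete [snp_matrix()] (no missing cells; see
#'   [impute_missing()]).
#' @param config a [cfhlc_config()].
#' @return An `fhlc_forest`: node and edge tables (with per-edge scaled
#'   mutual information), root priors, child conditional probability tables,
#'   and the imputed data matrix for every validated latent variable. A
#'   per-window summary is attached as attribute `window_log`.
#' @examples
#' sim <- generate_block_ld(n_individuals = 200, blocks = data.frame(
#'   n_snps = c(6, 6), n_haplotypes = 3, fidelity = 0.98
#' ), seed = 7)
#' f <- cfhlc(sim$data, cfhlc_config(window_size = 12, seed = 7))
#' tree_count(f)
#' @export
cfhlc <- function(x, config = cfhlc_config()) {
  stopifnot(inherits(x, "snp_matrix"), inherits(config, "cfhlc_config"))
  if (any(x == -1L)) abort("missing cells present; run impute_missing() first")
  wins <- split_windows(x, config$window_size)
  counter <- new_lv_counter()
  parts <- vector("list", nrow(wins))
  for (i in seq_len(nrow(wins))) {
    cols <- wins$from[i]:wins$to[i]
    wcfg <- config
    parts[[i]] <- build_window(
      unclass(x)[, cols, drop = FALSE], colnames(x)[cols], wins$window[i],
      wcfg, counter
    )
  }
  nodes <- bind_rows(lapply(parts, `[[`, "nodes"))
  edges <- bind_rows(lapply(parts, `[[`, "edges"))
  priors <- do.call(c, lapply(parts, `[[`, "priors"))
  cpts <- do.call(c, lapply(parts, `[[`, "cpts"))
  imp_list <- do.call(c, lapply(parts, `[[`, "imputed"))
  imputed <- if (length(imp_list)) {
    m <- do.call(cbind, imp_list)
    colnames(m) <- names(imp_list)
    storage.mode(m) <- "integer"
    m
  } else {
    matrix(integer(0), nrow = nrow(x), ncol = 0)
  }
  # marginal priors for observed roots (isolated nodes and tree leaves keep
  # their CPTs; isolated observed nodes need a prior for the joint density)
  obs_roots <- setdiff(nodes$id[nodes$type == "observed"], edges$child)
  dom_size <- length(snp_domain(attr(x, "coding")))
  for (r in obs_roots) {
    v <- unclass(x)[, r]
    priors[[r]] <- tabulate(v + 1L, nbins = dom_size) / length(v)
  }
  f <- new_fhlc_forest(nodes, edges, priors, cpts, imputed, nrow(x),
                       config = unclass(config))
  validate_forest(f)
  attr(f, "window_log") <- tibble(
    window = wins$window,
    steps = vapply(parts, function(p) p$log$steps, integer(1)),
    lv_created = vapply(parts, function(p) p$log$lv_created, integer(1)),
    lv_rejected = vapply(parts, function(p) p$log$lv_rejected, integer(1))
  )
  f
}
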