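#' Latent-variable cardinality from cluster size
#'
#' Affine rule `min(floor(a * size + b), card_max)`, floored to at least 2
#' states. The more children a latent variable subsumes, the more joint
#' configurations its cluster can realize, so its cardinality grows with
#' cluster size up to the cap.
#'
#' @param cluster_size number of child variables (>= 2).
#' @param a,b affine coefficients (defaults 0.2 and 2).
#' @param card_max cardinality cap (>= 2; default 20).
#' @return Integer cardinality in `[2, card_max]`.
#' @examples
#' latent_cardinality(10) # 4
#' latent_cardinality(100) # capped at 20
#' @export
latent_cardinality <- function(cluster_size, a = 0.2, b = 2, card_max = 20L) {
  if (!is_count(card_max, 2L)) abort("card_max must be an integer >= 2")
  if (!is_count(cluster_size, 2L)) abort("cluster_size must be an integer >= 2")
  max(2L, min(as.integer(floor(a * cluster_size + b)), as.integer(card_max)))
}

#' Regularized cardinality from child cardinalities
#'
#' Product of the child cardinalities divided by their maximum. For ten
#' children of cardinality 3 this gives 3^10 / 3 = 19683 — illustrating why an
#' unconstrained regularization rule is impractical on SNP clusters and why
#' the capped affine rule of [latent_cardinality()] is used instead. Kept as a
#' utility.
#'
#' @param child_cards integer vector of child cardinalities, each >= 2.
#' @return Integer-valued cardinality.
#' @export
regularization_cardinality <- function(child_cards) {
  if (length(child_cards) == 0L) abort("child_cards must be non-empty")
  if (any(child_cards < 2L)) abort("child cardinalities must be >= 2")
  round(prod(as.double(child_cards)) / max(child_cards))
}

#' EM control settings for latent class model fitting
#'
#' @param n_restarts independent random restarts; the best log-likelihood fit
#'   is kept.
#' @param max_iter maximum EM iterations per restart.
#' @param tol convergence threshold on the relative log-likelihood change.
#' @param smoothing pseudo-count added to aggregated responsibilities before
#'   M-step normalization, preventing zero-probability lock-in.
#' @return A list of settings for [em_learn()].
#' @export
em_control <- function(n_restarts = 3L, max_iter = 500L, tol = 1e-6,
                       smoothing = 1e-9) {
  stopifnot(is_count(n_restarts), is_count(max_iter), tol > 0, smoothing >= 0)
  list(n_restarts = as.integer(n_restarts), max_iter = as.integer(max_iter),
       tol = tol, smoothing = smoothing)
}

#' Fit a latent class model by EM
#'
#' One discrete latent root with the given cardinality; the observed child
#' columns are conditionally independent given the root. Parameters (root
#' prior and one conditional probability table per child) are estimated by
#' standard EM from several random restarts (symmetric Dirichlet(1) draws),
#' keeping the best log-likelihood.
#'
#' @param data integer matrix (individuals x children), complete, values
#'   `0..card_j-1` per child; at least two columns.
#' @param cardinality number of latent states (>= 2).
#' @param control settings from [em_control()].
#' @param seed integer seed driving all restarts.
#' @param child_cards optional integer vector of child state counts; defaults
#'   to `max(column) + 1`.
#' @return An object of class `lcm_fit` with elements `cardinality`,
#'   `child_ids`, `child_cards`, `prior`, `child_cpts` (each a
#'   `child_card x cardinality` matrix with columns summing to 1), `loglik`,
#'   `loglik_trace` (one numeric vector per restart), `n_restarts_used`.
#' @export
em_learn <- function(data, cardinality, control = em_control(), seed = 1L,
                     child_cards = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "integer"
  if (ncol(data) < 2L) abort("a latent class model needs at least two children")
  if (!is_count(cardinality, 2L)) abort("cardinality must be an integer >= 2")
  if (any(data < 0L)) abort("em_learn requires complete non-negative data")
  n <- nrow(data)
  pc <- ncol(data)
  if (is.null(child_cards)) child_cards <- apply(data, 2, max) + 1L
  child_cards <- pmax(as.integer(child_cards), 2L)
  if (all(apply(data, 2, function(v) length(unique(v))) == 1L)) {
    warn("all child columns are constant; returning a degenerate model")
  }
  K <- as.integer(cardinality)
  best <- NULL
  traces <- vector("list", control$n_restarts)
  for (r in seq_len(control$n_restarts)) {
    fit <- with_seed(derive_seed(seed, 811L, r), {
      em_single_run(data, K, child_cards, control)
    })
    traces[[r]] <- fit$trace
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  structure(list(
    latent_id = NA_character_,
    cardinality = K,
    child_ids = colnames(data),
    child_cards = child_cards,
    prior = best$prior,
    child_cpts = best$cpts,
    loglik = best$loglik,
    loglik_trace = traces,
    n_restarts_used = control$n_restarts
  ), class = "lcm_fit")
}

# one EM run from a random Dirichlet(1) start; assumes seeded RNG
em_single_run <- function(data, K, child_cards, control) {
  n <- nrow(data)
  pc <- ncol(data)
  prior <- rdirichlet1(K)
  cpts <- lapply(seq_len(pc), function(j) {
    m <- vapply(seq_len(K), function(k) rdirichlet1(child_cards[j]),
                numeric(child_cards[j]))
    matrix(m, nrow = child_cards[j], ncol = K)
  })
  trace <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(control$max_iter)) {
    # E-step in log space
    logp <- matrix(log(prior), n, K, byrow = TRUE)
    for (j in seq_len(pc)) {
      logp <- logp + log(cpts[[j]])[data[, j] + 1L, , drop = FALSE]
    }
    mx <- apply(logp, 1, max)
    w <- exp(logp - mx)
    rs <- rowSums(w)
    ll <- sum(mx + log(rs))
    resp <- w / rs
    trace <- c(trace, ll)
    # M-step with smoothing pseudo-counts
    eps <- control$smoothing
    colsums <- colSums(resp)
    prior <- (colsums + eps) / (n + K * eps)
    for (j in seq_len(pc)) {
      counts <- rowsum(resp, group = data[, j], reorder = TRUE)
      full <- matrix(0, child_cards[j], K)
      full[as.integer(rownames(counts)) + 1L, ] <- counts
      full <- full + eps
      cpts[[j]] <- sweep(full, 2, colSums(full), "/")
    }
    if (is.finite(ll_old) && abs(ll - ll_old) <= control$tol * abs(ll_old)) break
    ll_old <- ll
  }
  list(prior = prior, cpts = cpts, loglik = trace[length(trace)], trace = trace)
}

# posterior over latent states: n x K matrix of P(H = k | children)
lcm_posterior <- function(model, data) {
  data <- as.matrix(data)
  storage.mode(data) <- "integer"
  if (ncol(data) != length(model$child_cpts)) {
    abort("data columns do not match the model's children")
  }
  n <- nrow(data)
  K <- model$cardinality
  logp <- matrix(log(model$prior), n, K, byrow = TRUE)
  for (j in seq_along(model$child_cpts)) {
    logp <- logp + log(model$child_cpts[[j]])[data[, j] + 1L, , drop = FALSE]
  }
  mx <- apply(logp, 1, max)
  w <- exp(logp - mx)
  w / rowSums(w)
}

#' Impute latent values for each individual
#'
#' MAP mode assigns the most probable latent state given the child
#' observations (ties broken toward the lowest state index) and is
#' deterministic; sample mode draws each individual's state from its exact
#' posterior.
#'
#' @param model an [em_learn()] fit.
#' @param data child-column matrix compatible with the fit.
#' @param mode `"map"` or `"sample"`.
#' @param seed seed for sample mode.
#' @return Integer vector of latent states in `0..cardinality-1`, length
#'   `nrow(data)`.
#' @export
impute_latent <- function(model, data, mode = c("map", "sample"), seed = 1L) {
  mode <- match.arg(mode)
  post <- lcm_posterior(model, data)
  if (mode == "map") {
    as.integer(max.col(post, ties.method = "first") - 1L)
  } else {
    K <- ncol(post)
    with_seed(seed, {
      u <- runif(nrow(post))
      cum <- t(apply(post, 1, cumsum))
      as.integer(rowSums(u > cum + 1e-15))
    })
  }
}

#' Information-decay criterion C of a latent class model
#'
#' The average over children of the scaled mutual information between the
#' child column and the imputed latent column: the average fraction of each
#' child's information captured by the latent variable. Used as the validation
#' gate (`C >= t`) during forest construction.
#'
#' @param child_data matrix of child columns.
#' @param latent_values imputed latent state per individual.
#' @return A value in \[0, 1\].
#' @export
criterion_c <- function(child_data, latent_values) {
  child_data <- as.matrix(child_data)
  if (nrow(child_data) != length(latent_values)) {
    abort("latent_values must align with child_data rows")
  }
  mean(vapply(
    seq_len(ncol(child_data)),
    function(j) scaled_mutual_information(child_data[, j], latent_values),
    numeric(1)
  ))
}

#' Total information shared between a latent variable and its children
#'
#' The sum of mutual information over the model's edges,
#' \eqn{\Delta = \sum_i I(X_i, H)}: the entropy difference between the
#' independence model and the latent class model.
#'
#' @inheritParams criterion_c
#' @return Non-negative total, in bits.
#' @export
delta_information <- function(child_data, latent_values) {
  child_data <- as.matrix(child_data)
  if (nrow(child_data) != length(latent_values)) {
    abort("latent_values must align with child_data rows")
  }
  sum(vapply(
    seq_len(ncol(child_data)),
    function(j) mutual_information(child_data[, j], latent_values),
    numeric(1)
  ))
}
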