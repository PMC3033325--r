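test_that("affine cardinality rule floors, caps and bounds below", {
  expect_equal(latent_cardinality(10, 0.2, 2, 20), 4L)
  expect_equal(latent_cardinality(100, 0.2, 2, 20), 20L)
  expect_equal(latent_cardinality(2, 0.2, 2, 20), 2L) # floor(2.4)
  expect_equal(latent_cardinality(3, 0, 0, 20), 2L) # floored up to 2
  expect_error(latent_cardinality(10, 0.2, 2, 1), "card_max")
  expect_error(latent_cardinality(1, 0.2, 2, 20), "cluster_size")
})

test_that("regularization cardinality is product over maximum", {
  expect_equal(regularization_cardinality(rep(3L, 10)), 19683)
  expect_equal(regularization_cardinality(5L), 1)
  expect_equal(regularization_cardinality(c(2L, 3L)), 2)
  expect_error(regularization_cardinality(integer(0)), "non-empty")
  expect_error(regularization_cardinality(c(3L, 1L)), ">= 2")
})

test_that("EM recovers a deterministic two-child dependence", {
  set.seed(5)
  x1 <- sample(0:1, 50, replace = TRUE)
  d <- cbind(a = x1, b = x1)
  fit <- em_learn(d, 2, seed = 42)
  h <- impute_latent(fit, d)
  # latent must capture all of x1's information
  expect_equal(mutual_information(h, x1), entropy_bits(x1), tolerance = 1e-6)
})

test_that("EM on independent children approaches the independence likelihood", {
  set.seed(6)
  n <- 2000
  d <- cbind(a = sample(0:1, n, replace = TRUE),
             b = sample(0:1, n, replace = TRUE))
  fit <- em_learn(d, 2, seed = 3)
  ll_ind <- oracle_independence_loglik(d)
  expect_gte(fit$loglik, ll_ind - 1e-6) # latent model nests independence
  expect_lte(abs(fit$loglik - ll_ind), 1e-3 * n)
})

test_that("EM log-likelihood traces are non-decreasing within restarts", {
  set.seed(8)
  for (rep in 1:10) {
    d <- random_cat_matrix(60, sample(2:4, 1), k = sample(2:3, 1))
    fit <- em_learn(d, sample(2:4, 1), seed = rep)
    for (tr in fit$loglik_trace) {
      expect_true(all(diff(tr) >= -1e-8))
    }
  }
})

test_that("best-of-restarts selection dominates every single restart", {
  set.seed(9)
  d <- random_cat_matrix(80, 3, k = 3)
  fit <- em_learn(d, 3, control = em_control(n_restarts = 5), seed = 17)
  finals <- vapply(fit$loglik_trace, function(tr) tr[length(tr)], numeric(1))
  expect_equal(fit$loglik, max(finals))
  expect_gte(fit$loglik, max(finals) - 1e-9)
})

test_that("EM output is a valid probability model", {
  set.seed(10)
  d <- random_cat_matrix(100, 4, k = 3)
  fit <- em_learn(d, 4, seed = 2)
  expect_equal(sum(fit$prior), 1, tolerance = 1e-9)
  for (cpt in fit$child_cpts) {
    expect_equal(colSums(cpt), rep(1, ncol(cpt)), tolerance = 1e-9)
    expect_true(all(cpt >= 0))
  }
  expect_error(em_learn(d, 1, seed = 1), "cardinality")
  expect_error(em_learn(d[, 1, drop = FALSE], 2, seed = 1), "two children")
  expect_warning(em_learn(cbind(rep(0L, 20), rep(1L, 20)), 2, seed = 1),
                 "constant")
})

test_that("MAP imputation recovers generating latent values", {
  # children are deterministic functions of the latent with distinct
  # signatures, so MAP must recover the latent exactly up to relabeling
  f <- make_two_layer_forest(
    n_trees = 1, clusters_per_tree = 1, snps_per_cluster = 4,
    latent_card = 3, fidelity = 1
  )
  sim <- sample_fhlcm(f, 500, seed = 21)
  fit <- em_learn(unclass(sim$data), 3, seed = 4)
  h <- impute_latent(fit, unclass(sim$data), mode = "map")
  truth <- sim$latents[, 1]
  tab <- table(h, truth)
  purity <- sum(apply(tab, 1, max)) / length(h)
  expect_equal(purity, 1)
})

test_that("MAP ties break toward the lowest state and sampling is calibrated", {
  # uniform posterior: prior uniform, children carry no information
  d <- cbind(a = rep(0L, 10), b = rep(0L, 10))
  fit <- structure(list(
    latent_id = "H1_1", cardinality = 3L, child_ids = c("a", "b"),
    child_cards = c(2L, 2L),
    prior = rep(1 / 3, 3),
    child_cpts = list(matrix(0.5, 2, 3), matrix(0.5, 2, 3)),
    loglik = 0, loglik_trace = list(0), n_restarts_used = 1L
  ), class = "lcm_fit")
  expect_equal(impute_latent(fit, d, mode = "map"), rep(0L, 10))
  # posterior sampling matches posterior frequencies within 3 sigma
  n <- 10000
  dd <- cbind(a = rep(0L, n), b = rep(0L, n))
  s1 <- impute_latent(fit, dd, mode = "sample", seed = 11)
  expect_identical(s1, impute_latent(fit, dd, mode = "sample", seed = 11))
  freq <- tabulate(s1 + 1L, 3) / n
  sigma <- sqrt((1 / 3) * (2 / 3) / n)
  expect_true(all(abs(freq - 1 / 3) < 3 * sigma + 1e-9))
})

test_that("criterion C averages per-child scaled MI and is order-invariant", {
  set.seed(13)
  h <- sample(0:2, 300, replace = TRUE)
  c1 <- h %% 2 # strongly dependent
  c2 <- ifelse(runif(300) < 0.7, h %% 2, sample(0:1, 300, replace = TRUE))
  c3 <- sample(0:1, 300, replace = TRUE) # independent
  d <- cbind(c1, c2, c3)
  expected <- mean(c(
    scaled_mutual_information(c1, h),
    scaled_mutual_information(c2, h),
    scaled_mutual_information(c3, h)
  ))
  expect_equal(criterion_c(d, h), expected, tolerance = 1e-12)
  expect_equal(criterion_c(d[, c(3, 1, 2)], h), expected, tolerance = 1e-12)
  expect_equal(criterion_c(cbind(h, h, h), h), 1.0)
  expect_gte(criterion_c(d, h), 0)
  expect_lte(criterion_c(d, h), 1)
})

test_that("delta information sums per-edge MI", {
  z <- rep(0:1, 100)
  expect_equal(delta_information(cbind(z, z, z), z), 3.0)
  set.seed(14)
  h <- sample(0:1, 200, replace = TRUE)
  d <- random_cat_matrix(200, 3, k = 2)
  expected <- sum(vapply(1:3, function(j) oracle_mi(d[, j], h), numeric(1)))
  expect_equal(delta_information(d, h), expected, tolerance = 1e-12)
  ind <- rep(0:1, each = 100)
  half <- rep(c(0, 1), 100)
  expect_equal(delta_information(cbind(half), ind), 0, tolerance = 1e-9)
})

test_that("latent recovery from a sampled LCM reaches high adjusted Rand", {
  f <- make_two_layer_forest(
    n_trees = 1, clusters_per_tree = 1, snps_per_cluster = 5,
    latent_card = 3, fidelity = 0.95, coding = "genotype_012"
  )
  sim <- sample_fhlcm(f, 2000, seed = 31)
  fit <- em_learn(unclass(sim$data), 3, seed = 7)
  h <- impute_latent(fit, unclass(sim$data))
  ari <- mclust::adjustedRandIndex(h, sim$latents[, 1])
  expect_gte(ari, 0.9)
})
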