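test_that("windowing covers all markers contiguously with a remainder tail", {
  w <- split_windows(103, 100)
  expect_equal(w$from, c(1L, 101L))
  expect_equal(w$to, c(100L, 103L))
  w2 <- split_windows(200, 100)
  expect_equal(nrow(w2), 2L)
  expect_equal(w2$to - w2$from + 1L, c(100L, 100L))
  w3 <- split_windows(50, 100)
  expect_equal(nrow(w3), 1L)
  expect_equal(c(w3$from, w3$to), c(1L, 50L))
  expect_error(split_windows(50, 1), ">= 2")
})

test_that("independent markers yield no latent variables", {
  set.seed(61)
  x <- snp_matrix(random_cat_matrix(2000, 8, k = 2), coding = "haplotype_01")
  # t = 0.6, the reference setting for simulated-data studies: a two-state
  # latent copying one of two independent children always scores C = 0.5,
  # so a gate above 0.5 is what rejects spurious pair clusters
  f <- cfhlc(x, cfhlc_config(window_size = 8, t = 0.6, seed = 3))
  expect_equal(sum(f$nodes$type == "latent"), 0L)
  expect_equal(tree_count(f), 8L)
  expect_equal(dimension_reduction_rate(f), 1.0)
})

test_that("two perfectly correlated blocks collapse into two trees", {
  set.seed(62)
  a <- sample(0:1, 2000, replace = TRUE)
  b <- sample(0:1, 2000, replace = TRUE)
  x <- snp_matrix(cbind(s1 = a, s2 = a, s3 = a, s4 = b, s5 = b, s6 = b),
                  coding = "haplotype_01")
  f <- cfhlc(x, cfhlc_config(window_size = 6, t = 0.6, seed = 3))
  lat1 <- f$nodes$id[f$nodes$type == "latent" & f$nodes$layer == 1L]
  expect_equal(length(lat1), 2L)
  expect_equal(tree_count(f), 2L)
  leafsets <- lapply(forest_roots(f), function(r) {
    sort(fhlcforest:::subtree_leaves(f, r))
  })
  expect_setequal(
    vapply(leafsets, paste, "", collapse = ","),
    c("s1,s2,s3", "s4,s5,s6")
  )
})

test_that("a maximal dilution threshold forbids every latent variable", {
  set.seed(63)
  s <- generate_block_ld(300, data.frame(n_snps = c(4, 4), n_haplotypes = 3,
                                         fidelity = 0.9), seed = 5)
  f <- cfhlc(s$data, cfhlc_config(window_size = 8, t = 1.0, seed = 5))
  expect_equal(sum(f$nodes$type == "latent"), 0L)
  expect_equal(tree_count(f), 8L)
})

test_that("single-column windows survive as isolated observed nodes", {
  set.seed(64)
  x <- snp_matrix(random_cat_matrix(100, 5, k = 2), coding = "haplotype_01")
  f <- cfhlc(x, cfhlc_config(window_size = 4, seed = 2)) # windows 4 + 1
  expect_equal(sum(f$nodes$type == "observed"), 5L)
  expect_true(all(f$nodes$window[f$nodes$id == "V5"] == 2L))
})

test_that("construction is deterministic and honours forest invariants", {
  s <- generate_block_ld(250, data.frame(n_snps = c(5, 5), n_haplotypes = 3,
                                         fidelity = 0.95), seed = 17)
  cfg <- cfhlc_config(window_size = 10, seed = 17)
  f1 <- cfhlc(s$data, cfg)
  f2 <- cfhlc(s$data, cfg)
  expect_identical(f1$nodes, f2$nodes)
  expect_identical(f1$edges, f2$edges)
  expect_identical(f1$imputed, f2$imputed)
  # invariants: single parent, layers, CPT columns (validate_forest throws)
  expect_silent(fhlcforest:::validate_forest(f1))
  # every latent variable passed the validation gate
  cdata <- cbind(unclass(s$data), f1$imputed)
  for (lv in f1$nodes$id[f1$nodes$type == "latent"]) {
    ch <- f1$edges$child[f1$edges$parent == lv]
    expect_gte(criterion_c(cdata[, ch, drop = FALSE], f1$imputed[, lv]),
               cfg$t)
  }
})

test_that("edges never cross window boundaries", {
  s <- generate_block_ld(200, data.frame(n_snps = c(4, 4, 4), n_haplotypes = 3,
                                         fidelity = 0.95), seed = 23)
  f <- cfhlc(s$data, cfhlc_config(window_size = 6, seed = 23)) # 2 windows
  win <- setNames(f$nodes$window, f$nodes$id)
  expect_true(all(win[f$edges$parent] == win[f$edges$child]))
})

test_that("raising the dilution threshold never merges more", {
  s <- generate_block_ld(400, data.frame(n_snps = c(6, 6), n_haplotypes = 3,
                                         fidelity = 0.9), seed = 29)
  trees <- vapply(c(0.1, 0.3, 0.6), function(t) {
    tree_count(cfhlc(s$data, cfhlc_config(window_size = 12, t = t, seed = 29)))
  }, numeric(1))
  expect_true(all(diff(trees) >= 0))
})

test_that("stronger LD gives fewer trees and deeper forests", {
  res <- purrr::map_dfr(1:10, function(seed) {
    purrr::map_dfr(c(0.55, 0.75, 0.95), function(fid) {
      s <- generate_block_ld(
        400, data.frame(n_snps = c(6, 6), n_haplotypes = 3, fidelity = fid),
        coding = "haplotype_01", seed = seed
      )
      f <- cfhlc(s$data, cfhlc_config(window_size = 12, t = 0.6, seed = seed))
      tibble::tibble(fid = fid, trees = tree_count(f),
                     max_layer = max(f$nodes$layer))
    })
  })
  med <- res |>
    dplyr::group_by(fid) |>
    dplyr::summarise(trees = median(trees), ml = median(max_layer))
  expect_true(all(diff(med$trees) <= 0))
  expect_true(all(diff(med$ml) >= 0))
})

test_that("learned clusters recover the generating partition", {
  # the learned grouping of SNPs is the partition induced by the forest's
  # trees: within-cluster LD is strong enough to agglomerate each true
  # cluster, while the moderate root coupling stays below the C gate
  f_true <- make_two_layer_forest(
    n_trees = 2, clusters_per_tree = 2, snps_per_cluster = 5,
    latent_card = 3, fidelity = 0.95, coding = "genotype_012"
  )
  truth <- rep(1:4, each = 5)
  aris <- vapply(1:10, function(seed) {
    sim <- sample_fhlcm(f_true, 2000, seed = seed)
    f <- cfhlc(sim$data, cfhlc_config(window_size = 20, t = 0.6, seed = seed))
    learned <- fhlcforest:::tree_assignment(f)[colnames(sim$data)]
    mclust::adjustedRandIndex(learned, truth)
  }, numeric(1))
  expect_gte(median(aris), 0.8)
})
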