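test_that("DRR and tree count follow the roots of the forest", {
  f <- toy_forest()
  # 7 observed markers; roots are H3_1 and isolated SNP7
  expect_equal(tree_count(f), 2L)
  expect_equal(dimension_reduction_rate(f), 2 / 7)
  pf <- forest_from_parent_map(random_parent_forest(5, 0))
  expect_equal(tree_count(pf), 5L)
  expect_equal(dimension_reduction_rate(pf), 1.0)
})

test_that("entropy compression rate matches hand-computable cases", {
  z <- rep(0:1, 30)
  set.seed(3)
  w <- sample(0:1, 60, replace = TRUE)
  d <- snp_matrix(cbind(a = z, b = z, c = w), coding = "haplotype_01")
  # all singletons: no compression
  expect_equal(entropy_compression_rate(list("a", "b", "c"), d), 1.0)
  # two identical markers in one cluster: H(X,X) = H(X) halves their term
  d2 <- snp_matrix(cbind(a = z, b = z), coding = "haplotype_01")
  expect_equal(entropy_compression_rate(list(c("a", "b")), d2), 0.5)
  expect_error(entropy_compression_rate(list("a"), d), "cover")
  const <- snp_matrix(cbind(a = rep(0L, 10)), coding = "haplotype_01")
  expect_error(entropy_compression_rate(list("a"), const), "constant")
})

test_that("ECR is at most 1 and reaches 1 only for independent clusters", {
  set.seed(19)
  for (rep in 1:10) {
    d <- snp_matrix(random_cat_matrix(150, 6, k = 2), coding = "haplotype_01")
    grouping <- split(colnames(d), rep(1:2, each = 3))
    ecr <- entropy_compression_rate(grouping, d)
    expect_lte(ecr, 1 + 1e-9)
    expect_gt(ecr, 0)
  }
})

test_that("MRCA levels match the toy tree's structure", {
  f <- toy_forest()
  m <- mrca_levels(f)
  expect_equal(m["SNP1", "SNP2"], 1L) # siblings under H1_1
  expect_equal(m["SNP3", "SNP4"], 1L)
  expect_equal(m["SNP1", "SNP6"], 2L) # through H2_1
  expect_equal(m["SNP1", "SNP3"], 3L) # through the root H3_1
  expect_equal(m["SNP5", "SNP2"], 2L)
  expect_true(is.na(m["SNP1", "SNP7"])) # different trees -> sentinel
  expect_equal(diag(m), setNames(rep(0L, 7), rownames(m)))
  expect_equal(unclass(m), t(unclass(m)), ignore_attr = TRUE)
})

test_that("MRCA agrees with brute-force LCA on random forests", {
  set.seed(23)
  for (rep in 1:15) {
    pf <- random_parent_forest(sample(4:12, 1), sample(1:6, 1))
    f <- forest_from_parent_map(pf)
    m <- mrca_levels(f)
    obs <- pf$obs
    for (a in obs) {
      for (b in obs) {
        if (a < b) {
          expect_identical(
            m[a, b],
            oracle_mrca_level(a, b, pf$parents, pf$layers)
          )
        }
      }
    }
  }
})

test_that("MRCA sentinel is written as N", {
  f <- toy_forest()
  tf <- tempfile(fileext = ".tsv")
  write_mrca_matrix(mrca_levels(f), tf)
  txt <- read.delim(tf, row.names = 1, check.names = FALSE,
                    colClasses = "character")
  expect_equal(txt["SNP1", "SNP7"], "N")
  expect_equal(txt["SNP1", "SNP2"], "1")
})

test_that("most common haplotypes implement minimal coverage", {
  one <- matrix(0L, 10, 3)
  expect_equal(most_common_haplotypes(one), 1L)
  four <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), 4, 2) # 4 equifrequent rows
  expect_equal(most_common_haplotypes(four, 0.75), 3L)
  freqs <- rbind(
    matrix(rep(c(0L, 0L), 5), ncol = 2, byrow = TRUE),
    matrix(rep(c(0L, 1L), 3), ncol = 2, byrow = TRUE),
    matrix(c(1L, 0L), ncol = 2),
    matrix(c(1L, 1L), ncol = 2)
  ) # frequencies 0.5, 0.3, 0.1, 0.1
  expect_equal(most_common_haplotypes(freqs, 0.75), 2L)
  expect_error(most_common_haplotypes(matrix(0L, 0, 2)), "empty")
})

test_that("haplotype diversity grows with subtree level on the toy forest", {
  f <- toy_forest()
  set.seed(2)
  d <- snp_matrix(random_cat_matrix(40, 7, k = 2), coding = "haplotype_01",
                  marker_names = paste0("SNP", 1:7))
  hd <- haplotype_diversity(f, d)
  expect_equal(nrow(hd), 4L)
  expect_equal(hd$n_leaves[hd$latent == "H3_1"], 6L)
  expect_true(all(hd$n_common_haplotypes >= 1L))
})

test_that("layer statistics count all nodes and average incoming edges", {
  f <- toy_forest()
  st <- layer_statistics(f)
  expect_equal(sum(st$n_variables), nrow(f$nodes))
  expect_equal(st$n_variables[st$layer == 0], 7L)
  expect_equal(st$mean_scaled_mi[st$layer == 1], mean(c(0.9, 0.85, 0.8, 0.8)))
  expect_equal(st$mean_scaled_mi[st$layer == 2], mean(c(0.6, 0.55, 0.55)))
  expect_true(is.na(st$mean_scaled_mi[st$layer == 0]))
  # no latent variables: one row for layer 0
  f0 <- forest_from_parent_map(random_parent_forest(4, 0))
  st0 <- layer_statistics(f0)
  expect_equal(nrow(st0), 1L)
  expect_equal(st0$n_variables, 4L)
})

test_that("r2-versus-MRCA table pairs markers with their LCA level", {
  f <- toy_forest()
  set.seed(4)
  d <- snp_matrix(random_cat_matrix(50, 7, k = 2), coding = "haplotype_01",
                  marker_names = paste0("SNP", 1:7))
  tab <- mrca_r2_table(f, d)
  expect_equal(nrow(tab), choose(7, 2))
  expect_true(all(tab$r2 >= 0 & tab$r2 <= 1))
  got <- tab$mrca_level[tab$marker_a == "SNP1" & tab$marker_b == "SNP2"]
  expect_equal(got, 1L)
})
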