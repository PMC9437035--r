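# Section weighting, normalization, replicate merging and group statistics.

two_slab_scaffold <- function(counts) {
  # stub scaffold whose AP slab shell counts equal `counts`
  stub_scaffold(i_ap = rep(seq_along(counts), counts),
                i_dv = 1L, i_ml = 1L, dims = c(length(counts), 1L, 1L))
}

test_that("uniform OMP and layer shares give unit weights", {
  sc <- two_slab_scaffold(c(3, 3, 3, 3))
  tab <- section_table(matrix(1, 2, 4, dimnames = list(c("a", "b"), NULL)),
                       omp = rep(7, 4), axis = "AP")
  w <- compute_section_weights(tab, sc)
  expect_equal(w$weights, rep(1, 4))
  expect_equal(sum(w$omp_share), 1)
  expect_equal(sum(w$layer_share), 1)
})

test_that("weights follow w = layer_share / omp_share with mean-1 rescale", {
  # p = (0.5, 0.5), l = (0.25, 0.75)  ->  w = (0.5, 1.5)
  sc <- two_slab_scaffold(c(1, 3))
  tab <- section_table(matrix(1, 2, 2, dimnames = list(c("a", "b"), NULL)),
                       omp = c(10, 10), axis = "AP")
  w <- compute_section_weights(tab, sc)
  expect_equal(w$omp_share, c(0.5, 0.5))
  expect_equal(w$layer_share, c(0.25, 0.75))
  expect_equal(w$weights, c(0.5, 1.5))
})

test_that("zero-OMP sections get zero weight and are flagged", {
  sc <- two_slab_scaffold(c(2, 2, 2))
  tab <- section_table(matrix(5, 2, 3, dimnames = list(c("a", "b"), NULL)),
                       omp = c(4, 0, 4), axis = "AP")
  w <- compute_section_weights(tab, sc)
  expect_equal(w$flagged, 2L)
  expect_equal(w$weights[2], 0)
  nm <- normalize_and_mean_position(tab, w, excluded = character(0))
  expect_true(all(nm$weighted[, 2] == 0))
  # all-zero OMP is fatal
  tab0 <- section_table(matrix(5, 2, 3, dimnames = list(c("a", "b"), NULL)),
                        omp = c(0, 0, 0), axis = "AP")
  expect_error(compute_section_weights(tab0, sc), "all-zero OMP")
})

test_that("min-max normalization and weighted mean position follow the rules", {
  sc <- two_slab_scaffold(c(1, 1, 1, 1))
  vals <- rbind(pointy = c(0, 0, 4, 0), two = c(1, 3, 0, 0))
  tab <- section_table(vals, omp = rep(1, 4), axis = "AP")
  w <- compute_section_weights(tab, sc)
  nm <- normalize_and_mean_position(tab, w, excluded = character(0))
  expect_equal(unname(nm$normalized["pointy", ]), c(0, 0, 1, 0))
  expect_equal(unname(nm$mean_position["pointy"]), 3)
  # weighted row (1, 3) at positions (1, 2): mean = (1*1 + 2*3) / 4 = 1.75
  expect_equal(unname(nm$mean_position["two"]), (1 * 1 + 2 * 3 + 0 + 0) / 4)
})

test_that("flat rows are zeroed and excluded receptors dropped", {
  sc <- two_slab_scaffold(c(1, 1, 1))
  vals <- rbind(flat = c(2, 2, 2), ok = c(0, 5, 0), Olfr32 = c(1, 2, 3))
  tab <- section_table(vals, omp = rep(1, 3), axis = "AP")
  w <- compute_section_weights(tab, sc)
  nm <- normalize_and_mean_position(tab, w)
  expect_false("Olfr32" %in% rownames(nm$normalized))
  expect_equal(nm$flat_rows, "flat")
  expect_true(all(nm$normalized["flat", ] == 0))
  expect_true(is.na(nm$mean_position["flat"]))
  expect_setequal(default_excluded_receptors(),
                  c("Olfr287", "Olfr32", "Olfr361", "Olfr1033"))
})

test_that("min-max normalization is idempotent on non-flat rows", {
  set.seed(11)
  sc <- two_slab_scaffold(rep(1, 6))
  vals <- matrix(runif(30), 5, 6,
                 dimnames = list(sprintf("r%d", 1:5), NULL))
  tab <- section_table(vals, omp = rep(1, 6), axis = "AP")
  w <- compute_section_weights(tab, sc)
  nm1 <- normalize_and_mean_position(tab, w, excluded = character(0))
  tab2 <- section_table(nm1$normalized, omp = rep(1, 6), axis = "AP")
  nm2 <- normalize_and_mean_position(tab2, w, excluded = character(0))
  expect_equal(nm2$normalized, nm1$normalized)
})

test_that("weighted mean position is invariant to row rescaling", {
  sc <- two_slab_scaffold(rep(1, 5))
  vals <- rbind(a = c(0, 2, 5, 1, 0), b = 10 * c(0, 2, 5, 1, 0))
  tab <- section_table(vals, omp = rep(1, 5), axis = "AP")
  w <- compute_section_weights(tab, sc)
  nm <- normalize_and_mean_position(tab, w, excluded = character(0))
  expect_equal(unname(nm$mean_position["a"]), unname(nm$mean_position["b"]))
})

test_that("replicate merging is the cellwise median with renormalization", {
  sc <- two_slab_scaffold(c(1, 1))
  mk <- function(vals, id) {
    tab <- section_table(vals, omp = c(1, 1), axis = "AP", replicate_id = id)
    normalize_and_mean_position(tab, compute_section_weights(tab, sc),
                                excluded = character(0))
  }
  r1 <- mk(rbind(x = c(0, 1)), "rep1")
  r2 <- mk(rbind(x = c(0, 1)), "rep2")
  r3 <- mk(rbind(x = c(1, 0)), "rep3")
  merged <- merge_replicates(list(r1, r2, r3))
  expect_equal(unname(merged$normalized["x", ]), c(0, 1))
  # three identical replicates merge to themselves
  same <- merge_replicates(list(r1, r1, r1))
  expect_equal(same$normalized, r1$normalized)
  # mismatched shapes name the offending replicate
  r4 <- mk(rbind(y = c(0, 1)), "odd-one")
  expect_error(merge_replicates(list(r1, r4)), "odd-one")
  expect_error(merge_replicates(list(r1)), "at least two")
})

test_that("group comparisons: exact enumeration, ties, and Spearman", {
  pos <- c(a = 1, b = 2, c = 3, d = 4, e = 5, f = 6)
  groups <- c(a = "g1", b = "g1", c = "g1", d = "g2", e = "g2", f = "g2")
  out <- group_position_comparison(pos, groups,
                                   contrasts = list(c("g1", "g2")))
  expect_equal(out$tests$p, 0.1)       # 2 / choose(6, 3), two-tailed
  expect_equal(out$tests$method, "exact")
  # identical groups: no shift
  pos2 <- c(a = 1, b = 2, c = 3, d = 1, e = 2, f = 3)
  out2 <- group_position_comparison(pos2, groups,
                                    contrasts = list(c("g1", "g2")))
  expect_equal(out2$tests$p, 1)
  # perfectly concordant reference index
  out3 <- group_position_comparison(pos, groups, contrasts = list(),
                                    reference_index = pos * 3 + 1)
  expect_equal(out3$spearman$rho, 1)
  # empty group is fatal
  expect_error(group_position_comparison(pos, groups,
                                         contrasts = list(c("g1", "zzz"))),
               "empty group")
})

test_that("exact Mann-Whitney agrees with wilcox.test and its normal path", {
  set.seed(21)
  for (rep in 1:10) {
    x <- rnorm(8); y <- rnorm(8)
    exact <- mwu_test(x, y)
    ref <- wilcox.test(x, y, exact = TRUE, correct = TRUE)
    expect_equal(exact$U, unname(ref$statistic))
    expect_equal(exact$p, ref$p.value, tolerance = 1e-10)
    approx <- mwu_test(x, y, exact_max = 0)
    ref2 <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    expect_equal(approx$p, ref2$p.value, tolerance = 1e-10)
  }
  # enumeration vs the large-sample path, exhaustively over every achievable
  # U at n1 = n2 = 8: the worst case is 0.0109 (8 of 65 U values exceed
  # 0.01, all near |U - mu| = 8; verified against pwilcox), so assert the
  # exhaustive bound 0.011 plus near-universal agreement at 0.01
  diffs <- local({
    idx <- utils::combn(16, 8)
    u_all <- colSums(matrix((1:16)[idx], nrow = 8)) - 8 * 9 / 2
    mu <- 32; sigma <- sqrt(8 * 8 * 17 / 12)
    vapply(0:64, function(u) {
      exact <- mean(abs(u_all - mu) >= abs(u - mu) - 1e-12)
      z <- u - mu; z <- (z - sign(z) * 0.5) / sigma
      norm <- min(1, 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE)))
      abs(exact - norm)
    }, numeric(1))
  })
  expect_gte(mean(diffs < 0.01), 0.85)
  expect_lt(max(diffs), 0.011)
})
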