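# Sequence-position analyses: identity, Grantham distances, permutation
# test, boosted-tree regression.

test_that("percent identity: examples, symmetry, range, errors", {
  expect_equal(pairwise_identity("ACDEFGHIKL", "ACDEFGHIKL"), 100)
  expect_equal(pairwise_identity("ACDEFGHIKL", "ACDEFGHIKV"), 90)
  expect_error(pairwise_identity("", "ACD"), "non-empty")
  set.seed(5)
  for (k in 1:15) {
    a <- random_protein(sample(6:15, 1))
    b <- random_protein(sample(6:15, 1))
    ab <- pairwise_identity(a, b)
    expect_equal(ab, pairwise_identity(b, a))
    expect_gte(ab, 0); expect_lte(ab, 100)
  }
})

test_that("identity matches a brute-force affine-gap global aligner", {
  set.seed(6)
  for (k in 1:100) {
    a <- random_protein(sample(5:12, 1))
    b <- random_protein(sample(5:12, 1))
    o <- oracle_global_align(a, b)
    expect_true(any(abs(o$identities - pairwise_identity(a, b)) < 1e-6),
                info = paste(a, b))
  }
})

test_that("Grantham distances: table values, symmetry, identity, errors", {
  expect_equal(grantham_distance("L", "I"), 5)
  expect_equal(grantham_distance("W", "C"), 215)   # table maximum
  tab <- grantham_table()
  aa <- rownames(tab$matrix)
  for (a in aa) expect_equal(grantham_distance(a, a), 0)
  pairs <- utils::combn(aa, 2)
  d_ab <- grantham_distance(pairs[1, ], pairs[2, ])
  d_ba <- grantham_distance(pairs[2, ], pairs[1, ])
  expect_equal(d_ab, d_ba)                          # all 190 ordered pairs
  expect_equal(max(tab$matrix), 215)
  expect_error(grantham_distance("L", "-"), "gap or unknown")
  expect_error(grantham_distance("B", "A"), "gap or unknown")
})

test_that("the published table round-trips with the distance formula", {
  # printed integers agree with the formula within rounding, except for the
  # known printing-era deviations of the 1974 table
  aa <- rownames(grantham_table()$matrix)
  pairs <- utils::combn(aa, 2)
  printed <- grantham_distance(pairs[1, ], pairs[2, ])
  formula <- glomap:::grantham_formula(pairs[1, ], pairs[2, ])
  dev <- abs(printed - formula)
  expect_lte(sum(dev > 1), 3)
  expect_lt(max(dev), 10)
  expect_equal(mean(formula), 100, tolerance = 0.01) # rho normalizes the mean
})

test_that("identity-distance analysis separates constructed strata", {
  # identity >= 40 pairs all at distance 1, the rest at distance 10
  set.seed(7)
  n <- 20
  records <- data.frame(
    id_a = sprintf("a%02d", 1:n), id_b = sprintf("b%02d", 1:n),
    pct_identity = rep(c(60, 20), each = n / 2),
    d_ap = rep(c(1, 10), each = n / 2), d_dv = NA_real_, d_ml = NA_real_)
  strata <- stats::setNames(rep("ClassII_ventral", 2 * n),
                            c(records$id_a, records$id_b))
  out <- identity_vs_distance_analysis(records, strata)
  row <- out[out$axis == "AP" & grepl(">=40", out$comparison), ][1, ]
  expect_lt(row$p, 0.05)
  # all-equal distances: p = 1
  rec2 <- records; rec2$d_ap <- 1
  out2 <- identity_vs_distance_analysis(rec2, strata)
  expect_equal(out2[out2$axis == "AP" & grepl(">=40", out2$comparison), "p"][1], 1)
  # empty bins reported as NA, not fatal
  expect_true(any(is.na(out$p)))
})

test_that("pairwise records cover all pairs with per-axis distances", {
  seqs <- c(r1 = "ACDEFGHIKL", r2 = "ACDEFGHIKV", r3 = "WWDDFGHIKL")
  pos <- matrix(c(1, 3, 6, 2, 2, 2), 3, 2,
                dimnames = list(names(seqs), c("AP", "DV")))
  rec <- pairwise_records(seqs, pos)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$d_ap[rec$id_a == "r1" & rec$id_b == "r3"], 5)
  expect_true(all(is.na(rec$d_ml)))
  expect_equal(rec$pct_identity[1], 90)
})

test_that("residue association test: structure, errors, determinism", {
  recs <- make_receptors(40, seed = 12)
  aln <- generate_aligned_sequences(recs, seq_len(40), n_columns = 20,
                                    effect = 0, seed = 12)
  expect_error(residue_association_test(aln, recs$id[1], recs$id),
               "at least 2")
  r1 <- residue_association_test(aln, recs$id[1:20], recs$id, n_perm = 100,
                                 seed = 3)
  r2 <- residue_association_test(aln, recs$id[1:20], recs$id, n_perm = 100,
                                 seed = 3)
  expect_identical(r1, r2)
  expect_true(all(r1$p >= 0 & r1$p <= 1, na.rm = TRUE))
  expect_true(all(r1$q >= r1$p - 1e-12, na.rm = TRUE))
  # columns exceeding the gap cap are excluded and carry no p
  gapped <- aln$alignment
  substr(gapped[1:10], 5, 5) <- "-"     # 25% gaps in column 5
  r3 <- residue_association_test(gapped, recs$id[1:20], recs$id,
                                 n_perm = 50, max_gap_fraction = 0.10,
                                 seed = 3)
  expect_true(r3$excluded[5])
  expect_true(is.na(r3$p[5]))
})

test_that("null permutation p-values are not anti-conservative", {
  recs <- make_receptors(60, seed = 13)
  fr <- vapply(1:6, function(sd) {
    aln <- generate_aligned_sequences(recs, seq_len(60), n_columns = 25,
                                      effect = 0, seed = sd)
    r <- residue_association_test(aln, recs$id[1:30], recs$id, n_perm = 200,
                                  seed = sd)
    mean(r$q <= 0.05, na.rm = TRUE)
  }, numeric(1))
  expect_lte(mean(fr), 0.05)
})

test_that("planted signal columns are detected with high power", {
  hits <- vapply(1:4, function(sd) {
    recs <- make_receptors(120, seed = sd)
    pos <- stats::setNames(seq_len(120), recs$id)
    aln <- generate_aligned_sequences(recs, pos, n_columns = 30, effect = 3,
                                      seed = sd)
    ant <- select_extreme_receptors(pos, 0.3, "anterior")
    r <- residue_association_test(aln, ant, recs$id, n_perm = 500, seed = sd)
    mean(r$q[aln$signal_columns] <= 0.05)
  }, numeric(1))
  expect_gte(mean(hits), 0.8)
})

test_that("BH correction matches a brute-force implementation", {
  set.seed(14)
  for (k in 1:20) {
    p <- runif(sample(3:50, 1))
    expect_equal(stats::p.adjust(p, "BH"), oracle_bh(p))
  }
})

test_that("extreme-receptor selection takes the stated quantile cuts", {
  pos <- stats::setNames(1:40, sprintf("r%02d", 1:40))
  ant <- select_extreme_receptors(pos, 0.275, "anterior")
  expect_equal(length(ant), 11)
  expect_true(all(pos[ant] <= 11))
  post <- select_extreme_receptors(pos, 0.20, "posterior")
  expect_true(all(pos[post] >= 33))
})

test_that("position regressor recovers a planted signal and rejects noise", {
  recs <- make_receptors(100, seed = 9)
  aln <- generate_aligned_sequences(recs, rnorm(100), n_columns = 25,
                                    effect = 0, seed = 9)
  tab <- grantham_table()$properties
  mat <- do.call(rbind, strsplit(aln$alignment, ""))
  y <- tab$polarity[mat[, 7]] * 2 + 3     # noiseless function of one column
  names(y) <- recs$id
  fit <- fit_position_regressor(aln, y, regressor_config(n_trees = 300,
                                                         seed = 1))
  expect_gte(fit$r_squared, 0.9)
  expect_true(any(grepl("col007", fit$importance$Feature[1:3])))
  expect_error(fit_position_regressor(aln, y[1:10]), ">= 20")
  cfg <- regressor_config()
  expect_equal(cfg$n_trees, 1000)
  expect_equal(cfg$cv_folds, 10)
  expect_equal(cfg$holdout_fraction, 0.1)
})

test_that("permuted positions yield no predictive power", {
  recs <- make_receptors(200, seed = 15)
  aln <- generate_aligned_sequences(recs, rnorm(200), n_columns = 25,
                                    effect = 0, seed = 15)
  r2 <- vapply(1:10, function(sd) {
    set.seed(2000 + sd)
    y <- stats::setNames(rnorm(200), recs$id)
    fit_position_regressor(aln, y, regressor_config(n_trees = 200,
                                                    seed = sd))$r_squared
  }, numeric(1))
  expect_gte(mean(r2 <= 0.1), 0.9)
})
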