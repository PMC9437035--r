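# Multinomial-Dirichlet posterior sampling, voxel projection, assignment.

test_that("posterior compositions follow the conjugate closed form", {
  m <- matrix(c(10, 0, 0), 3, 1, dimnames = list(c("a", "b", "c"), NULL))
  ps <- sample_posterior_compositions(m, alpha = 0.65, n_samples = 1000,
                                      seed = 1)
  mu <- 10.65 / 11.95
  mcse <- sqrt(mu * (1 - mu) / (11.95 + 1)) / sqrt(1000)
  expect_lt(abs(mean(ps$samples[1, 1, ]) - mu), 3 * mcse)
  # all-zero counts: symmetric prior, mean 1/3 each
  z <- matrix(0, 3, 1, dimnames = list(c("a", "b", "c"), NULL))
  pz <- sample_posterior_compositions(z, alpha = 0.65, n_samples = 2000,
                                      seed = 2)
  expect_equal(rowMeans(pz$samples[, 1, ]), c(a = 1, b = 1, c = 1) / 3,
               tolerance = 0.03)
})

test_that("posterior samples are simplex-valued and seed-reproducible", {
  set.seed(3)
  m <- matrix(rpois(20, 40), 4, 5, dimnames = list(letters[1:4], NULL))
  p1 <- sample_posterior_compositions(m, n_samples = 50, seed = 9)
  p2 <- sample_posterior_compositions(m, n_samples = 50, seed = 9)
  expect_identical(p1$samples, p2$samples)
  sums <- apply(p1$samples, c(2, 3), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_error(sample_posterior_compositions(m[1, , drop = FALSE]),
               "at least 2")
  expect_error(sample_posterior_compositions(m, alpha = 0), "positive")
})

test_that("Monte-Carlo posterior means converge at the Dirichlet rate", {
  set.seed(4)
  for (K in 2:5) {
    counts <- matrix(rpois(K, 15), K, 1,
                     dimnames = list(sprintf("r%d", 1:K), NULL))
    ps <- sample_posterior_compositions(counts, alpha = 0.65,
                                        n_samples = 2000, seed = K)
    a0 <- sum(counts) + K * 0.65
    mu <- (counts[, 1] + 0.65) / a0
    mcse <- sqrt(mu * (1 - mu) / (a0 + 1)) / sqrt(2000)
    expect_true(all(abs(rowMeans(ps$samples[, 1, ]) - mu) < 4 * mcse))
  }
})

test_that("voxel projection weights sections by inverse shell counts", {
  # two AP slabs with 2 and 4 shell voxels; DV and ML single slabs
  sc <- stub_scaffold(i_ap = c(1, 1, 2, 2, 2, 2), i_dv = 1,
                      i_ml = c(1, 2, 1, 2, 3, 4), dims = c(2, 1, 4))
  c_equal <- matrix(c(0.3, 0.7, 0.3, 0.7), 2, 2,
                    dimnames = list(c("a", "b"), NULL))
  cm <- matrix(c(0.3, 0.7), 2, 1, dimnames = list(c("a", "b"), NULL))
  cml <- matrix(c(0.3, 0.7), 2, 4, dimnames = list(c("a", "b"), NULL))
  post <- list(AP = stub_posterior(c_equal), DV = stub_posterior(cm),
               ML = stub_posterior(cml))
  field <- project_to_voxels(post, sc)
  # equal compositions in every intersecting section: each voxel carries the
  # common composition regardless of the 1/V weights (scale invariance)
  for (v in seq_len(6)) {
    expect_equal(unname(field$medians[, v]), c(0.3, 0.7), tolerance = 1e-12)
  }
  # unequal compositions: voxel composition proportional to c1/V1 + ...
  c_uneq <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2,
                   dimnames = list(c("a", "b"), NULL))
  post$AP <- stub_posterior(c_uneq)
  f2 <- project_to_voxels(post, sc)
  # voxel 1 lies in AP slab 1 (V=2), DV slab 1 (V=6), ML slab 1 (V=2)
  expected <- c(0.9, 0.1) / 2 + c(0.3, 0.7) / 6 + c(0.3, 0.7) / 2
  expected <- expected / sum(expected)
  expect_equal(unname(f2$medians[, 1]), expected, tolerance = 1e-12)
})

test_that("a receptor confined to one slab per axis peaks at the intersection", {
  sc <- build_scaffold(c(6, 6, 6))
  S <- 6
  mk <- function(slab) {
    comp <- matrix(0.1 / (S - 1), 2, S, dimnames = list(c("hot", "bg"), NULL))
    comp[2, ] <- 1 - comp[1, ]
    comp[1, slab] <- 0.9
    comp[2, slab] <- 0.1
    stub_posterior(comp)
  }
  field <- project_to_voxels(list(AP = mk(2), DV = mk(3), ML = mk(5)), sc)
  vox <- field$voxels
  best <- which.max(field$medians["hot", ])
  expect_equal(unname(unlist(vox[best, c("i_ap", "i_dv", "i_ml")])),
               c(2, 3, 5))
})

test_that("assignment on a bare field: planted clusters, pairing, tau filter", {
  sc <- build_scaffold(c(10, 9, 9))
  vox <- sc$voxels
  K <- 2
  med <- matrix(1e-6, K, nrow(vox), dimnames = list(c("single", "pair"), NULL))
  # one high lateral cluster for "single"
  lat_idx <- which(vox$side == "lateral" & vox$i_ap == 4 & vox$i_dv == 5)
  med[1, lat_idx] <- 0.05 * 0.9^(seq_along(lat_idx) - 1)
  # mirror clusters 3 slabs apart for "pair"
  la <- which(vox$side == "lateral" & vox$i_ap == 3 & vox$i_dv == 5)[1]
  me <- which(vox$side == "medial" & vox$i_ap == 6 & vox$i_dv == 5)[1]
  med[2, la] <- 0.06
  med[2, me] <- 0.055
  field <- structure(list(medians = med, voxels = vox, axis_medians = NULL,
                          n_samples = 1), class = "glom_field")
  pairs <- assign_glomeruli(field, sc, dv_mean = c(single = 5, pair = 5))
  a1 <- pairs$assignments$single
  expect_equal(a1$lateral$best_voxel, lat_idx[which.max(med[1, lat_idx])])
  expect_null(a1$medial)               # nothing comparable on the medial side
  a2 <- pairs$assignments$pair
  expect_equal(vox$i_ap[a2$medial$best_voxel], 6)
  expect_equal(vox$i_ap[a2$lateral$best_voxel], 3)
  expect_gt(vox$i_ap[a2$medial$best_voxel], vox$i_ap[a2$lateral$best_voxel])
  expect_true(all(as.data.frame(pairs)$passed_filter))
})

test_that("the tau filter is monotone and catches sub-threshold receptors", {
  sc <- build_scaffold(c(8, 8, 8))
  vox <- sc$voxels
  med <- matrix(0, 3, nrow(vox),
                dimnames = list(c("strong", "weak", "zero"), NULL))
  med[1, which(vox$side == "lateral")[1]] <- 0.02
  med[2, which(vox$side == "lateral")[2]] <- 0.0003
  field <- structure(list(medians = med, voxels = vox, axis_medians = NULL,
                          n_samples = 1), class = "glom_field")
  pairs <- assign_glomeruli(field, sc)
  expect_true(pairs$assignments$strong$passed_filter)
  expect_false(pairs$assignments$weak$passed_filter)   # 0.0003 < 5e-4
  expect_false(pairs$assignments$zero$passed_filter)
  n_pass <- vapply(c(1e-5, 1e-4, 5e-4, 1e-2, 0.5), function(tau) {
    p <- assign_glomeruli(field, sc, tau = tau)
    sum(vapply(p$assignments, `[[`, logical(1), "passed_filter"))
  }, numeric(1))
  expect_true(all(diff(n_pass) <= 0))
})

test_that("evaluation distances, baselines and replicate variance", {
  # disjoint single voxels (1,1,1) and (4,5,1) at 100 um voxels: 500 um
  a <- data.frame(i_ap = 1, i_dv = 1, i_ml = 1)
  b <- data.frame(i_ap = 4, i_dv = 5, i_ml = 1)
  expect_equal(glomap:::min_voxel_distance(a, b, 100), 500)
  expect_equal(glomap:::min_voxel_distance(a, a, 100), 0)

  # synthetic pairs object with known clusters
  sc <- build_scaffold(c(8, 8, 8))
  vox <- sc$voxels
  ids <- sprintf("r%02d", 1:12)
  med <- matrix(0, 12, nrow(vox), dimnames = list(ids, NULL))
  lat_all <- which(vox$side == "lateral")
  for (i in seq_along(ids)) med[i, lat_all[i]] <- 0.05
  field <- structure(list(medians = med, voxels = vox, axis_medians = NULL,
                          n_samples = 1), class = "glom_field")
  pairs <- assign_glomeruli(field, sc)
  recs <- data.frame(id = ids, oe_zone_index = rep(0.1, 12))
  refs <- data.frame(receptor_id = "r01", i_ap = vox$i_ap[lat_all[1]],
                     i_dv = vox$i_dv[lat_all[1]], i_ml = vox$i_ml[lat_all[1]])
  ev <- suppressWarnings(evaluate_assignments(pairs, refs, recs,
                                              n_random = 50, seed = 1))
  expect_equal(ev$per_reference$distance_um, 0)      # overlap -> 0
  expect_lt(ev$per_reference$n_baseline, 50)          # fewer eligible than 50
  expect_warning(evaluate_assignments(pairs, refs, recs, n_random = 50,
                                      seed = 1), "eligible")

  rv <- replicate_variance(pairs, pairs)
  expect_equal(unname(rv$median_um["d3d"]), 0)
})
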