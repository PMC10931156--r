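test_that("LOD is the smallest concentration above blank mean + 3 sigma", {
  s <- dose_response_series("trans-2-hexenal", c(5, 10, 20), c(48, 52, 60),
                            blank_mean = 47.75, blank_sd = 2)
  lod <- estimate_lod(s)
  expect_equal(as.numeric(lod), 20)
  expect_equal(attr(lod, "threshold"), 53.75)
  # not reached
  s2 <- dose_response_series("ethanol", c(5, 10), c(48, 50))
  expect_true(is.na(estimate_lod(s2)))
  # unsorted concentrations error
  s3 <- s; s3$concentrations <- c(10, 5, 20)
  expect_error(estimate_lod(s3), "sorted")
})

test_that("LOD is monotone non-decreasing in the blank sd", {
  s <- dose_response_series("ethanol", c(1, 2, 5, 10, 20, 50),
                            c(48, 50, 54, 60, 70, 90), blank_mean = 47.75)
  sds <- seq(0, 10, by = 0.5)
  lods <- vapply(sds, function(bs) {
    v <- as.numeric(estimate_lod(s, blank_sd = bs))
    if (is.na(v)) Inf else v
  }, numeric(1))
  expect_true(all(diff(lods) >= 0))
})

test_that("per-dye LOD uses the requested spot's ED column", {
  per_spot <- matrix(0.5, 3, 25)
  per_spot[, 9] <- c(1, 4, 9)
  s <- dose_response_series("ethanol", c(10, 50, 100), c(40, 50, 60),
                            per_spot_ed = per_spot)
  lod <- estimate_lod(s, blank_mean = 1, blank_sd = 0.5, spot = 9)
  expect_equal(as.numeric(lod), 50)   # threshold 2.5, first crossing at 4
  expect_true(is.na(estimate_lod(s, blank_mean = 1, blank_sd = 0.5,
                                 spot = 2)))
})

test_that("sensitive-dye ranking recovers a planted order", {
  per_spot <- matrix(0.1, 2, 25)
  per_spot[2, c(17, 4, 9)] <- c(30, 20, 10)  # planted top-3
  s <- dose_response_series("ethanol", c(10, 100), c(5, 65),
                            per_spot_ed = per_spot)
  expect_equal(rank_sensitive_dyes(s, 3), c(17L, 4L, 9L))
  # k = 25 returns a permutation of all dye ids
  expect_setequal(rank_sensitive_dyes(s, 25), 1:25)
  # ties break toward the lower dye id
  per_spot2 <- matrix(1, 2, 25)
  s2 <- dose_response_series("ethanol", c(10, 100), c(5, 65),
                             per_spot_ed = per_spot2)
  expect_equal(rank_sensitive_dyes(s2, 3), c(1L, 2L, 3L))
})

test_that("reference ranges are class-wise min-max intervals", {
  rr <- build_reference_ranges(list(a = c(50, 60, 55), b = c(70, 80)))
  expect_equal(rr$lo, c(50, 70))
  expect_equal(rr$hi, c(60, 80))
  # degenerate single-sample class
  rr1 <- build_reference_ranges(list(a = 42))
  expect_equal(c(rr1$lo, rr1$hi), c(42, 42))
  expect_error(build_reference_ranges(list(a = numeric(0))), "at least one")
})

test_that("ED classification picks the containing interval", {
  rr <- build_reference_ranges(list(lo = c(10, 20), mid = c(30, 60),
                                    wide = c(25, 90)))
  out <- classify_by_ed(c(15, 40, 95, 70), rr)
  expect_equal(as.character(out), c("lo", "mid", "out_of_range", "wide"))
  expect_equal(attr(out, "ambiguous"), c(FALSE, TRUE, FALSE, FALSE))
  # disjoint ranges classify training samples exactly
  samples <- list(a = c(1, 5), b = c(10, 14), c = c(20, 30))
  rr2 <- build_reference_ranges(samples)
  for (cls in names(samples))
    expect_true(all(classify_by_ed(samples[[cls]], rr2) == cls))
})

test_that("Ward linkage merges duplicates first and separates far pairs", {
  set.seed(2)
  X <- matrix(rnorm(4 * 25), 4)
  X <- rbind(X, X[2, ])  # duplicate row
  lk <- hca_ward(X)
  expect_equal(lk$n, 5L)
  expect_equal(nrow(lk$merge), 4L)
  expect_equal(lk$height[1], 0)
  expect_setequal(abs(lk$merge[1, ]), c(2, 5))
  # 4-point toy: two tight pairs far apart -> top split separates the pairs
  Y <- rbind(c(0, 0), c(0.1, 0), c(10, 0), c(10.1, 0))
  Y <- cbind(Y, matrix(0, 4, 23))
  cl <- cut_linkage(hca_ward(Y), 2)
  expect_equal(cl[1], cl[2])
  expect_equal(cl[3], cl[4])
  expect_false(cl[1] == cl[3])
  expect_error(hca_ward(matrix(c(1, NA, 2, 3), 2)), "non-finite")
  expect_error(hca_ward(X[1, , drop = FALSE]), "at least 2")
})

test_that("Ward linkage equals the brute-force minimum-variance oracle", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(4:7, 1)
    X <- matrix(rnorm(n * 3), n)
    lk <- hca_ward(X)
    bf <- brute_force_ward(X)
    expect_equal(lk$height, bf$heights, tolerance = 1e-8)
    for (s in seq_len(n - 1))
      expect_true(same_partition(cutree(lk$hclust, n - s),
                                 bf$partitions[[s]]))
  }
})

test_that("the VOC ED matrix is 27 x 25 and clusters perfectly at k = 27", {
  em <- simulate_voc_ed_matrix(1)
  expect_equal(dim(em$means), c(27L, 25L))
  expect_equal(dim(em$replicates), c(81L, 25L))
  expect_equal(length(unique(em$condition)), 27L)
  # separation really is >= 10x the noise sd
  expect_gte(min(dist(em$true_means)) / em$noise_sd, 10 - 1e-9)
  lk <- hca_ward(em$means)
  expect_equal(cluster_success_rate(lk, em$condition, 27), 1)
  # replicate-level clustering keeps conditions pure
  lkr <- hca_ward(em$replicates)
  expect_equal(cluster_success_rate(lkr, em$rep_condition, 27), 1)
})

test_that("cluster success rate handles the degenerate cuts", {
  X <- matrix(rnorm(6 * 25), 6)
  lk <- hca_ward(X)
  expect_equal(cluster_success_rate(lk, rep("x", 6), 1), 1)
  expect_equal(cluster_success_rate(lk, letters[1:6], 6), 1)
  # an impure cut scores the impure cluster members as failures
  Y <- rbind(c(0, 0), c(0.1, 0), c(10, 0), c(10.1, 0))
  lk2 <- hca_ward(cbind(Y, matrix(0, 4, 23)))
  expect_equal(cluster_success_rate(lk2, c("a", "b", "c", "c"), 2), 0.5)
})

test_that("measured LOD from rendered images matches the printed-rule arithmetic", {
  lib <- test_library(1)
  pr <- generate_dose_response_images(lib, "trans-2-hexenal",
                                      c(0, 1, 2, 5, 10, 25),
                                      replicates = 3, seed = 9)
  s <- measure_dose_response(pr)
  lod <- estimate_lod(s, blank_mean = 47.75, blank_sd = 2)
  above <- s$concentrations[s$total_ed > 53.75]
  expect_equal(as.numeric(lod), min(above))
})
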