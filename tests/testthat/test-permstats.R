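# GLM contrasts, cluster and max-t permutation tests, Bonferroni, GESD and
# group contrasts with covariates.

test_that("first_level_contrast equals OLS / paired-difference identities", {
  set.seed(50)
  # paired two-condition design with contrast (1, -1)
  vals <- matrix(rnorm(2 * 10), 2, 10)
  X <- rbind(c(1, 0), c(0, 1))
  est <- first_level_contrast(vals, X, c(1, -1))
  expect_equal(est, vals[1, ] - vals[2, ], tolerance = 1e-12)
  # intercept-only design returns the mean
  Xi <- matrix(1, 5, 1)
  v5 <- matrix(rnorm(5 * 3), 5, 3)
  expect_equal(first_level_contrast(v5, Xi, 1), colMeans(v5), tolerance = 1e-12)
  # random design matches the normal equations
  Xr <- cbind(1, rnorm(20), rnorm(20))
  yr <- matrix(rnorm(20 * 4), 20, 4)
  cr <- c(0, 1, -1)
  beta <- solve(crossprod(Xr), crossprod(Xr, yr))
  expect_equal(first_level_contrast(yr, Xr, cr), drop(cr %*% beta),
               tolerance = 1e-10)
  # rank deficiency is reported
  Xd <- cbind(1, rnorm(10), 0)
  expect_error(first_level_contrast(matrix(rnorm(10), 10, 1), Xd, c(1, 0, 0)),
               "rank")
})

test_that("cluster_permutation_test finds planted band effects", {
  n <- 24; fqs <- seq(1, 45, by = 1)
  hits <- vapply(1:20, function(r) {
    set.seed(60 + r)
    M <- matrix(rnorm(n * length(fqs)), n)
    M[, fqs >= 13 & fqs <= 30] <- M[, fqs >= 13 & fqs <= 30] + 1
    res <- cluster_permutation_test(M, freqs = fqs, n_perm = 200, seed = r)
    sig <- res$clusters[res$clusters$p_value < 0.05 & res$clusters$mean_t > 0, ]
    nrow(sig) > 0 && any(sig$freq_lo <= 30 & sig$freq_hi >= 13) &&
      any(sig$peak_freq >= 13 & sig$peak_freq <= 30)
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("cluster_permutation_test edge behaviour", {
  # identically zero contrasts yield no clusters
  M0 <- matrix(0, 10, 20)
  res0 <- cluster_permutation_test(M0, n_perm = 50, seed = 1)
  expect_equal(nrow(res0$clusters), 0)
  # p-values live in [1/(n_perm+1), 1] and are seed-reproducible
  set.seed(62)
  M <- matrix(rnorm(12 * 30), 12)
  r1 <- cluster_permutation_test(M, n_perm = 100, seed = 7)
  r2 <- cluster_permutation_test(M, n_perm = 100, seed = 7)
  expect_identical(r1$clusters, r2$clusters)
  if (nrow(r1$clusters) > 0) {
    expect_true(all(r1$clusters$p_value >= 1 / 101))
    expect_true(all(r1$clusters$p_value <= 1))
  }
  # frequency axis relabelling moves cluster extents with the axis
  fq <- seq(2, 60, by = 2)[1:30]
  r3 <- cluster_permutation_test(M, freqs = fq, n_perm = 100, seed = 7)
  expect_equal(r3$clusters$mass, r1$clusters$mass)
  if (nrow(r1$clusters)) {
    idx <- match(r1$clusters$freq_lo, seq_len(30))
    expect_equal(r3$clusters$freq_lo, fq[idx])
  }
})

test_that("max_t_permutation is selective and reduces to a sign-flip test", {
  hits <- vapply(1:20, function(r) {
    set.seed(70 + r)
    M <- matrix(rnorm(20 * 5), 20, 5)
    M[, 3] <- M[, 3] + 1.5
    res <- max_t_permutation(M, n_perm = 200, seed = r)
    sig <- which(res$p_corrected < 0.05)
    identical(sig, 3L)
  }, TRUE)
  expect_gte(mean(hits), 0.9)

  # K = 1 equals an ordinary sign-flip t-test within Monte-Carlo error
  set.seed(71)
  x <- rnorm(15, 0.4)
  res1 <- max_t_permutation(matrix(x, ncol = 1), n_perm = 2000, seed = 3)
  tobs <- abs(mean(x) / (sd(x) / sqrt(15)))
  signs <- matrix(sample(c(-1, 1), 2000 * 15, replace = TRUE), 2000)
  tnull <- apply(signs, 1, function(s) {
    xs <- x * s; abs(mean(xs) / (sd(xs) / sqrt(15)))
  })
  p_ref <- (1 + sum(tnull >= tobs)) / 2001
  expect_lt(abs(res1$p_corrected - p_ref), 0.03)
  # corrected p dominates the uncorrected per-state p
  set.seed(72)
  M <- matrix(rnorm(12 * 4, 0.3), 12, 4)
  corr <- max_t_permutation(M, n_perm = 500, seed = 4)$p_corrected
  for (k in 1:4) {
    unc <- max_t_permutation(M[, k, drop = FALSE], n_perm = 500, seed = 4)$p_corrected
    expect_gte(corr[k] + 1e-12, unc)
  }
  expect_error(max_t_permutation(cbind(rep(1, 5), rnorm(5))), "constant")
})

test_that("bonferroni_threshold arithmetic", {
  expect_equal(bonferroni_threshold(0.05, 8), 0.00625)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 4), 0.0025)
  expect_error(bonferroni_threshold(0.05, 0))
})

test_that("gesd matches the textbook recursion and flags planted outliers", {
  set.seed(80)
  x <- c(rnorm(9), 2.5, 8, -7)    # length 12 with two gross outliers
  res <- gesd(x, alpha = 0.05, max_outliers = 4)
  oracle <- brute_gesd_stats(x, 0.05, 4)
  expect_equal(res$test_statistics, oracle$R, tolerance = 1e-12)
  expect_equal(res$critical_values, oracle$lambda, tolerance = 1e-12)

  # planted single outlier at mean + 10 sd is always found; occasional
  # extra flags are genuine alpha-level events of the sequential test
  flags <- lapply(1:50, function(r) {
    set.seed(200 + r)
    y <- rnorm(100)
    y[37] <- mean(y) + 10 * sd(y)
    gesd(y, 0.05, 10)$outlier_indices
  })
  expect_true(all(vapply(flags, function(f) 37L %in% f, TRUE)))
  expect_gte(mean(vapply(flags, function(f) identical(f, 37L), TRUE)), 0.9)

  # null behaviour: mostly no outliers
  none <- vapply(1:50, function(r) {
    set.seed(300 + r)
    length(gesd(rnorm(100), 0.05, 10)$outlier_indices) == 0
  }, TRUE)
  expect_gte(mean(none), 0.9)

  # affine invariance and degenerate inputs
  set.seed(81)
  z <- rnorm(30); z[5] <- 9
  expect_identical(gesd(z, 0.05, 5)$outlier_indices,
                   gesd(3 * z - 7, 0.05, 5)$outlier_indices)
  expect_length(gesd(c(1, 1), 0.05, 1)$outlier_indices, 0)
})

test_that("group_contrast_with_covariates detects gaps and stays calibrated", {
  hits <- vapply(1:20, function(r) {
    set.seed(90 + r)
    grp <- rep(c("pd", "hc"), each = 25)
    age <- rnorm(50, 60, 8); sex <- rbinom(50, 1, 0.5)
    y <- 0.05 * age + 0.3 * sex + rnorm(50) + 2 * (grp == "pd")
    res <- group_contrast_with_covariates(y, grp, data.frame(age, sex),
                                          n_perm = 200, seed = r)
    res$p_perm < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.95)

  # identical groups give t = 0
  y0 <- rep(c(1, 2, 3, 4, 5), 2)
  g0 <- rep(c("a", "b"), each = 5)
  res0 <- group_contrast_with_covariates(y0, g0, NULL, n_perm = 50, seed = 1)
  expect_equal(res0$t, 0, tolerance = 1e-12)

  # confounded design errors
  grp <- rep(c("a", "b"), each = 5)
  expect_error(group_contrast_with_covariates(rnorm(10), grp,
               data.frame(dup = as.integer(grp == "a")), n_perm = 10, seed = 1),
               "collinear")
})

test_that("permutation type-I error is nominal (reduced-scale null sims)", {
  # cluster test
  fp_cluster <- vapply(1:60, function(r) {
    set.seed(400 + r)
    M <- matrix(rnorm(24 * 45), 24)
    res <- cluster_permutation_test(M, n_perm = 100, seed = r)
    nrow(res$clusters) > 0 && any(res$clusters$p_value < 0.05)
  }, TRUE)
  expect_lt(mean(fp_cluster), 0.15)
  # max-t FWER
  fp_maxt <- vapply(1:60, function(r) {
    set.seed(500 + r)
    any(max_t_permutation(matrix(rnorm(24 * 8), 24), n_perm = 100,
                          seed = r)$p_corrected < 0.05)
  }, TRUE)
  expect_lt(mean(fp_maxt), 0.15)
})
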