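# Permutation-based statistics: within-subject GLM contrasts, cluster-based
# permutation over frequency with a parametric cluster-forming threshold,
# max-t permutation pooled across states, Bonferroni adjustment, a GESD
# outlier test, and group contrasts with nuisance covariates.

#' Within-subject first-level GLM contrast
#'
#' Ordinary least squares per subject; for a paired two-condition design
#' with contrast `(1, -1)` this reduces exactly to the within-subject
#' condition difference.
#'
#' @param values Observations x frequencies matrix (or vector) for one
#'   subject.
#' @param design Observations x regressors design matrix.
#' @param contrast Length-regressors contrast vector.
#' @return Numeric contrast estimate per frequency (or scalar).
#' @export
first_level_contrast <- function(values, design, contrast) {
  values <- as.matrix(values)
  design <- as.matrix(design)
  stopifnot(nrow(values) == nrow(design), length(contrast) == ncol(design))
  if (all(contrast == 0)) stop("contrast must not be all zero")
  q <- qr(design)
  if (q$rank < ncol(design)) {
    bad <- colnames(design)[setdiff(seq_len(ncol(design)), q$pivot[seq_len(q$rank)])]
    stop("rank-deficient design; collinear regressors: ",
         paste(bad %||% "(unnamed)", collapse = ", "))
  }
  beta <- qr.coef(q, values)
  drop(crossprod(matrix(contrast, ncol = 1), beta))
}

# one-sample t statistics per column; zero-variance columns give 0 (zero
# mean) or +-Inf (constant nonzero effect)
col_t <- function(M) {
  n <- nrow(M)
  m <- colMeans(M)
  s <- sqrt(colSums(sweep(M, 2, m)^2) / (n - 1))
  tv <- numeric(length(m))
  nz <- s > 0
  tv[nz] <- m[nz] / (s[nz] / sqrt(n))
  tv[!nz] <- sign(m[!nz]) * Inf
  tv[!nz & m == 0] <- 0
  tv
}

# contiguous runs where `flag` is TRUE, as a start/end index matrix
runs_true <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Cluster-based permutation test over frequency
#'
#' Group-level one-sample t per frequency on the subject contrast spectra;
#' contiguous supra-threshold runs (|t| above the two-sided parametric
#' critical value at `cluster_alpha`, df = n - 1) form clusters scored by
#' their summed |t| (cluster mass).  The null distribution records the
#' maximum cluster mass under random subject-level sign flips.
#'
#' @param subject_contrasts Subjects x frequencies matrix of first-level
#'   contrast estimates.
#' @param freqs Frequency axis (defaults to bin indices).
#' @param n_perm Number of permutations (1000 by default).
#' @param cluster_alpha Cluster-forming significance level.
#' @param seed Integer seed.
#' @return Object of class `contrast_result` with `t_spectrum`, `clusters`
#'   (data frame: freq_lo, freq_hi, mass, mean_t, peak_freq, p_value),
#'   `cluster_threshold`, `n_perm`.
#' @export
cluster_permutation_test <- function(subject_contrasts, freqs = NULL,
                                     n_perm = 1000, cluster_alpha = 0.05,
                                     seed = 1) {
  M <- as.matrix(subject_contrasts)
  n <- nrow(M); F <- ncol(M)
  stopifnot(n >= 2, F >= 1, n_perm >= 1)
  if (is.null(freqs)) freqs <- seq_len(F)
  tcrit <- stats::qt(1 - cluster_alpha / 2, df = n - 1)
  tobs <- col_t(M)

  # sign-specific clusters: positive and negative excursions never merge
  cluster_runs <- function(tv) {
    rbind(runs_true(tv > tcrit), runs_true(tv < -tcrit))
  }
  cluster_mass <- function(tv) {
    rr <- cluster_runs(tv)
    if (nrow(rr) == 0) return(numeric(0))
    vapply(seq_len(nrow(rr)), function(i)
      sum(abs(tv[rr[i, 1]:rr[i, 2]])), 0)
  }

  rr <- cluster_runs(tobs)
  rr <- rr[order(rr[, 1]), , drop = FALSE]
  null_max <- withr_seed(seed, {
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    vapply(seq_len(n_perm), function(p) {
      m <- cluster_mass(col_t(M * signs[p, ]))
      if (length(m)) max(m) else 0
    }, 0)
  })

  clusters <- if (nrow(rr)) {
    do.call(rbind, lapply(seq_len(nrow(rr)), function(i) {
      sel <- rr[i, 1]:rr[i, 2]
      mass <- sum(abs(tobs[sel]))
      data.frame(freq_lo = freqs[rr[i, 1]], freq_hi = freqs[rr[i, 2]],
                 mass = mass, mean_t = mean(tobs[sel]),
                 peak_freq = freqs[sel][which.max(abs(tobs[sel]))],
                 p_value = (1 + sum(null_max >= mass)) / (1 + n_perm))
    }))
  } else {
    data.frame(freq_lo = numeric(0), freq_hi = numeric(0), mass = numeric(0),
               mean_t = numeric(0), peak_freq = numeric(0), p_value = numeric(0))
  }
  structure(list(t_spectrum = tobs, freqs = freqs, clusters = clusters,
                 cluster_threshold = tcrit, n_perm = n_perm,
                 cluster_alpha = cluster_alpha, df = n - 1),
            class = "contrast_result")
}

#' Max-t permutation test across states
#'
#' One-sample t per state on paired subject differences; the null pools the
#' maximum |t| across states per sign-flip permutation, yielding
#' family-wise-corrected p-values.
#'
#' @param values Subjects x states matrix of paired differences.
#' @param n_perm Number of permutations (1000 by default).
#' @param seed Integer seed.
#' @return List with `t` (per state), `p_corrected`, `n_perm`.
#' @export
max_t_permutation <- function(values, n_perm = 1000, seed = 1) {
  M <- as.matrix(values)
  n <- nrow(M)
  stopifnot(n >= 2, n_perm >= 1)
  sds <- apply(M, 2, stats::sd)
  if (any(sds == 0)) stop("constant column: t statistic undefined")
  tobs <- col_t(M)
  null_max <- withr_seed(seed, {
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    vapply(seq_len(n_perm), function(p) max(abs(col_t(M * signs[p, ]))), 0)
  })
  p <- vapply(abs(tobs), function(tk) (1 + sum(null_max >= tk)) / (1 + n_perm), 0)
  list(t = tobs, p_corrected = p, n_perm = n_perm)
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha Family-wise level (0.05 by default).
#' @param m Number of comparisons.
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (m < 1) stop("m must be at least 1")
  alpha / m
}

#' Generalised extreme studentized deviate (GESD) outlier test
#'
#' Iteratively removes the most extreme studentized value; after `r = 1 ..
#' max_outliers` removals the statistic `R_i = max |x - mean| / sd` is
#' compared with the t-based critical value `lambda_i`, and the declared
#' outliers are the first `i*` removals where `i*` is the largest `i` with
#' `R_i > lambda_i`.
#'
#' @param values Numeric sample (n >= 3 for a non-trivial test; smaller
#'   samples return no outliers).
#' @param alpha Significance level (0.05 by default).
#' @param max_outliers Upper bound on the number of outliers; defaults to
#'   `ceiling(0.2 * n)`.
#' @return Object of class `gesd_result`: `outlier_indices` (into `values`),
#'   `test_statistics`, `critical_values`.
#' @export
gesd <- function(values, alpha = 0.05, max_outliers = NULL) {
  x <- as.numeric(values)
  n <- length(x)
  if (is.null(max_outliers)) max_outliers <- ceiling(0.2 * n)
  max_outliers <- min(max_outliers, max(0L, n %/% 2 - 1L))
  empty <- structure(list(outlier_indices = integer(0),
                          test_statistics = numeric(0),
                          critical_values = numeric(0)),
                     class = "gesd_result")
  if (n < 3 || max_outliers < 1) return(empty)

  idx <- seq_len(n)
  removed <- integer(0)
  R <- numeric(0); lam <- numeric(0)
  for (i in seq_len(max_outliers)) {
    xi <- x[idx]
    s <- stats::sd(xi)
    if (!is.finite(s) || s == 0) break
    dev <- abs(xi - mean(xi))
    j <- which.max(dev)
    R <- c(R, dev[j] / s)
    ni <- length(xi)
    pq <- 1 - alpha / (2 * ni)
    tq <- stats::qt(pq, df = ni - 2)
    lam <- c(lam, (ni - 1) * tq / sqrt((ni - 2 + tq^2) * ni))
    removed <- c(removed, idx[j])
    idx <- idx[-j]
  }
  n_out <- if (any(R > lam)) max(which(R > lam)) else 0L
  structure(list(outlier_indices = removed[seq_len(n_out)],
                 test_statistics = R, critical_values = lam),
            class = "gesd_result")
}

#' Group contrast with nuisance covariates
#'
#' OLS of the per-subject values on a group indicator plus covariates; the
#' reported t is the coefficient t for the group regressor, and the
#' permutation p-value follows the Freedman-Lane scheme (permute the
#' residuals of the covariate-only model, refit, compare |t|).
#'
#' @param values Per-subject scalar outcomes.
#' @param group Two-level factor or character vector of group labels.
#' @param covariates Data frame (e.g. age, sex) or NULL.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return List with `t`, `p_param`, `p_perm`, `df`.
#' @export
group_contrast_with_covariates <- function(values, group, covariates = NULL,
                                           n_perm = 1000, seed = 1) {
  y <- as.numeric(values)
  g <- as.integer(factor(group)) - 1
  if (length(unique(g)) != 2) stop("group must have exactly two levels")
  if (min(table(g)) < 2) stop("each group needs at least 2 subjects")
  Z <- matrix(1, length(y), 1)
  if (!is.null(covariates)) {
    cv <- as.data.frame(covariates)
    Z <- cbind(Z, stats::model.matrix(~ ., cv)[, -1, drop = FALSE])
  }
  X <- cbind(g, Z)
  if (qr(X)$rank < ncol(X)) stop("group regressor is collinear with the covariates")

  fit_t <- function(yv, gv) {
    Xf <- cbind(gv, Z)
    XtX <- crossprod(Xf)
    beta <- solve(XtX, crossprod(Xf, yv))
    res <- yv - Xf %*% beta
    df <- length(yv) - ncol(Xf)
    s2 <- sum(res^2) / df
    beta[1] / sqrt(s2 * solve(XtX)[1, 1])
  }
  tobs <- fit_t(y, g)
  # Freedman-Lane: permute reduced-model residuals
  qz <- qr(Z)
  yz_hat <- qr.fitted(qz, y)
  rz <- y - yz_hat
  pvec <- withr_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      ystar <- yz_hat + sample(rz)
      abs(fit_t(ystar, g))
    }, 0)
  })
  df <- length(y) - ncol(X)
  list(t = tobs, df = df,
       p_param = 2 * stats::pt(-abs(tobs), df),
       p_perm = (1 + sum(pvec >= abs(tobs))) / (1 + n_perm))
}
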