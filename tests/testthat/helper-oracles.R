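# Independent oracles shared across tests.  These deliberately reimplement
# the operations they check by brute force, without touching the package's
# own code paths.

# exhaustive-path posterior/evidence for a small HMM (K^T paths)
brute_forward_backward <- function(model, Y) {
  K <- model$n_states
  Tn <- nrow(Y)
  logd <- sapply(seq_len(K), function(k) {
    S <- model$covariances[[k]]
    R <- chol(S)
    z <- Y %*% backsolve(R, diag(ncol(Y)))
    -0.5 * (ncol(Y) * log(2 * pi) + 2 * sum(log(diag(R))) + rowSums(z^2))
  })
  logd <- matrix(logd, nrow = Tn)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  lp <- apply(paths, 1, function(p) {
    v <- log(model$initial[p[1]]) + logd[1, p[1]]
    if (Tn > 1)
      for (t in 2:Tn)
        v <- v + log(model$transition[p[t - 1], p[t]]) + logd[t, p[t]]
    v
  })
  le <- max(lp) + log(sum(exp(lp - max(lp))))
  w <- exp(lp - le)
  gamma <- matrix(0, Tn, K)
  for (t in seq_len(Tn))
    for (k in seq_len(K))
      gamma[t, k] <- sum(w[paths[, t] == k])
  list(gamma = gamma, log_evidence = le)
}

# brute-force run-length burst scan: strictly supra-threshold runs of at
# least min_len samples
brute_bursts <- function(envelope, thr, min_len) {
  above <- envelope > thr
  out <- NULL
  i <- 1L
  n <- length(above)
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1L]) j <- j + 1L
      if (j - i + 1L >= min_len) out <- rbind(out, c(i, j + 1L))
      i <- j + 1L
    } else i <- i + 1L
  }
  if (is.null(out)) out <- matrix(integer(0), 0, 2)
  colnames(out) <- c("start", "end")
  out
}

# step-by-step GESD statistics on a fixed vector (textbook recursion)
brute_gesd_stats <- function(x, alpha, r) {
  R <- lam <- numeric(r)
  xi <- x
  for (i in seq_len(r)) {
    dev <- abs(xi - mean(xi))
    j <- which.max(dev)
    R[i] <- dev[j] / sd(xi)
    ni <- length(xi)
    p <- 1 - alpha / (2 * ni)
    tq <- qt(p, ni - 2)
    lam[i] <- (ni - 1) * tq / sqrt((ni - 2 + tq^2) * ni)
    xi <- xi[-j]
  }
  list(R = R, lambda = lam)
}

# random positive-definite matrix
rand_pd <- function(p, scale = 1) {
  A <- matrix(rnorm(p * p), p)
  tcrossprod(A) / p * scale + diag(p) * 0.3 * scale
}

# tiny two-state recording fixture used by several spectral tests
tiny_recording <- function(n = 2000, fs = 100, seed = 1) {
  set.seed(seed)
  recording(matrix(rnorm(2 * n), 2), fs = fs,
            channel_labels = c("ctx", "stn"),
            channel_roles = c("cortical", "lfp"))
}
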