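# Time-delay embedding, PCA reduction and a zero-mean full-covariance
# Gaussian hidden Markov model fit by EM (Baum-Welch), with support for
# inference under fixed "canonical" state observation models.  States are
# covariance-defined: the embedded covariance of each state captures the
# multichannel auto- and cross-spectral pattern of that network.

#' Embedding configuration
#'
#' @param n_lags_each_side Number of lags L on each side (default 7); the
#'   embedded dimension is `channels * (2L + 1)`.
#' @export
embedding_config <- function(n_lags_each_side = 7) {
  stopifnot(n_lags_each_side >= 0)
  structure(list(n_lags_each_side = as.integer(n_lags_each_side)),
            class = "embedding_config")
}

#' Time-delay embed a multichannel series
#'
#' Row `t` of the output stacks the channel values at offsets `-L..+L`
#' around sample `t + L` of the input; columns are ordered channel-major
#' (all lags of channel 1, then channel 2, ...), lag `-L` first.  An
#' embedded row touching any bad sample is itself marked bad.
#'
#' @param X Channels x samples matrix.
#' @param cfg An [embedding_config()].
#' @param bad_mask Optional per-sample logical mask.
#' @return List with `Y` ((samples - 2L) x C(2L+1) matrix), `good` (logical
#'   per embedded row) and `offset` (= L; embedded row `t` is centred on
#'   input sample `t + L`).
#' @export
time_delay_embed <- function(X, cfg = embedding_config(), bad_mask = NULL) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  L <- cfg$n_lags_each_side
  C <- nrow(X); Tn <- ncol(X)
  if (Tn <= 2 * L) stop("series shorter than the embedding window")
  Tt <- Tn - 2 * L
  Y <- matrix(0, Tt, C * (2 * L + 1))
  cn <- character(ncol(Y))
  col <- 1L
  for (c in seq_len(C)) {
    for (lag in -L:L) {
      Y[, col] <- X[c, (1 + L + lag):(Tt + L + lag)]
      cn[col] <- sprintf("ch%d.lag%+d", c, lag)
      col <- col + 1L
    }
  }
  colnames(Y) <- cn
  good <- rep(TRUE, Tt)
  if (!is.null(bad_mask)) {
    stopifnot(length(bad_mask) == Tn)
    # row t spans input samples t .. t + 2L
    bad_any <- vapply(seq_len(Tt), function(t) any(bad_mask[t:(t + 2 * L)]),
                      TRUE)
    good <- !bad_any
  }
  list(Y = Y, good = good, offset = L)
}

#' PCA basis for the embedded space
#'
#' Eigendecomposition of the covariance of the (good) embedded rows.
#'
#' @param embedded Embedded matrix (rows = samples) or the list returned by
#'   [time_delay_embed()].
#' @param P Number of components to keep (120 by default).
#' @param whiten If TRUE, projections are scaled to unit variance per
#'   component.
#' @return Object of class `pca_basis` with orthonormal `components`
#'   (dim x P), `explained_variance`, and `center`.
#' @export
fit_pca <- function(embedded, P = 120, whiten = FALSE) {
  good <- NULL
  if (is.list(embedded) && !is.null(embedded$Y)) {
    good <- embedded$good
    embedded <- embedded$Y
  }
  if (!is.null(good)) embedded <- embedded[good, , drop = FALSE]
  d <- ncol(embedded)
  if (P > d) stop("P exceeds the embedded dimension")
  if (nrow(embedded) < P) stop("fewer rows than requested components")
  ctr <- colMeans(embedded)
  S <- stats::cov(embedded)
  eg <- eigen(S, symmetric = TRUE)
  comps <- eg$vectors[, seq_len(P), drop = FALSE]
  ev <- pmax(eg$values[seq_len(P)], 0)
  structure(list(components = comps, explained_variance = ev,
                 total_variance = sum(pmax(eg$values, 0)),
                 center = ctr, whiten = whiten),
            class = "pca_basis")
}

#' Project embedded data onto a PCA basis
#'
#' @param basis A [fit_pca()] basis.
#' @param embedded Embedded matrix or [time_delay_embed()] list.
#' @return Projected matrix (all rows, including bad ones).
#' @export
pca_project <- function(basis, embedded) {
  if (is.list(embedded) && !is.null(embedded$Y)) embedded <- embedded$Y
  Y <- sweep(embedded, 2, basis$center) %*% basis$components
  if (isTRUE(basis$whiten))
    Y <- sweep(Y, 2, sqrt(pmax(basis$explained_variance, 1e-12)), "/")
  Y
}

#' Construct an HMM model object
#'
#' @param transition K x K row-stochastic matrix.
#' @param initial Length-K initial distribution.
#' @param covariances List of K symmetric positive-definite matrices
#'   (zero-mean Gaussian observation models).
#' @export
hmm_model <- function(transition, initial, covariances) {
  K <- length(covariances)
  transition <- as.matrix(transition)
  stopifnot(nrow(transition) == K, ncol(transition) == K,
            length(initial) == K, all(transition >= 0),
            all(abs(rowSums(transition) - 1) < 1e-8),
            abs(sum(initial) - 1) < 1e-8)
  for (S in covariances) chol(S)  # PD check
  structure(list(n_states = K, transition = transition,
                 initial = as.numeric(initial), covariances = covariances),
            class = "hmm_model")
}

# T x K matrix of zero-mean Gaussian log densities
gauss_logdens <- function(Y, covariances) {
  K <- length(covariances)
  P <- ncol(Y)
  out <- matrix(0, nrow(Y), K)
  for (k in seq_len(K)) {
    R <- chol(covariances[[k]])
    logdet <- 2 * sum(log(diag(R)))
    Z <- Y %*% backsolve(R, diag(P))      # Y %*% R^{-1}
    out[, k] <- -0.5 * (P * log(2 * pi) + logdet + rowSums(Z^2))
  }
  out
}

# contiguous runs of TRUE as (start, end) pairs
good_segments <- function(good) {
  r <- rle(good)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

#' Exact posterior inference (forward-backward)
#'
#' Scaled forward-backward over each contiguous run of good samples; the
#' initial distribution restarts at every segment, and the log evidence sums
#' over segments.  Bad rows receive `NA` posteriors.
#'
#' @param model An [hmm_model()].
#' @param Y Samples x P projected data.
#' @param good Optional logical row mask.
#' @return Object of class `state_posterior`: `gamma` (T x K), `log_evidence`,
#'   `viterbi_path` (argmax of gamma per row), `good`.
#' @export
forward_backward <- function(model, Y, good = NULL) {
  stopifnot(inherits(model, "hmm_model"))
  if (!is.matrix(Y)) Y <- matrix(Y, ncol = 1)
  if (ncol(Y) != nrow(model$covariances[[1]]))
    stop("data dimension does not match the model covariances")
  if (is.null(good)) good <- rep(TRUE, nrow(Y))
  if (!any(good)) stop("no good samples")
  segs <- good_segments(good)
  logB <- matrix(-Inf, nrow(Y), model$n_states)
  gi <- which(good)
  logB[gi, ] <- gauss_logdens(Y[gi, , drop = FALSE], model$covariances)
  fb <- .fb_cpp(logB, model$initial, model$transition,
                as.integer(segs[, "start"]), as.integer(segs[, "end"]))
  gamma <- fb$gamma
  gamma[!good, ] <- NA_real_
  structure(list(gamma = gamma, log_evidence = fb$loglik,
                 viterbi_path = apply_argmax(gamma), good = good,
                 xi = fb$xi, first = fb$first),
            class = "state_posterior")
}

apply_argmax <- function(gamma) {
  out <- rep(NA_integer_, nrow(gamma))
  ok <- stats::complete.cases(gamma)
  if (any(ok)) out[ok] <- max.col(gamma[ok, , drop = FALSE], ties.method = "first")
  out
}

#' Fit a zero-mean Gaussian HMM by EM
#'
#' Baum-Welch with full-covariance, zero-mean Gaussian emissions and
#' multiple random restarts; the restart with the best log evidence wins.
#' A ridge of `ridge * mean(diag)` is added to every covariance update for
#' positive definiteness in high dimension.
#'
#' @param Y Samples x P matrix (standardised, PCA-projected embeddings).
#' @param K Number of states.
#' @param seed Master seed; restart seeds derive from it.
#' @param tol EM stops when the per-sample log-likelihood improves by less
#'   than this.
#' @param max_iter Maximum EM iterations per restart.
#' @param n_restarts Number of random restarts.
#' @param good Optional logical row mask (bad rows are skipped and the chain
#'   restarts after each gap).
#' @param ridge Relative covariance ridge.
#' @param verbose Print per-restart convergence summaries.
#' @return List with `model` ([hmm_model()]), `posterior`
#'   ([forward_backward()] output) and `loglik_trace`.
#' @export
fit_hmm <- function(Y, K, seed = 1, tol = 1e-5, max_iter = 100,
                    n_restarts = 3, good = NULL, ridge = 1e-6,
                    verbose = FALSE) {
  if (!is.matrix(Y)) Y <- matrix(Y, ncol = 1)
  stopifnot(all(is.finite(Y)), K >= 1)
  if (K > nrow(Y)) stop("more states than samples")
  if (is.null(good)) good <- rep(TRUE, nrow(Y))
  segs <- good_segments(good)
  gi <- which(good)
  Yg <- Y[gi, , drop = FALSE]
  P <- ncol(Y)
  S0 <- crossprod(Yg) / nrow(Yg)

  best <- NULL
  for (r in seq_len(n_restarts)) {
    rseed <- (seed + 1009 * (r - 1)) %% .Machine$integer.max
    # init: random contiguous block segmentation -> per-state covariances,
    # a data-informed start that keeps states spectrally diverse
    covs <- withr_seed(rseed, {
      blk <- max(10L, min(100L, nrow(Yg) %/% (K * 10L)))
      n_blk <- ceiling(nrow(Yg) / blk)
      lab <- rep(sample(rep_len(seq_len(K), n_blk)), each = blk)[seq_len(nrow(Yg))]
      lapply(seq_len(K), function(k) {
        rows <- which(lab == k)
        S <- if (length(rows) > P) crossprod(Yg[rows, , drop = FALSE]) / length(rows)
             else S0
        S <- (S + t(S)) / 2
        S + diag(1e-4 * mean(diag(S)), P)
      })
    })
    A <- matrix(1 / K, K, K) + diag(K) * 4
    A <- A / rowSums(A)
    model <- hmm_model(A, rep(1 / K, K), covs)

    ll_prev <- -Inf
    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      logB <- matrix(-Inf, nrow(Y), K)
      logB[gi, ] <- gauss_logdens(Yg, model$covariances)
      fb <- .fb_cpp(logB, model$initial, model$transition,
                    as.integer(segs[, "start"]), as.integer(segs[, "end"]))
      ll <- fb$loglik
      trace <- c(trace, ll)
      g <- fb$gamma[gi, , drop = FALSE]
      # M-step
      Anew <- fb$xi + 1e-12
      Anew <- Anew / rowSums(Anew)
      pinew <- (fb$first + 1e-12) / sum(fb$first + 1e-12)
      covs <- lapply(seq_len(K), function(k) {
        w <- g[, k]
        sw <- sum(w)
        S <- crossprod(Yg * sqrt(w)) / max(sw, 1e-12)
        S <- (S + t(S)) / 2
        S + diag(ridge * mean(diag(S)), P)
      })
      model <- hmm_model(Anew, pinew, covs)
      if (is.finite(ll_prev) && (ll - ll_prev) / length(gi) < tol && ll >= ll_prev - 1e-8)
        break
      ll_prev <- ll
    }
    if (verbose)
      message(sprintf("restart %d: loglik %.3f after %d iterations", r, ll, it))
    if (is.null(best) || ll > best$loglik) {
      best <- list(model = model, loglik = ll, trace = trace)
    }
  }
  post <- forward_backward(best$model, Y, good)
  list(model = best$model, posterior = post, loglik_trace = best$trace)
}

#' Infer state time courses under fixed canonical observation models
#'
#' Observation covariances stay fixed at the canonical definitions; if
#' `re_estimate_transition` is TRUE (the default), EM updates only the
#' transition matrix and initial distribution before the final posterior
#' pass.
#'
#' @param canonical An [hmm_model()] (the canonical state definitions).
#' @param Y Samples x P projected data.
#' @param re_estimate_transition Re-fit transition/initial by EM.
#' @param good Optional logical row mask.
#' @param max_iter,tol EM controls for the transition re-estimation.
#' @return A `state_posterior`.
#' @export
infer_with_canonical_states <- function(canonical, Y, re_estimate_transition = TRUE,
                                        good = NULL, max_iter = 50, tol = 1e-6) {
  stopifnot(inherits(canonical, "hmm_model"))
  if (!is.matrix(Y)) Y <- matrix(Y, ncol = 1)
  if (ncol(Y) != nrow(canonical$covariances[[1]]))
    stop("data dimension does not match the canonical covariances")
  if (is.null(good)) good <- rep(TRUE, nrow(Y))
  segs <- good_segments(good)
  gi <- which(good)
  logB <- matrix(-Inf, nrow(Y), canonical$n_states)
  logB[gi, ] <- gauss_logdens(Y[gi, , drop = FALSE], canonical$covariances)
  model <- canonical
  if (re_estimate_transition) {
    ll_prev <- -Inf
    for (it in seq_len(max_iter)) {
      fb <- .fb_cpp(logB, model$initial, model$transition,
                    as.integer(segs[, "start"]), as.integer(segs[, "end"]))
      Anew <- fb$xi + 1e-12
      Anew <- Anew / rowSums(Anew)
      pinew <- (fb$first + 1e-12) / sum(fb$first + 1e-12)
      model <- hmm_model(Anew, pinew, canonical$covariances)
      if ((fb$loglik - ll_prev) / length(gi) < tol && is.finite(ll_prev)) break
      ll_prev <- fb$loglik
    }
  }
  forward_backward(model, Y, good)
}

#' Fractional occupancy
#'
#' Column means of the posterior over good samples; sums to 1.
#'
#' @param post A `state_posterior` (or a gamma matrix).
#' @return Length-K numeric vector.
#' @export
fractional_occupancy <- function(post) {
  gamma <- if (inherits(post, "state_posterior")) post$gamma else post
  ok <- stats::complete.cases(gamma)
  colMeans(gamma[ok, , drop = FALSE])
}

#' Match estimated states to reference states
#'
#' Optimal one-to-one assignment maximising the summed Pearson correlation
#' between vectorised state covariance matrices (or between gamma columns if
#' matrices are not available), solved exactly with the Hungarian algorithm.
#'
#' @param estimated,reference [hmm_model()]s with equal K and dimension, or
#'   K-column matrices whose columns are matched by correlation.
#' @return Integer permutation `p` such that estimated state `k` corresponds
#'   to reference state `p[k]`.
#' @export
match_states <- function(estimated, reference) {
  # correlation of the vectorised matrices, penalised by the normalised
  # Frobenius distance: correlation alone cannot separate states that share
  # a covariance pattern at different scales
  simfun <- function(a, b) {
    cc <- if (stats::sd(a) == 0 || stats::sd(b) == 0) 0 else stats::cor(a, b)
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    d <- if (na > 0 && nb > 0) sqrt(sum((a - b)^2)) / sqrt(na * nb) else 0
    cc - d
  }
  if (inherits(estimated, "hmm_model")) {
    stopifnot(inherits(reference, "hmm_model"),
              estimated$n_states == reference$n_states)
    K <- estimated$n_states
    sim <- matrix(0, K, K)
    for (i in seq_len(K)) for (j in seq_len(K))
      sim[i, j] <- simfun(as.numeric(estimated$covariances[[i]]),
                          as.numeric(reference$covariances[[j]]))
  } else {
    estimated <- as.matrix(estimated); reference <- as.matrix(reference)
    stopifnot(ncol(estimated) == ncol(reference))
    K <- ncol(estimated)
    sim <- matrix(0, K, K)
    for (i in seq_len(K)) for (j in seq_len(K))
      sim[i, j] <- simfun(estimated[, i], reference[, j])
  }
  hungarian_max(sim)
}

# exact linear assignment (maximisation) via shortest augmenting paths;
# column index 1 is the virtual unmatched column of the classical algorithm
hungarian_max <- function(sim) {
  n <- nrow(sim)
  cost <- max(sim) - sim          # convert to minimisation, non-negative
  u <- numeric(n)                 # row potentials
  v <- numeric(n + 1)             # column potentials (1 = virtual)
  p <- integer(n + 1)             # p[j]: row assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (j in 2:(n + 1)) {
        if (!used[j]) {
          cur <- cost[i0, j - 1L] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in 1:(n + 1)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  perm <- integer(n)
  for (j in 2:(n + 1)) if (p[j] > 0) perm[p[j]] <- j - 1L
  perm
}

#' Permute the states of a model or posterior
#'
#' @param x An [hmm_model()] or `state_posterior`.
#' @param perm Integer permutation mapping old index -> new index position:
#'   new state `k` is old state `which(perm == k)`... states are reordered so
#'   that `permute_states(x, match_states(x, ref))` aligns `x` with `ref`.
#' @export
permute_states <- function(x, perm) {
  inv <- order(perm)   # inv[k] = old index that becomes new state k
  if (inherits(x, "hmm_model")) {
    hmm_model(x$transition[inv, inv, drop = FALSE], x$initial[inv],
              x$covariances[inv])
  } else if (inherits(x, "state_posterior")) {
    x$gamma <- x$gamma[, inv, drop = FALSE]
    x$viterbi_path <- perm[x$viterbi_path]
    x
  } else stop("unsupported object")
}
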