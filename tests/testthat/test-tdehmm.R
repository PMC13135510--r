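# Time-delay embedding, PCA, HMM inference and state utilities.

test_that("time_delay_embed matches a hand-rolled shift oracle", {
  set.seed(1)
  x <- rnorm(50)
  emb <- time_delay_embed(matrix(x, 1), embedding_config(2))
  expect_equal(dim(emb$Y), c(46, 5))
  for (t in c(1, 10, 46))
    expect_equal(unname(emb$Y[t, ]), x[t:(t + 4)])
  # L = 0 is the identity
  emb0 <- time_delay_embed(matrix(x, 1), embedding_config(0))
  expect_equal(unname(emb0$Y[, 1]), x)
  # dimensions: C = 3, L = 1 -> 9 columns, channel-major ordering
  X3 <- matrix(rnorm(30), 3)
  emb3 <- time_delay_embed(X3, embedding_config(1))
  expect_equal(ncol(emb3$Y), 9)
  expect_equal(colnames(emb3$Y)[1:3], c("ch1.lag-1", "ch1.lag+0", "ch1.lag+1"))
  expect_error(time_delay_embed(matrix(rnorm(4), 1), embedding_config(2)),
               "shorter")
})

test_that("embedded rows touching bad samples are masked", {
  x <- matrix(rnorm(20), 1)
  bad <- rep(FALSE, 20); bad[10] <- TRUE
  emb <- time_delay_embed(x, embedding_config(2), bad_mask = bad)
  # row t spans input t..t+4; rows 6..10 touch sample 10
  expect_equal(which(!emb$good), 6:10)
})

test_that("fit_pca recovers exact subspaces and is monotone in P", {
  set.seed(2)
  B <- matrix(rnorm(10 * 2), 10, 2)
  Y <- matrix(rnorm(500 * 2), 500, 2) %*% t(B)   # rank-2 data in 10 dims
  basis <- fit_pca(Y, P = 2)
  expect_lt(abs(sum(basis$explained_variance) / basis$total_variance - 1), 1e-8)
  expect_lt(max(abs(crossprod(basis$components) - diag(2))), 1e-8)
  # isotropic data has near-equal eigenvalues
  Yi <- matrix(rnorm(50000 * 5), ncol = 5)
  bi <- fit_pca(Yi, P = 5)
  expect_lt(max(bi$explained_variance) / min(bi$explained_variance), 1.3)
  # reconstruction error nonincreasing in P
  set.seed(3)
  Z <- matrix(rnorm(300 * 6), 300, 6) %*% diag(c(3, 2.5, 2, 1.5, 1, 0.5))
  errs <- vapply(1:6, function(P) {
    b <- fit_pca(Z, P = P)
    W <- b$components
    R <- sweep(Z, 2, b$center) %*% W %*% t(W)
    sum((sweep(Z, 2, b$center) - R)^2)
  }, 0)
  expect_true(all(diff(errs) <= 1e-8))
  expect_error(fit_pca(Z, P = 7), "exceeds")
})

test_that("forward_backward matches exhaustive enumeration (property)", {
  set.seed(4)
  for (r in 1:25) {
    K <- sample(2:3, 1); Tn <- sample(2:7, 1)
    A <- matrix(rexp(K * K), K); A <- A / rowSums(A)
    pi0 <- rexp(K); pi0 <- pi0 / sum(pi0)
    model <- hmm_model(A, pi0, lapply(seq_len(K), function(k) rand_pd(2)))
    Y <- matrix(rnorm(Tn * 2), Tn, 2)
    fb <- forward_backward(model, Y)
    or <- brute_forward_backward(model, Y)
    expect_lt(max(abs(fb$gamma - or$gamma)), 1e-10)
    expect_lt(abs(fb$log_evidence - or$log_evidence), 1e-10)
    expect_equal(rowSums(fb$gamma), rep(1, Tn), tolerance = 1e-10)
  }
})

test_that("forward_backward symmetry, absorption, label equivariance", {
  K <- 3
  S <- rand_pd(2, 1)
  uni <- hmm_model(matrix(1 / K, K, K), rep(1 / K, K), rep(list(S), K))
  Y <- matrix(rnorm(20), 10, 2)
  fb <- forward_backward(uni, Y)
  expect_equal(fb$gamma, matrix(1 / K, 10, K), tolerance = 1e-12)

  # permutation equivariance: permuting states permutes gamma columns
  set.seed(5)
  covs <- lapply(1:3, function(k) rand_pd(2, k))
  A <- matrix(c(.8, .1, .1, .2, .7, .1, .1, .2, .7), 3, byrow = TRUE)
  m1 <- hmm_model(A, c(.5, .3, .2), covs)
  prm <- c(2, 3, 1)
  inv <- order(prm)
  m2 <- hmm_model(A[inv, inv], c(.5, .3, .2)[inv], covs[inv])
  f1 <- forward_backward(m1, Y)
  f2 <- forward_backward(m2, Y)
  expect_equal(f2$gamma, f1$gamma[, inv], tolerance = 1e-12)
  expect_equal(f2$log_evidence, f1$log_evidence, tolerance = 1e-10)

  # near-absorbing state keeps the posterior after entry
  Aab <- matrix(c(1, 0, 0.5, 0.5), 2, byrow = TRUE)
  mab <- hmm_model(Aab, c(0, 1), list(diag(2), diag(2) * 9))
  Yab <- rbind(matrix(rnorm(10, sd = 3), 5, 2), matrix(rnorm(10, sd = .5), 5, 2))
  fab <- forward_backward(mab, Yab)
  expect_gt(min(fab$gamma[tail(which(fab$gamma[, 1] > 0.99), 1):10, 1]), 0.99)
})

test_that("fit_hmm degenerate K = 1 and EM monotonicity", {
  set.seed(6)
  Y <- matrix(rnorm(2000), 500, 4)
  fit <- fit_hmm(Y, K = 1, seed = 1, n_restarts = 1, max_iter = 5)
  expect_true(all(fit$posterior$gamma == 1))
  S_hat <- fit$model$covariances[[1]]
  S_emp <- crossprod(Y) / nrow(Y)
  # equality up to the documented PD ridge (1e-6 x mean diagonal)
  expect_lt(max(abs(S_hat - S_emp)) / mean(diag(S_emp)), 1e-5)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
})

test_that("fit_hmm recovers a planted two-state model", {
  set.seed(7)
  Tn <- 20000
  st <- sample_state_sequence(uniform_markov_spec(2, 50, 1), Tn, seed = 8)
  Y <- matrix(rnorm(Tn * 3), Tn, 3)
  Y[st == 2, ] <- Y[st == 2, ] * 2    # covariance scale ratio 4
  fit <- fit_hmm(Y, K = 2, seed = 1, n_restarts = 2, max_iter = 60)
  ref <- hmm_model(uniform_markov_spec(2, 50, 1)$transition, c(.5, .5),
                   list(diag(3), diag(3) * 4))
  perm <- match_states(fit$model, ref)
  post <- permute_states(fit$posterior, perm)
  model <- permute_states(fit$model, perm)
  expect_gt(mean(post$viterbi_path == st), 0.95)
  expect_lt(max(abs(diag(model$transition) - 0.98)), 0.01)
  for (k in 1:2) {
    S <- model$covariances[[k]]
    S_true <- ref$covariances[[k]]
    expect_lt(norm(S - S_true, "F") / norm(S_true, "F"), 0.1)
  }
})

test_that("bad samples split the chain into segments", {
  set.seed(9)
  Y <- matrix(rnorm(600), 300, 2)
  good <- rep(TRUE, 300); good[101:120] <- FALSE
  m <- hmm_model(matrix(c(.9, .1, .1, .9), 2), c(.5, .5),
                 list(diag(2), diag(2) * 3))
  fb <- forward_backward(m, Y, good = good)
  expect_true(all(is.na(fb$gamma[101:120, ])))
  # posteriors of each good stretch equal the stand-alone run
  fb1 <- forward_backward(m, Y[1:100, , drop = FALSE])
  expect_equal(fb$gamma[1:100, ], fb1$gamma, tolerance = 1e-12)
})

test_that("infer_with_canonical_states is faithful to the generating model", {
  set.seed(10)
  Tn <- 10000
  st <- sample_state_sequence(uniform_markov_spec(2, 50, 1), Tn, seed = 11)
  Y <- matrix(rnorm(Tn * 3), Tn, 3)
  Y[st == 2, ] <- Y[st == 2, ] * 2
  gen <- hmm_model(uniform_markov_spec(2, 50, 1)$transition, c(.5, .5),
                   list(diag(3), diag(3) * 4))
  post <- infer_with_canonical_states(gen, Y)
  fit <- fit_hmm(Y, K = 2, seed = 1, n_restarts = 2)
  perm <- match_states(fit$model, gen)
  fpost <- permute_states(fit$posterior, perm)
  expect_lt(mean(abs(post$gamma - fpost$gamma)), 0.05)
  # K = 1 canonical gives a sure state
  one <- hmm_model(matrix(1), 1, list(diag(3)))
  expect_true(all(infer_with_canonical_states(one, Y)$gamma == 1))
  # permuted canonical model permutes gamma columns identically
  gperm <- hmm_model(gen$transition[2:1, 2:1], gen$initial[2:1],
                     gen$covariances[2:1])
  p2 <- infer_with_canonical_states(gperm, Y, re_estimate_transition = FALSE)
  p1 <- infer_with_canonical_states(gen, Y, re_estimate_transition = FALSE)
  expect_equal(p2$gamma, p1$gamma[, 2:1], tolerance = 1e-10)
})

test_that("fractional_occupancy sums to one and counts hard sequences", {
  g <- matrix(rep(c(0.3, 0.7), each = 50), 50, 2)
  expect_equal(fractional_occupancy(g), c(0.3, 0.7))
  st <- rep(c(1, 2, 2, 2), 25)
  gh <- cbind(st == 1, st == 2) * 1
  expect_equal(fractional_occupancy(gh), c(0.25, 0.75))
  set.seed(12)
  gr <- matrix(rexp(300), 100, 3); gr <- gr / rowSums(gr)
  expect_equal(sum(fractional_occupancy(gr)), 1, tolerance = 1e-10)
})

test_that("match_states finds the optimal assignment", {
  set.seed(13)
  covs <- lapply(1:4, function(k) rand_pd(5, k))
  A <- diag(4) * 0.7 + 0.1; A <- A / rowSums(A)
  ref <- hmm_model(A, rep(.25, 4), covs)
  expect_equal(match_states(ref, ref), 1:4)
  swap <- hmm_model(A, rep(.25, 4), covs[c(2, 1, 3, 4)])
  expect_equal(match_states(swap, ref), c(2, 1, 3, 4))
  # noisy copies over 20 replicates
  ok <- vapply(1:20, function(r) {
    set.seed(100 + r)
    prm <- sample(4)
    noisy <- lapply(covs[prm], function(S) {
      E <- matrix(rnorm(25, sd = 0.05), 5)
      S + (E + t(E)) / 2 * mean(diag(S))
    })
    noisy <- lapply(noisy, function(S) S + diag(5) * 0.1)
    est <- hmm_model(A, rep(.25, 4), noisy)
    identical(match_states(est, ref), prm)
  }, TRUE)
  expect_true(all(ok))
})
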