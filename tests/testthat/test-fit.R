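test_that("the single-state spherical fit has its closed form", {
  set.seed(31)
  par <- mvhmm_params(1, matrix(1), list(matrix(2, 2, 2)),
                      list(1.5 * diag(2)), list(diag(2)))
  sim <- simulate_mvhmm(par, I = 20, T = 4, seed = 1)
  fit <- mvhmm(sim$data, "EII-II", K = 1, init_runs = 1, seed = 2)
  d <- dim(sim$data$values)
  Xbar <- apply(sim$data$values, c(3, 4), mean)
  expect_equal(fit$params$M[[1]], Xbar, tolerance = 1e-8)
  # lambda-hat = total squared deviation / (P R T I)
  lam_hat <- sum(vapply(1:20, function(i) {
    sum(vapply(1:4, function(t) {
      sum((obs_matrix(sim$data, i, t) - Xbar)^2)
    }, numeric(1)))
  }, numeric(1))) / prod(d)
  expect_equal(fit$params$Sigma[[1]][1, 1], lam_hat, tolerance = 1e-6)
  expect_lte(fit$n_iter, 3)
  expect_true(fit$converged)
})

test_that("chain and mean updates match direct summation on a toy posterior", {
  set.seed(32)
  vals <- array(stats::rnorm(2 * 2 * 2 * 2), c(2, 2, 2, 2))
  fw <- fourway(vals)
  z <- array(0, c(2, 2, 2))
  z[1, , ] <- rbind(c(0.9, 0.1), c(0.3, 0.7))
  z[2, , ] <- rbind(c(0.2, 0.8), c(0.6, 0.4))
  zz <- array(0, c(2, 1, 2, 2))
  zz[1, 1, , ] <- rbind(c(0.25, 0.65), c(0.05, 0.05))
  zz[2, 1, , ] <- rbind(c(0.1, 0.1), c(0.5, 0.3))
  post <- structure(list(z = z, zz = zz), class = "mvhmm_posteriors")
  up <- update_chain_and_means(post, fw)
  expect_equal(up$pi, c((0.9 + 0.2) / 2, (0.1 + 0.8) / 2))
  num <- zz[1, 1, , ] + zz[2, 1, , ]
  expect_equal(up$Pi, num / rowSums(num))
  for (k in 1:2) {
    num_M <- matrix(0, 2, 2); den <- 0
    for (i in 1:2) for (t in 1:2) {
      num_M <- num_M + z[i, t, k] * vals[i, t, , ]
      den <- den + z[i, t, k]
    }
    expect_equal(up$M[[k]], num_M / den, tolerance = 1e-12)
  }
})

test_that("hard single-state memberships give the pooled mean", {
  set.seed(33)
  vals <- array(stats::rnorm(3 * 2 * 2 * 2), c(3, 2, 2, 2))
  fw <- fourway(vals)
  z <- array(0, c(3, 2, 2)); z[, , 1] <- 1
  zz <- array(0, c(3, 1, 2, 2)); zz[, 1, 1, 1] <- 1
  post <- structure(list(z = z, zz = zz), class = "mvhmm_posteriors")
  expect_error(update_chain_and_means(post, fw), "state 2")
  # uniform memberships: every state mean equals the grand mean
  z[] <- 0.5; zz[] <- 0.25
  post <- structure(list(z = z, zz = zz), class = "mvhmm_posteriors")
  up <- update_chain_and_means(post, fw)
  expect_equal(up$M[[1]], up$M[[2]], tolerance = 1e-12)
  expect_equal(up$M[[1]], apply(vals, c(3, 4), mean), tolerance = 1e-12)
})

test_that("the ECM trace is monotone and recovery is accurate when separated", {
  set.seed(34)
  par <- toy_params_k2(sep = 4)
  sim <- simulate_mvhmm(par, I = 100, T = 5, seed = 11)
  fit <- mvhmm(sim$data, "EII-II", K = 2, init_runs = 10, seed = 12)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
  for (k in 1:2) {
    expect_lt(max(abs(fit$params$M[[k]] - par$M[[k]])), 0.1)
  }
  expect_equal(fit$n_params, 12)
  expect_equal(fit$bic, -2 * fit$loglik + 12 * log(500), tolerance = 1e-10)
})

test_that("every ECM sweep ascends across a spread of structure pairs", {
  set.seed(35)
  pre <- scenario_preset("D1-T1-K2-O1", model = "VVE-EV")
  sim <- simulate_mvhmm(pre$params, I = 25, T = 4, seed = 21)
  for (s in c("VII-EI", "VEI-VI", "EVE-VE", "VVE-EV", "VEV-EE", "EVV-VV")) {
    fit <- mvhmm(sim$data, s, K = 2, init_runs = 3, seed = 22, max_iter = 150,
                 tol = 1e-7)
    expect_true(all(diff(fit$loglik_trace) > -1e-8), label = s)
    for (k in 1:2) {
      expect_equal(det(fit$params$Psi[[k]]), 1, tolerance = 1e-8)
    }
  }
})

test_that("a more general structure attains at least the nested likelihood", {
  set.seed(36)
  pre <- scenario_preset("D1-T1-K2-O2", model = "VVE-EV")
  sim <- simulate_mvhmm(pre$params, I = 40, T = 5, seed = 31)
  row_chain <- c("EII-II", "EEI-EI", "EEE-EE", "VVV-VV")
  prev <- NULL
  lls <- numeric(0)
  for (s in row_chain) {
    fit <- if (is.null(prev)) {
      mvhmm(sim$data, s, K = 2, init_runs = 10, seed = 32, tol = 1e-8)
    } else {
      mvhmm(sim$data, s, K = 2, seed = 32, tol = 1e-8, start = prev$params)
    }
    lls <- c(lls, fit$loglik)
    prev <- fit
  }
  expect_true(all(diff(lls) >= -1e-6))
})

test_that("short-EM initialization is seed-deterministic", {
  set.seed(37)
  par <- toy_params_k2(sep = 3)
  sim <- simulate_mvhmm(par, I = 30, T = 4, seed = 41)
  s1 <- short_em_init(sim$data, "EII-II", K = 2, H = 10, s = 1, seed = 5)
  s2 <- short_em_init(sim$data, "EII-II", K = 2, H = 10, s = 1, seed = 5)
  expect_equal(s1$M, s2$M, tolerance = 1e-15)
  expect_equal(s1$Pi, s2$Pi, tolerance = 1e-15)
  f1 <- mvhmm(sim$data, "EII-II", K = 2, init_runs = 8, seed = 6)
  f2 <- mvhmm(sim$data, "EII-II", K = 2, init_runs = 8, seed = 6)
  expect_identical(f1$loglik, f2$loglik)
  expect_identical(f1$labels, f2$labels)
})

test_that("many short starts beat a handful of full starts almost always", {
  set.seed(38)
  par <- toy_params_k2(sep = 4)
  wins <- 0L
  n_rep <- 10
  for (r in seq_len(n_rep)) {
    sim <- simulate_mvhmm(par, I = 30, T = 4, seed = 100 + r)
    f_short <- mvhmm(sim$data, "EII-II", K = 2, init_runs = 100,
                     init_iters = 1, seed = 200 + r)
    single <- vapply(1:10, function(j) {
      mvhmm(sim$data, "EII-II", K = 2, init_runs = 1, seed = 300 + 10 * r + j)$loglik
    }, numeric(1))
    if (f_short$loglik >= max(single) - 1e-6) wins <- wins + 1L
  }
  expect_gte(wins, ceiling(0.9 * n_rep))
})

test_that("states come back ordered by their mean level with consistent permutation", {
  set.seed(39)
  par <- toy_params_k2(sep = 4)
  sim <- simulate_mvhmm(par, I = 60, T = 5, seed = 51)
  fit <- mvhmm(sim$data, "VVI-VI", K = 2, init_runs = 10, seed = 52)
  keys <- vapply(fit$params$M, mean, numeric(1))
  expect_true(all(diff(keys) > 0))
  # alignment is idempotent and leaves the likelihood of the stored
  # parameters unchanged
  re <- align_labels(fit)
  expect_equal(re$params$Pi, fit$params$Pi)
  ll <- forward_backward(sim$data, fit$params)$loglik
  expect_equal(ll, fit$loglik, tolerance = 1e-8)
  # manually scrambling the states and re-aligning restores the original
  scr <- fit
  perm <- c(2, 1)
  scr$params <- matrixhmm:::permute_params(fit$params, perm)
  scr$decomp <- matrixhmm:::permute_decomp(fit$decomp, perm)
  scr$posteriors$z <- fit$posteriors$z[, , perm, drop = FALSE]
  scr$posteriors$zz <- fit$posteriors$zz[, , perm, perm, drop = FALSE]
  scr$labels <- matrix(match(fit$labels, perm), nrow(fit$labels))
  back <- align_labels(scr)
  expect_equal(back$params$M, fit$params$M, tolerance = 1e-12)
  expect_equal(back$params$Pi, fit$params$Pi, tolerance = 1e-12)
  expect_identical(back$labels, fit$labels)
  ll_scr <- forward_backward(sim$data, scr$params)$loglik
  expect_equal(ll_scr, fit$loglik, tolerance = 1e-10)
})

test_that("invalid state counts and structures are rejected", {
  sim <- simulate_mvhmm(toy_params_k2(), I = 5, T = 3, seed = 61)
  expect_error(mvhmm(sim$data, "EII-II", K = 0), "at least 1")
  expect_error(mvhmm(sim$data, "ABC-II", K = 2), "unknown structure")
  expect_error(mvhmm(sim$data, "EII-XX", K = 2), "unknown structure")
})
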