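# Shared machinery: random scatter instances and repeated application of the
# conditional updates until the prev-dependent structures reach a fixed point.

random_scatter_instance <- function(K, Q, n_scale = 20) {
  weights <- stats::rgamma(K, 5) * n_scale / K
  scatters <- lapply(seq_len(K), function(k) weights[k] * rpd(Q))
  list(scatters = scatters, weights = weights)
}

iterate_sigma <- function(code, inst, dims, n_sweeps = 25) {
  prev <- NULL
  for (s in seq_len(n_sweeps)) {
    prev <- update_sigma(code, inst$scatters, inst$weights, dims, prev = prev)
  }
  prev
}

iterate_psi <- function(code, inst, n_sweeps = 25) {
  prev <- NULL
  for (s in seq_len(n_sweeps)) {
    prev <- update_psi(code, inst$scatters, inst$weights, prev = prev)
  }
  prev
}

test_that("spherical and unconstrained updates reproduce their closed forms", {
  # lambda = tr(Y) / (P R T I) for the spherical equal-volume structure
  out <- update_sigma("EII", list(diag(c(2, 2))), weights = 1,
                      dims = list(P = 2, R = 1, T = 1, I = 1))
  expect_equal(out$lam[1], 2)
  expect_equal(out$Sigma[[1]], 2 * diag(2))
  # Sigma_k = Y_k / (R n_k) for the unconstrained structure
  set.seed(11)
  Y1 <- rpd(3)
  out <- update_sigma("VVV", list(Y1), weights = 10,
                      dims = list(P = 3, R = 1, T = 10, I = 1))
  expect_equal(out$Sigma[[1]], Y1 / 10, tolerance = 1e-10)
})

test_that("column updates keep unit determinants and match printed forms", {
  out <- update_psi("II", list(diag(2) * 3), weights = 5)
  expect_equal(out$Psi[[1]], diag(2))
  out <- update_psi("EE", list(diag(c(4, 1))), weights = 5)
  expect_equal(out$Psi[[1]], diag(c(2, 0.5)), tolerance = 1e-10)
  set.seed(12)
  for (code in col_structure_codes) {
    inst <- random_scatter_instance(K = 3, Q = 3)
    out <- update_psi(code, inst$scatters, inst$weights)
    for (k in 1:3) {
      expect_equal(det(out$Psi[[k]]), 1, tolerance = 1e-8,
                   label = paste(code, "det"))
    }
  }
})

test_that("MM rotation is orthogonal, monotone, and matches closed forms", {
  set.seed(13)
  # spherical shape: any rotation attains the same criterion
  Y <- rpd(3)
  G <- mm_rotation(list(Y), list(rep(1, 3)), init = rorth(3))
  expect_lt(max(abs(crossprod(G) - diag(3))), 1e-8)
  expect_equal(sum(diag(Y %*% G %*% t(G))), sum(diag(Y)), tolerance = 1e-10)

  # identical scatters and shapes: optimum aligns eigenvectors of Y with the
  # shape so that descending eigenvalues meet ascending 1/delta
  Y <- rpd(3)
  d <- sort(exp(c(0.8, 0, -0.8)), decreasing = TRUE)
  d <- d / exp(mean(log(d)))
  ev <- eigen(Y, symmetric = TRUE)
  best <- sum(ev$values / d)  # rearrangement optimum: both sorted descending
  # descent is local, so start from a handful of rotations and keep the best
  got <- min(vapply(1:5, function(s) {
    G <- mm_rotation(rep(list(Y), 3), rep(list(d), 3), init = rorth(3),
                     max_iter = 5000, tol = 1e-14)
    sum(diag(Y %*% G %*% ((1 / d) * t(G))))
  }, numeric(1)))
  expect_equal(got, best, tolerance = 1e-6)

  # Q = 2 random instances against the angle-grid oracle
  for (i in 1:3) {
    Ys <- lapply(1:3, function(k) rpd(2))
    ds <- lapply(1:3, function(k) {
      v <- exp(stats::runif(2, -1, 1)); v / exp(mean(log(v)))
    })
    G <- mm_rotation(Ys, ds, init = diag(2))
    got <- sum(vapply(1:3, function(k) {
      sum(diag(Ys[[k]] %*% G %*% ((1 / ds[[k]]) * t(G))))
    }, numeric(1)))
    expect_lt(got - angle_grid_min(Ys, ds), 1e-4)
  }
  expect_error(mm_rotation(list(diag(2)), list(rep(1, 2)),
                           init = matrix(1, 2, 2)), "orthogonal")
})

test_that("rotation-based updates reach the planar joint optimizer", {
  set.seed(14)
  dims <- list(P = 2, R = 1, T = 10, I = 2)
  for (code in c("EVE", "VVE")) {
    inst <- random_scatter_instance(K = 2, Q = 2)
    out <- iterate_sigma(code, inst, dims)
    # profile objective in Gamma after maximizing Delta_k coordinate-wise
    scat <- if (code == "VVE") Map(`/`, inst$scatters, out$lam) else inst$scatters
    prof <- function(G) {
      sum(vapply(1:2, function(k) {
        d <- diag(t(G) %*% scat[[k]] %*% G)
        d <- pmax(d, 1e-12)
        sum(d / (d / exp(mean(log(d)))))
      }, numeric(1)))
    }
    thetas <- seq(0, pi, length.out = 1e4)
    grid_best <- min(vapply(thetas, function(th) {
      prof(matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2))
    }, numeric(1)))
    expect_lt(prof(out$Gamma[[1]]) - grid_best, 1e-4, label = code)
  }
})

test_that("every row estimator beats random admissible draws", {
  set.seed(15)
  dims2 <- list(P = 2, R = 2, T = 10, I = 2)
  for (code in row_structure_codes) {
    inst <- random_scatter_instance(K = 2, Q = 2)
    dims2$T <- 1; dims2$I <- sum(inst$weights)  # align N with the weights
    est <- iterate_sigma(code, inst, dims2)
    obj_est <- matrixhmm:::sigma_objective(est$Sigma, inst$scatters,
                                           inst$weights, R = dims2$R)
    draws <- replicate(200, {
      S <- random_admissible_sigma(code, K = 2, Q = 2)
      matrixhmm:::sigma_objective(S, inst$scatters, inst$weights, R = dims2$R)
    })
    expect_true(all(obj_est >= draws - 1e-8), label = code)
  }
})

test_that("every column estimator beats random admissible draws", {
  set.seed(16)
  for (code in col_structure_codes) {
    inst <- random_scatter_instance(K = 2, Q = 2)
    est <- iterate_psi(code, inst)
    obj_est <- matrixhmm:::psi_objective(est$Psi, inst$scatters,
                                         inst$weights, P = 2)
    draws <- replicate(200, {
      S <- random_admissible_psi(code, K = 2, Q = 2)
      matrixhmm:::psi_objective(S, inst$scatters, inst$weights, P = 2)
    })
    expect_true(all(obj_est >= draws - 1e-8), label = code)
  }
})

test_that("closed-form structures match a general-purpose optimizer", {
  set.seed(17)
  # EEI: diagonal equal-shape equal-volume; optimize over log-diagonal
  inst <- random_scatter_instance(K = 2, Q = 3)
  N <- sum(inst$weights)
  dims <- list(P = 3, R = 2, T = 1, I = N)
  est <- update_sigma("EEI", inst$scatters, inst$weights, dims)
  obj <- function(logd) {
    S <- rep(list(diag(exp(logd))), 2)
    -matrixhmm:::sigma_objective(S, inst$scatters, inst$weights, R = 2)
  }
  opt <- stats::optim(rep(0, 3), obj, method = "L-BFGS-B",
                      lower = -4, upper = 8)
  expect_equal(matrixhmm:::sigma_objective(est$Sigma, inst$scatters,
                                           inst$weights, R = 2),
               -opt$value, tolerance = 1e-6)
  # VII: per-state spherical; closed form vs direct 1-D optimization
  est <- update_sigma("VII", inst$scatters, inst$weights, dims)
  for (k in 1:2) {
    o1 <- stats::optimize(function(l) {
      -matrixhmm:::sigma_objective(list(l * diag(3)), inst$scatters[k],
                                   inst$weights[k], R = 2)
    }, c(1e-3, 100))
    expect_equal(est$lam[k], o1$minimum, tolerance = 1e-4)
  }
})

test_that("E-constrained components are shared and V-constrained may differ", {
  set.seed(18)
  inst <- random_scatter_instance(K = 3, Q = 3)
  dims <- list(P = 3, R = 2, T = 5, I = 4)
  out <- update_sigma("VEE", inst$scatters, inst$weights, dims)
  expect_identical(out$Gamma[[1]], out$Gamma[[2]])
  expect_identical(out$delta[[1]], out$delta[[3]])
  expect_gt(stats::sd(out$lam), 0)
  out <- update_sigma("EEV", inst$scatters, inst$weights, dims)
  expect_identical(out$delta[[1]], out$delta[[2]])
  expect_equal(out$lam[1], out$lam[3])
  expect_gt(max(abs(out$Gamma[[1]] - out$Gamma[[2]])), 1e-6)
})

test_that("degenerate state weights raise an identifiable error", {
  expect_error(
    update_sigma("EII", list(diag(2), diag(2)), weights = c(5, 0),
                 dims = list(P = 2, R = 2, T = 5, I = 2)),
    "state 2"
  )
})

test_that("a full CM sweep never decreases the conditional objective", {
  # fixed responsibilities; one sigma-then-psi sweep on the complete-data
  # objective, across all 98 structure pairs
  set.seed(19)
  K <- 2; P <- 2; R <- 2; I <- 6; T <- 4; N <- I * T
  X <- lapply(seq_len(N), function(n) matrix(stats::rnorm(P * R, sd = 2), P, R))
  z <- t(replicate(N, rsimplex(K)))
  M <- lapply(seq_len(K), function(k) {
    Reduce(`+`, Map(`*`, X, z[, k])) / sum(z[, k])
  })
  ecd_obj <- function(Sig, Psi) {
    sum(vapply(seq_len(K), function(k) {
      sum(vapply(seq_len(N), function(n) {
        z[n, k] * dmatnorm(X[[n]], M[[k]], Sig[[k]], Psi[[k]])
      }, numeric(1)))
    }, numeric(1)))
  }
  scatY <- function(Psi) lapply(seq_len(K), function(k) {
    Reduce(`+`, lapply(seq_len(N), function(n) {
      E <- X[[n]] - M[[k]]
      z[n, k] * E %*% solve(Psi[[k]]) %*% t(E)
    }))
  })
  scatW <- function(Sig) lapply(seq_len(K), function(k) {
    Reduce(`+`, lapply(seq_len(N), function(n) {
      E <- X[[n]] - M[[k]]
      z[n, k] * t(E) %*% solve(Sig[[k]]) %*% E
    }))
  })
  nk <- colSums(z)
  sp <- structure_pairs()
  for (r in seq_len(nrow(sp))) {
    Sig0 <- rep(list(diag(P)), K)
    Psi0 <- rep(list(diag(R)), K)
    before <- ecd_obj(Sig0, Psi0)
    sig <- update_sigma(sp$row_code[r], scatY(Psi0), nk,
                        dims = list(P = P, R = R, T = T, I = I))
    mid <- ecd_obj(sig$Sigma, Psi0)
    psi <- update_psi(sp$col_code[r], scatW(sig$Sigma), nk)
    after <- ecd_obj(sig$Sigma, psi$Psi)
    expect_gte(mid, before - 1e-8)
    expect_gte(after, mid - 1e-8)
  }
})
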