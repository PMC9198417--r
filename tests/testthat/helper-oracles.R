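# Independent oracles and random-instance generators used across the suite.
# These are deliberately naive (enumeration, dense vec/Kronecker algebra,
# 1-D grid search) and never share code with the package internals they check.

rpd <- function(q, scale = 1) {
  A <- matrix(stats::rnorm(q * q), q)
  scale * (crossprod(A) / q + diag(q))
}

runit_det <- function(q) {
  S <- rpd(q)
  S / det(S)^(1 / q)
}

rsimplex <- function(k) {
  x <- stats::rgamma(k, 2)
  x / sum(x)
}

rtrans <- function(k) {
  m <- matrix(stats::rgamma(k * k, 2), k)
  m / rowSums(m)
}

rorth <- function(q) {
  qr.Q(qr(matrix(stats::rnorm(q * q), q)))
}

# Generic multivariate-normal log-density on the column-stacked observation;
# the Kronecker identity vec(X) ~ N(vec(M), Psi %x% Sigma) makes this an
# independent check of the matrix-normal density.
mvn_vec_logdens <- function(X, M, Sigma, Psi) {
  x <- as.vector(as.matrix(X))
  mu <- as.vector(as.matrix(M))
  V <- Psi %x% Sigma
  U <- chol(V)
  e <- backsolve(U, x - mu, transpose = TRUE)
  -0.5 * length(x) * log(2 * pi) - sum(log(diag(U))) - 0.5 * sum(e * e)
}

# Exhaustive path-enumeration log-likelihood for one unit's sequence of
# matrices, and the matching exact posteriors.
enum_unit <- function(X_list, pi0, Pi, M, Sigma, Psi) {
  T <- length(X_list)
  K <- length(pi0)
  dens <- sapply(seq_len(K), function(k) {
    sapply(X_list, function(X) {
      exp(mvn_vec_logdens(X, M[[k]], Sigma[[k]], Psi[[k]]))
    })
  })
  dens <- matrix(dens, T, K)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T)))
  pp <- apply(paths, 1, function(s) {
    p <- pi0[s[1]] * dens[1, s[1]]
    if (T > 1) for (t in 2:T) p <- p * Pi[s[t - 1], s[t]] * dens[t, s[t]]
    p
  })
  tot <- sum(pp)
  z <- matrix(0, T, K)
  zz <- array(0, c(T - 1, K, K))
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    w <- pp[r] / tot
    for (t in seq_len(T)) z[t, s[t]] <- z[t, s[t]] + w
    if (T > 1) for (t in 2:T) zz[t - 1, s[t - 1], s[t]] <-
        zz[t - 1, s[t - 1], s[t]] + w
  }
  list(loglik = log(tot), z = z, zz = zz)
}

# 1-D angle-grid minimizer of the rotation criterion
# sum_k tr(Y_k G(theta) Delta_k^-1 G(theta)') over planar rotations (Q = 2).
angle_grid_min <- function(Ys, deltas, n_grid = 1e4) {
  thetas <- seq(0, pi, length.out = n_grid)
  vals <- vapply(thetas, function(th) {
    G <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    sum(vapply(seq_along(Ys), function(k) {
      sum(diag(Ys[[k]] %*% G %*% ((1 / deltas[[k]]) * t(G))))
    }, numeric(1)))
  }, numeric(1))
  min(vals)
}

# Random admissible covariance draws for the estimator-optimality screen.
random_admissible_sigma <- function(code, K, Q) {
  vol <- function(shared) if (shared) rep(exp(stats::rnorm(1)), K) else
    exp(stats::rnorm(K))
  shp <- function(shared) {
    one <- function() { d <- exp(stats::rnorm(Q)); d / exp(mean(log(d))) }
    if (shared) rep(list(one()), K) else replicate(K, one(), simplify = FALSE)
  }
  ori <- function(shared) {
    if (shared) rep(list(rorth(Q)), K) else
      replicate(K, rorth(Q), simplify = FALSE)
  }
  idm <- rep(list(diag(Q)), K)
  ones <- rep(list(rep(1, Q)), K)
  parts <- switch(code,
    EII = list(vol(TRUE), idm, ones),
    VII = list(vol(FALSE), idm, ones),
    EEI = list(vol(TRUE), idm, shp(TRUE)),
    VEI = list(vol(FALSE), idm, shp(TRUE)),
    EVI = list(vol(TRUE), idm, shp(FALSE)),
    VVI = list(vol(FALSE), idm, shp(FALSE)),
    EEE = list(vol(TRUE), ori(TRUE), shp(TRUE)),
    VEE = list(vol(FALSE), ori(TRUE), shp(TRUE)),
    EVE = list(vol(TRUE), ori(TRUE), shp(FALSE)),
    VVE = list(vol(FALSE), ori(TRUE), shp(FALSE)),
    EEV = list(vol(TRUE), ori(FALSE), shp(TRUE)),
    VEV = list(vol(FALSE), ori(FALSE), shp(TRUE)),
    EVV = list(vol(TRUE), ori(FALSE), shp(FALSE)),
    VVV = list(vol(FALSE), ori(FALSE), shp(FALSE))
  )
  lapply(seq_len(K), function(k) {
    lam <- parts[[1]][k]
    G <- parts[[2]][[k]]
    d <- parts[[3]][[k]]
    lam * G %*% (d * t(G))
  })
}

random_admissible_psi <- function(code, K, Q) {
  # the column structures are the row structures with the volume fixed at 1
  row_equiv <- c(II = "EII", EI = "EEI", VI = "EVI", EE = "EEE",
                 VE = "EVE", EV = "EEV", VV = "EVV")
  draws <- random_admissible_sigma(row_equiv[[code]], K, Q)
  lapply(draws, function(S) S / det(S)^(1 / Q))
}

# Numerical free-parameter count of a constrained covariance set: the rank of
# the Jacobian of a smooth parameterization (volume on the log scale, shape
# through sum-free log coordinates, orientation through the Cayley transform
# of a skew-symmetric matrix) evaluated at a generic point. Discrete
# redundancies do not affect the rank; the one continuous redundancy (the
# shape block's constant direction) removes exactly one rank unit per block,
# matching the |Delta| = 1 constraint.
perturbation_rank <- function(side, code, K, Q) {
  if (side == "col") {
    row_equiv <- c(II = "EII", EI = "EEI", VI = "EVI", EE = "EEE",
                   VE = "EVE", EV = "EEV", VV = "EVV")
    code <- row_equiv[[code]]
    fixed_volume <- TRUE
  } else fixed_volume <- FALSE
  letters3 <- strsplit(code, "")[[1]]
  nvol <- if (fixed_volume) 0 else if (letters3[1] == "E") 1 else K
  nshape_blocks <- if (letters3[2] == "I") 0 else if (letters3[2] == "E") 1 else K
  nskew <- Q * (Q - 1) / 2
  nori_blocks <- if (letters3[3] == "I") 0 else if (letters3[3] == "E") 1 else K
  n_theta <- nvol + nshape_blocks * Q + nori_blocks * nskew

  build <- function(theta) {
    pos <- 0
    lam <- if (fixed_volume) rep(1, K) else if (nvol == 1) {
      pos <- 1; rep(exp(theta[1]), K)
    } else { pos <- K; exp(theta[1:K]) }
    deltas <- if (nshape_blocks == 0) rep(list(rep(1, Q)), K) else {
      blocks <- lapply(seq_len(nshape_blocks), function(b) {
        u <- theta[pos + (b - 1) * Q + seq_len(Q)]
        exp(u - mean(u))
      })
      pos <- pos + nshape_blocks * Q
      if (nshape_blocks == 1) rep(blocks, K) else blocks
    }
    gammas <- if (nori_blocks == 0) rep(list(diag(Q)), K) else {
      blocks <- lapply(seq_len(nori_blocks), function(b) {
        a <- theta[pos + (b - 1) * nskew + seq_len(nskew)]
        A <- matrix(0, Q, Q)
        A[upper.tri(A)] <- a
        A <- A - t(A)
        solve(diag(Q) + A, diag(Q) - A)  # Cayley transform
      })
      pos <- pos + nori_blocks * nskew
      if (nori_blocks == 1) rep(blocks, K) else blocks
    }
    unlist(lapply(seq_len(K), function(k) {
      S <- lam[k] * gammas[[k]] %*% (deltas[[k]] * t(gammas[[k]]))
      S[upper.tri(S, diag = TRUE)]
    }))
  }

  if (n_theta == 0) return(0L)
  theta0 <- stats::rnorm(n_theta, sd = 0.3)
  h <- 1e-6
  J <- vapply(seq_len(n_theta), function(j) {
    tp <- theta0; tm <- theta0
    tp[j] <- tp[j] + h; tm[j] <- tm[j] - h
    (build(tp) - build(tm)) / (2 * h)
  }, numeric(K * Q * (Q + 1) / 2))
  qr(matrix(J, ncol = n_theta))$rank
}

# Quick well-separated two-state test model (P = R = 2).
toy_params_k2 <- function(sep = 4, row_code = "EII", col_code = "II") {
  mvhmm_params(
    pi = c(0.5, 0.5),
    Pi = rbind(c(0.9, 0.1), c(0.1, 0.9)),
    M = list(matrix(0, 2, 2), matrix(sep, 2, 2)),
    Sigma = rep(list(diag(2)), 2),
    Psi = rep(list(diag(2)), 2),
    row_code = row_code, col_code = col_code
  )
}
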