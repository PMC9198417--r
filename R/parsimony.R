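# Constrained conditional-maximization updates for the state covariance
# matrices, from responsibility-weighted scatter matrices.
#
# Row side: Y_k = sum_it z_itk (X_it - M_k) Psi_k^-1 (X_it - M_k)'  (P x P)
# Col side: W_k = sum_it z_itk (X_it - M_k)' Sigma_k^-1 (X_it - M_k)  (R x R)
#
# Closed forms exist for most structures; EEV/VEV (and EV) use the eigen
# decomposition of each scatter, and EVE/VVE (and VE) use an iterative
# minorization-maximization (MM) update of the shared orientation matrix.

#' Row-covariance CM update
#'
#' Computes the conditional maximizer of the expected complete-data
#' log-likelihood over the row covariances \eqn{\Sigma_1,\dots,\Sigma_K}
#' under one of the 14 parsimonious structures, given per-state row scatter
#' matrices and state weights.
#'
#' @param code One of the 14 row structure codes (see [structure_codes]).
#' @param scatters List of `K` positive semi-definite `P x P` scatter
#'   matrices \eqn{Y_k}.
#' @param weights Numeric vector of state weights \eqn{n_k = \sum_{it} z_{itk}}.
#' @param dims Named list or vector with the data dimensions `P`, `R`, `T`, `I`.
#' @param prev Previous-iteration decomposition, a list with `lam` (length-`K`
#'   volumes), `Gamma` (list of orientation matrices) and `delta` (list of
#'   shape vectors). Required by the structures whose printed update involves
#'   previous-iteration values (VEI, VEE, VEV, EVE, VVE); identity/unit values
#'   are used when omitted.
#' @param control List with MM inner-loop settings `mm_max_iter` and `mm_tol`.
#'
#' @return A list with `Sigma` (list of `K` matrices), `lam`, `Gamma`, `delta`
#'   (per-state decomposition components; E-constrained components are the
#'   same object across states).
#' @export
update_sigma <- function(code, scatters, weights, dims,
                         prev = NULL, control = list()) {
  code <- match.arg(code, row_structure_codes)
  dims <- as.list(dims)
  P <- dims$P; R <- dims$R
  K <- length(scatters)
  N <- dims$T * dims$I
  check_scatters(scatters, weights, P)
  prev <- default_decomp(prev, K, P)
  ctrl <- mm_control(control)

  lam <- NULL; Gam <- NULL; del <- NULL
  trY <- vapply(scatters, function(Y) sum(diag(Y)), numeric(1))
  switch(code,
    EII = {
      l <- sum(trY) / (P * R * N)
      lam <- rep(l, K); Gam <- shared(diag(P), K); del <- shared(rep(1, P), K)
    },
    VII = {
      lam <- trY / (P * R * weights)
      Gam <- shared(diag(P), K); del <- shared(rep(1, P), K)
    },
    EEI = {
      Y <- Reduce(`+`, scatters)
      d <- diag_vec(Y)
      gd <- exp(mean(log(d)))
      lam <- rep(gd / (R * N), K)
      Gam <- shared(diag(P), K); del <- shared(d / gd, K)
    },
    VEI = {
      Yw <- Reduce(`+`, Map(function(Y, l) Y / l, scatters, prev$lam))
      d <- diag_vec(Yw)
      dd <- d / exp(mean(log(d)))
      lam <- vapply(seq_len(K), function(k) {
        sum(diag_vec(scatters[[k]]) / dd) / (P * R * weights[k])
      }, numeric(1))
      Gam <- shared(diag(P), K); del <- shared(dd, K)
    },
    EVI = {
      ds <- lapply(scatters, diag_vec)
      gds <- vapply(ds, function(d) exp(mean(log(d))), numeric(1))
      lam <- rep(sum(gds) / (R * N), K)
      Gam <- shared(diag(P), K)
      del <- Map(`/`, ds, gds)
    },
    VVI = {
      ds <- lapply(scatters, diag_vec)
      gds <- vapply(ds, function(d) exp(mean(log(d))), numeric(1))
      lam <- gds / (R * weights)
      Gam <- shared(diag(P), K)
      del <- Map(`/`, ds, gds)
    },
    EEE = {
      S <- Reduce(`+`, scatters) / (R * N)
      dc <- decompose_cov(S)
      lam <- rep(dc$lam, K); Gam <- shared(dc$Gamma, K); del <- shared(dc$delta, K)
    },
    VEE = {
      Yw <- Reduce(`+`, Map(function(Y, l) Y / l, scatters, prev$lam))
      C <- Yw / det(Yw)^(1 / P)
      Cinv <- solve(C)
      lam <- vapply(seq_len(K), function(k) {
        sum(Cinv * scatters[[k]]) / (P * R * weights[k])
      }, numeric(1))
      dc <- decompose_cov(C)
      Gam <- shared(dc$Gamma, K); del <- shared(dc$delta, K)
    },
    EVE = {
      G <- mm_rotation(scatters, prev$delta, init = prev$Gamma[[1]],
                       max_iter = ctrl$mm_max_iter, tol = ctrl$mm_tol)
      ds <- lapply(scatters, function(Y) diag_vec(t(G) %*% Y %*% G))
      gds <- vapply(ds, function(d) exp(mean(log(d))), numeric(1))
      del <- Map(`/`, ds, gds)
      l <- sum(vapply(seq_len(K), function(k) {
        sum(diag(G %*% ((1 / del[[k]]) * t(G)) %*% scatters[[k]]))
      }, numeric(1))) / (P * R * N)
      lam <- rep(l, K); Gam <- shared(G, K)
    },
    VVE = {
      # the rotation criterion carries the per-state volumes:
      # sum_k tr(Y_k Gamma Delta_k^-1 Gamma') / lambda_k at previous lambdas
      G <- mm_rotation(Map(`/`, scatters, prev$lam), prev$delta,
                       init = prev$Gamma[[1]],
                       max_iter = ctrl$mm_max_iter, tol = ctrl$mm_tol)
      ds <- lapply(scatters, function(Y) diag_vec(t(G) %*% Y %*% G))
      gds <- vapply(ds, function(d) exp(mean(log(d))), numeric(1))
      del <- Map(`/`, ds, gds)
      lam <- gds / (R * weights)
      Gam <- shared(G, K)
    },
    EEV = {
      eg <- lapply(scatters, eigen_pieces)
      om <- Reduce(`+`, lapply(eg, `[[`, "omega"))
      gom <- exp(mean(log(om)))
      lam <- rep(gom / (R * N), K)
      Gam <- lapply(eg, `[[`, "L")
      del <- shared(om / gom, K)
    },
    VEV = {
      eg <- lapply(scatters, eigen_pieces)
      om <- Reduce(`+`, Map(function(e, l) e$omega / l, eg, prev$lam))
      dd <- om / exp(mean(log(om)))
      lam <- vapply(seq_len(K), function(k) {
        sum(eg[[k]]$omega / dd) / (P * R * weights[k])
      }, numeric(1))
      Gam <- lapply(eg, `[[`, "L")
      del <- shared(dd, K)
    },
    EVV = {
      dets <- vapply(scatters, function(Y) det(Y)^(1 / P), numeric(1))
      l <- sum(dets) / (R * N)
      lam <- rep(l, K)
      dcs <- Map(function(Y, d) decompose_cov(Y / d), scatters, dets)
      Gam <- lapply(dcs, `[[`, "Gamma"); del <- lapply(dcs, `[[`, "delta")
    },
    VVV = {
      Ss <- Map(function(Y, n) Y / (R * n), scatters, weights)
      dcs <- lapply(Ss, decompose_cov)
      lam <- vapply(dcs, `[[`, numeric(1), "lam")
      Gam <- lapply(dcs, `[[`, "Gamma"); del <- lapply(dcs, `[[`, "delta")
    }
  )
  Sigma <- Map(function(l, G, d) assemble_cov(l, G, d), lam, Gam, del)
  list(Sigma = Sigma, lam = lam, Gamma = Gam, delta = del)
}

#' Column-covariance CM update
#'
#' Conditional maximizer over the column covariances
#' \eqn{\Psi_1,\dots,\Psi_K} under one of the 7 structures compatible with the
#' identifiability restriction \eqn{|\Psi_k| = 1}; every returned matrix has
#' unit determinant.
#'
#' @param code One of the 7 column structure codes.
#' @param scatters List of `K` positive semi-definite `R x R` column scatter
#'   matrices \eqn{W_k}.
#' @inheritParams update_sigma
#'
#' @return A list with `Psi` (list of `K` unit-determinant matrices), `Gamma`
#'   and `delta`.
#' @export
update_psi <- function(code, scatters, weights, prev = NULL, control = list()) {
  code <- match.arg(code, col_structure_codes)
  K <- length(scatters)
  R <- nrow(scatters[[1]])
  check_scatters(scatters, weights, R)
  prev <- default_decomp(prev, K, R)
  ctrl <- mm_control(control)

  Gam <- NULL; del <- NULL
  switch(code,
    II = {
      Gam <- shared(diag(R), K); del <- shared(rep(1, R), K)
    },
    EI = {
      d <- diag_vec(Reduce(`+`, scatters))
      Gam <- shared(diag(R), K); del <- shared(d / exp(mean(log(d))), K)
    },
    VI = {
      ds <- lapply(scatters, diag_vec)
      Gam <- shared(diag(R), K)
      del <- lapply(ds, function(d) d / exp(mean(log(d))))
    },
    EE = {
      W <- Reduce(`+`, scatters)
      dc <- decompose_cov(W / det(W)^(1 / R))
      Gam <- shared(dc$Gamma, K); del <- shared(dc$delta, K)
    },
    VE = {
      G <- mm_rotation(scatters, prev$delta, init = prev$Gamma[[1]],
                       max_iter = ctrl$mm_max_iter, tol = ctrl$mm_tol)
      ds <- lapply(scatters, function(W) diag_vec(t(G) %*% W %*% G))
      Gam <- shared(G, K)
      del <- lapply(ds, function(d) d / exp(mean(log(d))))
    },
    EV = {
      eg <- lapply(scatters, eigen_pieces)
      om <- Reduce(`+`, lapply(eg, `[[`, "omega"))
      Gam <- lapply(eg, `[[`, "L")
      del <- shared(om / exp(mean(log(om))), K)
    },
    VV = {
      dcs <- lapply(scatters, function(W) decompose_cov(W / det(W)^(1 / R)))
      Gam <- lapply(dcs, `[[`, "Gamma"); del <- lapply(dcs, `[[`, "delta")
    }
  )
  Psi <- Map(function(G, d) assemble_cov(1, G, d), Gam, del)
  list(Psi = Psi, Gamma = Gam, delta = del)
}

#' MM update of a shared orientation matrix
#'
#' Minimizes \eqn{\sum_k \mathrm{tr}(Y_k \Gamma \Delta_k^{-1} \Gamma')} over
#' orthogonal \eqn{\Gamma} by minorization-maximization: the concave part of
#' the criterion is bounded by its tangent, giving the linear surrogate
#' \eqn{\mathrm{tr}(F\Gamma)} with
#' \eqn{F = \sum_k (\Delta_k^{-1}\Gamma'Y_k - e_k\Delta_k^{-1}\Gamma')} and
#' \eqn{e_k} the largest eigenvalue of \eqn{Y_k}; each inner step solves the
#' orthogonal Procrustes problem through a singular value decomposition of
#' the surrogate matrix. The criterion is non-increasing across iterations.
#'
#' @param scatters List of positive semi-definite `Q x Q` matrices.
#' @param shapes List of positive shape vectors (unit product), one per
#'   scatter.
#' @param init Orthogonal starting value for the orientation.
#' @param max_iter Maximum inner iterations.
#' @param tol Stop when the criterion decreases by less than `tol`.
#'
#' @return An orthogonal `Q x Q` matrix.
#' @export
mm_rotation <- function(scatters, shapes, init = NULL,
                        max_iter = 100, tol = 1e-8) {
  Q <- nrow(scatters[[1]])
  if (is.null(init)) init <- diag(Q)
  if (max(abs(crossprod(init) - diag(Q))) > 1e-8) {
    stop("`init` must be orthogonal", call. = FALSE)
  }
  if (Q == 1) return(matrix(1, 1, 1))
  crit <- function(G) {
    sum(vapply(seq_along(scatters), function(k) {
      sum(diag(scatters[[k]] %*% G %*% ((1 / shapes[[k]]) * t(G))))
    }, numeric(1)))
  }
  ek <- vapply(scatters, function(Y) max(eigen(Y, symmetric = TRUE,
                                               only.values = TRUE)$values),
               numeric(1))
  G <- init
  f_old <- crit(G)
  for (iter in seq_len(max_iter)) {
    F <- Reduce(`+`, lapply(seq_along(scatters), function(k) {
      (1 / shapes[[k]]) * (t(G) %*% scatters[[k]] - ek[k] * t(G))
    }))
    sv <- svd(-t(F))
    G_new <- sv$u %*% t(sv$v)
    f_new <- crit(G_new)
    if (f_new > f_old + 1e-10) break  # surrogate no longer improves
    G <- G_new
    if (abs(f_old - f_new) < tol) {
      f_old <- f_new
      break
    }
    f_old <- f_new
  }
  G
}

# ---- conditional objectives (used for estimator-optimality checks) ---------

# Sigma-part of the expected complete-data log-likelihood at fixed
# responsibilities: sum_k { -(R n_k / 2) log|Sigma_k| - tr(Sigma_k^-1 Y_k)/2 }.
sigma_objective <- function(Sigmas, scatters, weights, R) {
  sum(vapply(seq_along(Sigmas), function(k) {
    S <- Sigmas[[k]]
    -0.5 * R * weights[k] * determinant(S, logarithm = TRUE)$modulus -
      0.5 * sum(solve(S) * scatters[[k]])
  }, numeric(1)))
}

# Psi-part; the log-determinant term vanishes under |Psi_k| = 1.
psi_objective <- function(Psis, scatters, weights, P) {
  sum(vapply(seq_along(Psis), function(k) {
    Ps <- Psis[[k]]
    -0.5 * P * weights[k] * determinant(Ps, logarithm = TRUE)$modulus -
      0.5 * sum(solve(Ps) * scatters[[k]])
  }, numeric(1)))
}

# ---- internal helpers -------------------------------------------------------

shared <- function(x, K) rep(list(x), K)

diag_vec <- function(S) {
  d <- diag(S)
  if (any(d <= 0)) {
    stop(degenerate_error("scatter matrix has a non-positive diagonal entry"))
  }
  d
}

check_scatters <- function(scatters, weights, Q) {
  if (length(scatters) != length(weights)) {
    stop("`scatters` and `weights` lengths differ", call. = FALSE)
  }
  if (any(weights < 1e-8)) {
    k <- which(weights < 1e-8)[1]
    stop(degenerate_error(paste0("state ", k, " has (near) zero weight")))
  }
  for (S in scatters) {
    if (nrow(S) != Q || ncol(S) != Q) stop("scatter dimension mismatch", call. = FALSE)
  }
  invisible(TRUE)
}

default_decomp <- function(prev, K, Q) {
  if (is.null(prev)) {
    prev <- list(lam = rep(1, K), Gamma = shared(diag(Q), K),
                 delta = shared(rep(1, Q), K))
  }
  prev
}

mm_control <- function(control) {
  utils::modifyList(list(mm_max_iter = 100, mm_tol = 1e-8), control)
}

degenerate_error <- function(msg) {
  structure(class = c("mvhmm_degenerate", "error", "condition"),
            list(message = msg, call = NULL))
}

# Symmetrize after accumulation to control floating-point drift.
symmetrize <- function(S) (S + t(S)) / 2
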