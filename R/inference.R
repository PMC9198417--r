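# Scaled forward-backward recursions. Forward vectors are normalized to sum
# to one at each occasion and the log scale factors are accumulated; the
# backward recursion reuses the same scale constants, so smoothed
# memberships are gamma * beta without further normalization (it is applied
# anyway as a numerical guard).

#' Scaled forward-backward recursions
#'
#' Runs the forward and backward recursions independently for each unit,
#' with per-occasion scaling to prevent underflow. The per-unit
#' log-likelihood equals the log of
#' \eqn{\pi' \phi(X_{i1}) \Pi \phi(X_{i2}) \cdots \Pi \phi(X_{iT}) 1_K}.
#'
#' @param data A `fourway` object or long data frame (see [as_fourway()]).
#' @param params An [mvhmm_params()] object.
#'
#' @return An object of class `"mvhmm_fb"`: arrays `gamma` and `beta`
#'   (`I x T x K` scaled forward/backward variables), `log_scale`
#'   (`I x T` accumulated log scale constants), `loglik` and
#'   `per_unit_loglik`.
#' @export
forward_backward <- function(data, params) {
  data <- as_fourway(data)
  d <- dim(data$values)
  check_params_dims(params, d[3], d[4])
  logd <- all_state_logdens(flatten_fourway(data), d[3], d[4], params)
  fb_core(logd, params$pi, params$Pi, I = d[1], T = d[2])
}

#' Smoothed state memberships and transition posteriors
#'
#' Computes the E-step quantities: the smoothed membership probabilities
#' \eqn{\hat z_{itk} = \gamma_{itk}\beta_{itk} / \sum_h \gamma_{ith}\beta_{ith}}
#' and the pairwise transition posteriors
#' \eqn{\hat{zz}_{itjk} \propto \gamma_{i(t-1)j}\,\pi_{k|j}\,
#' \phi(X_{it}|k)\,\beta_{itk}} for \eqn{t = 2,\dots,T}.
#'
#' @inheritParams forward_backward
#' @param fb Optionally, a precomputed [forward_backward()] result for the
#'   same data and parameters.
#'
#' @return An object of class `"mvhmm_posteriors"`: `z` (`I x T x K`), `zz`
#'   (`I x (T-1) x K x K`, indexed from-state then to-state), `loglik`,
#'   `per_unit_loglik`.
#' @export
posterior_probs <- function(data, params, fb = NULL) {
  data <- as_fourway(data)
  d <- dim(data$values)
  check_params_dims(params, d[3], d[4])
  logd <- all_state_logdens(flatten_fourway(data), d[3], d[4], params)
  if (is.null(fb)) fb <- fb_core(logd, params$pi, params$Pi, I = d[1], T = d[2])
  posterior_core(fb, logd, params$Pi, I = d[1], T = d[2])
}

#' Local (posterior) decoding
#'
#' Assigns each (unit, occasion) the state with the largest smoothed
#' membership probability; ties break toward the smallest state index.
#'
#' @param post An `"mvhmm_posteriors"` object (or a fitted `"mvhmm"` model).
#' @return An `I x T` integer matrix of state labels.
#' @export
decode_local <- function(post) {
  if (inherits(post, "mvhmm")) post <- post$posteriors
  z <- post$z
  d <- dim(z)
  flat <- matrix(z, d[1] * d[2], d[3])
  matrix(max.col(flat, ties.method = "first"), d[1], d[2])
}

# ---- internal core ----------------------------------------------------------

# Log-densities for all N observations under each state: N x K matrix.
# Quadratic forms are computed from the inverse Cholesky factors so no
# covariance inverse is formed.
all_state_logdens <- function(Xf, P, R, params) {
  K <- params$K
  N <- nrow(Xf)
  out <- matrix(0, N, K)
  for (k in seq_len(K)) {
    US <- chol_or_stop(params$Sigma[[k]], paste0("Sigma[", k, "]"))
    UP <- chol_or_stop(params$Psi[[k]], paste0("Psi[", k, "]"))
    USi <- backsolve(US, diag(P))
    UPi <- backsolve(UP, diag(R))
    Kk <- UPi %x% USi
    E <- Xf - rep(as.vector(params$M[[k]]), each = N)
    quad <- rowSums((E %*% Kk)^2)
    out[, k] <- -0.5 * P * R * log(2 * pi) - R * sum(log(diag(US))) -
      P * sum(log(diag(UP))) - 0.5 * quad
  }
  out
}

fb_core <- function(logd, pi, Pi, I, T) {
  K <- length(pi)
  gam <- array(0, c(I, T, K))
  bet <- array(0, c(I, T, K))
  logscale <- matrix(0, I, T)
  cvec <- matrix(0, I, T)   # scaled normalizers (shift removed)
  per_unit <- numeric(I)
  tPi <- t(Pi)
  for (i in seq_len(I)) {
    idx <- (i - 1L) * T + seq_len(T)
    ld <- logd[idx, , drop = FALSE]
    m <- apply(ld, 1, max)
    dens <- exp(ld - m)
    A <- matrix(0, T, K)
    a <- pi * dens[1, ]
    c1 <- sum(a)
    if (c1 <= 0 || !is.finite(c1)) {
      stop("numerical collapse in forward recursion at unit ", i,
           ", occasion 1", call. = FALSE)
    }
    A[1, ] <- a / c1
    cvec[i, 1] <- c1
    if (T > 1) {
      for (t in 2:T) {
        a <- drop(tPi %*% A[t - 1, ]) * dens[t, ]
        ct <- sum(a)
        if (ct <= 0 || !is.finite(ct)) {
          stop("numerical collapse in forward recursion at unit ", i,
               ", occasion ", t, call. = FALSE)
        }
        A[t, ] <- a / ct
        cvec[i, t] <- ct
      }
    }
    B <- matrix(0, T, K)
    B[T, ] <- 1
    if (T > 1) {
      for (t in (T - 1):1) {
        B[t, ] <- drop(Pi %*% (dens[t + 1, ] * B[t + 1, ])) / cvec[i, t + 1]
      }
    }
    gam[i, , ] <- A
    bet[i, , ] <- B
    logscale[i, ] <- log(cvec[i, ]) + m
    per_unit[i] <- sum(logscale[i, ])
  }
  structure(list(gamma = gam, beta = bet, log_scale = logscale, cvec = cvec,
                 loglik = sum(per_unit), per_unit_loglik = per_unit),
            class = "mvhmm_fb")
}

posterior_core <- function(fb, logd, Pi, I, T) {
  K <- ncol(Pi)
  z <- array(0, c(I, T, K))
  zz <- if (T > 1) array(0, c(I, T - 1, K, K)) else
    array(0, c(I, 0, K, K))
  for (i in seq_len(I)) {
    idx <- (i - 1L) * T + seq_len(T)
    ld <- logd[idx, , drop = FALSE]
    m <- apply(ld, 1, max)
    dens <- exp(ld - m)
    A <- matrix(fb$gamma[i, , ], T, K)
    B <- matrix(fb$beta[i, , ], T, K)
    zi <- A * B
    zi <- zi / rowSums(zi)
    z[i, , ] <- zi
    if (T > 1) {
      for (t in 2:T) {
        M <- (A[t - 1, ] %o% (dens[t, ] * B[t, ])) * Pi / fb$cvec[i, t]
        zz[i, t - 1, , ] <- M / sum(M)
      }
    }
  }
  structure(list(z = z, zz = zz, loglik = fb$loglik,
                 per_unit_loglik = fb$per_unit_loglik),
            class = "mvhmm_posteriors")
}

check_params_dims <- function(params, P, R) {
  if (nrow(params$M[[1]]) != P || ncol(params$M[[1]]) != R) {
    stop("parameter dimensions (", nrow(params$M[[1]]), " x ",
         ncol(params$M[[1]]), ") do not match the data (", P, " x ", R, ")",
         call. = FALSE)
  }
  invisible(TRUE)
}
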