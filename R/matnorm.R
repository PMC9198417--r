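# Matrix-normal density and sampler: the state-dependent observation law.
# A P x R draw X with mean M, row covariance Sigma (P x P) and column
# covariance Psi (R x R) satisfies vec(X) ~ N(vec(M), Psi %x% Sigma).

#' Matrix-normal log-density
#'
#' Evaluates the log-density of the matrix-normal distribution
#' \deqn{\log\phi(X \mid M, \Sigma, \Psi) = -\frac{PR}{2}\log(2\pi)
#'   - \frac{R}{2}\log|\Sigma| - \frac{P}{2}\log|\Psi|
#'   - \frac{1}{2}\,\mathrm{tr}\{\Sigma^{-1}(X-M)\Psi^{-1}(X-M)'\}.}
#' Determinants and the quadratic form are computed through Cholesky factors;
#' no explicit covariance inverse is formed.
#'
#' @param X A numeric `P x R` matrix (or a list of such matrices).
#' @param M Mean matrix, `P x R`.
#' @param Sigma Row covariance, symmetric positive-definite `P x P`.
#' @param Psi Column covariance, symmetric positive-definite `R x R`.
#' @param log If `TRUE` (default) return the log-density.
#'
#' @return A numeric scalar (or vector, one entry per matrix in the list).
#' @export
#' @examples
#' dmatnorm(matrix(0, 1, 1), matrix(0, 1, 1), diag(1), diag(1))  # -log(2*pi)/2
dmatnorm <- function(X, M, Sigma, Psi, log = TRUE) {
  if (is.list(X)) {
    out <- vapply(X, dmatnorm, numeric(1), M = M, Sigma = Sigma, Psi = Psi, log = TRUE)
    return(if (log) out else exp(out))
  }
  X <- as.matrix(X)
  check_matnorm_params(M, Sigma, Psi)
  if (!all(dim(X) == dim(M))) {
    stop("`X` is ", nrow(X), " x ", ncol(X), " but `M` is ",
         nrow(M), " x ", ncol(M), call. = FALSE)
  }
  P <- nrow(M); R <- ncol(M)
  US <- chol_or_stop(Sigma, "Sigma")
  UP <- chol_or_stop(Psi, "Psi")
  E <- X - M
  # tr(Sigma^-1 E Psi^-1 E') = || U_S^-T E U_P^-1 ||_F^2 via triangular solves
  A <- backsolve(US, E, transpose = TRUE)          # U_S^-T E
  B <- t(backsolve(UP, t(A), transpose = TRUE))    # A U_P^-1
  quad <- sum(B * B)
  ld <- -0.5 * P * R * log(2 * pi) - R * sum(log(diag(US))) -
    P * sum(log(diag(UP))) - 0.5 * quad
  if (log) ld else exp(ld)
}

#' Sample from the matrix-normal distribution
#'
#' Draws `X = M + A Z B'` with `A` the lower Cholesky factor of `Sigma`,
#' `B` the lower Cholesky factor of `Psi` and `Z` a `P x R` matrix of
#' independent standard normals. Fixing the factors to the lower-triangular
#' Cholesky ones makes draws reproducible across platforms for a given seed.
#'
#' @param n Number of draws.
#' @inheritParams dmatnorm
#' @param seed Optional integer seed applied locally for this call.
#'
#' @return A list of `n` matrices of dimension `P x R`.
#' @export
rmatnorm <- function(n, M, Sigma, Psi, seed = NULL) {
  stopifnot(n >= 1)
  check_matnorm_params(M, Sigma, Psi)
  P <- nrow(M); R <- ncol(M)
  A <- t(chol_or_stop(Sigma, "Sigma"))
  B <- t(chol_or_stop(Psi, "Psi"))
  with_local_seed(seed, {
    lapply(seq_len(n), function(i) {
      Z <- matrix(stats::rnorm(P * R), P, R)
      M + A %*% Z %*% t(B)
    })
  })
}

# ---- internal helpers -------------------------------------------------------

check_matnorm_params <- function(M, Sigma, Psi) {
  M <- as.matrix(M)
  if (nrow(Sigma) != ncol(Sigma) || nrow(Psi) != ncol(Psi)) {
    stop("covariance matrices must be square", call. = FALSE)
  }
  if (nrow(Sigma) != nrow(M)) {
    stop("`Sigma` is ", nrow(Sigma), " x ", ncol(Sigma),
         " but `M` has ", nrow(M), " rows", call. = FALSE)
  }
  if (nrow(Psi) != ncol(M)) {
    stop("`Psi` is ", nrow(Psi), " x ", ncol(Psi),
         " but `M` has ", ncol(M), " columns", call. = FALSE)
  }
  if (max(abs(Sigma - t(Sigma))) > 1e-8) stop("`Sigma` is not symmetric", call. = FALSE)
  if (max(abs(Psi - t(Psi))) > 1e-8) stop("`Psi` is not symmetric", call. = FALSE)
  invisible(TRUE)
}

chol_or_stop <- function(S, name) {
  out <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(out)) {
    stop("`", name, "` is not positive definite", call. = FALSE)
  }
  out
}

# Evaluate and restore the RNG state around `code` when a seed is supplied.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
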