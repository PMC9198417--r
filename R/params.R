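# Parameter container for a K-state matrix-variate hidden Markov model.

#' Construct model parameters
#'
#' Bundles the Markov-chain parameters (initial law `pi`, transition matrix
#' `Pi`) with per-state matrix-normal parameters (`M`, `Sigma`, `Psi`) and the
#' structure codes they satisfy. Validation enforces the simplex constraints
#' and the identifiability restriction \eqn{|\Psi_k| = 1}.
#'
#' @param pi Length-`K` initial probability vector.
#' @param Pi `K x K` transition matrix (rows on the simplex); entry `(j, k)`
#'   is the probability of moving from state `j` to state `k`.
#' @param M List of `K` mean matrices (`P x R`).
#' @param Sigma List of `K` row covariance matrices (`P x P`), or a single
#'   matrix shared by all states.
#' @param Psi List of `K` column covariance matrices (`R x R`) with unit
#'   determinant, or a single shared matrix. Defaults to the identity.
#' @param row_code,col_code Structure codes the covariances are meant to
#'   satisfy (used for bookkeeping; defaults `"VVV"` and `"VV"` impose no
#'   cross-state constraint).
#'
#' @return An object of class `"mvhmm_params"`.
#' @export
mvhmm_params <- function(pi, Pi, M, Sigma, Psi = NULL,
                         row_code = "VVV", col_code = "VV") {
  K <- length(pi)
  if (!is.list(M)) M <- list(M)
  stopifnot(length(M) == K)
  M <- lapply(M, as.matrix)
  P <- nrow(M[[1]]); R <- ncol(M[[1]])
  if (!is.list(Sigma)) Sigma <- rep(list(as.matrix(Sigma)), K)
  if (is.null(Psi)) Psi <- diag(R)
  if (!is.list(Psi)) Psi <- rep(list(as.matrix(Psi)), K)
  stopifnot(length(Sigma) == K, length(Psi) == K)
  Pi <- as.matrix(Pi)
  if (abs(sum(pi) - 1) > 1e-8 || any(pi < -1e-12)) {
    stop("`pi` must lie on the probability simplex", call. = FALSE)
  }
  if (nrow(Pi) != K || ncol(Pi) != K ||
      max(abs(rowSums(Pi) - 1)) > 1e-8 || any(Pi < -1e-12)) {
    stop("rows of `Pi` must lie on the probability simplex", call. = FALSE)
  }
  for (k in seq_len(K)) {
    check_matnorm_params(M[[k]], Sigma[[k]], Psi[[k]])
    if (abs(det(Psi[[k]]) - 1) > 1e-6) {
      stop("`Psi[[", k, "]]` must have unit determinant (|det - 1| = ",
           format(abs(det(Psi[[k]]) - 1)), ")", call. = FALSE)
    }
  }
  structure(list(K = K, pi = as.numeric(pi), Pi = Pi, M = M,
                 Sigma = Sigma, Psi = Psi,
                 row_code = row_code, col_code = col_code),
            class = "mvhmm_params")
}

#' @export
print.mvhmm_params <- function(x, ...) {
  cat("<mvhmm_params> K = ", x$K, ", structure ", x$row_code, "-", x$col_code,
      ", states ", nrow(x$M[[1]]), " x ", ncol(x$M[[1]]), "\n", sep = "")
  invisible(x)
}

#' Write or read model parameters as structured text
#'
#' Parameters are serialized to YAML so fits are inspectable and diffable.
#'
#' @param params An `"mvhmm_params"` object.
#' @param path File path.
#' @return `read_mvhmm_params()` returns an `"mvhmm_params"` object;
#'   `write_mvhmm_params()` returns `path` invisibly.
#' @export
write_mvhmm_params <- function(params, path) {
  obj <- list(
    K = params$K, row_code = params$row_code, col_code = params$col_code,
    pi = as.numeric(params$pi),
    Pi = apply(params$Pi, 1, as.numeric, simplify = FALSE),
    M = lapply(params$M, mat_to_rows),
    Sigma = lapply(params$Sigma, mat_to_rows),
    Psi = lapply(params$Psi, mat_to_rows)
  )
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}

#' @rdname write_mvhmm_params
#' @export
read_mvhmm_params <- function(path) {
  obj <- yaml::read_yaml(path)
  mvhmm_params(
    pi = as.numeric(obj$pi),
    Pi = do.call(rbind, lapply(obj$Pi, as.numeric)),
    M = lapply(obj$M, rows_to_mat),
    Sigma = lapply(obj$Sigma, rows_to_mat),
    Psi = lapply(obj$Psi, rows_to_mat),
    row_code = obj$row_code, col_code = obj$col_code
  )
}

mat_to_rows <- function(m) apply(as.matrix(m), 1, as.numeric, simplify = FALSE)
rows_to_mat <- function(rows) do.call(rbind, lapply(rows, as.numeric))
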