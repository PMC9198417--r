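# The parsimonious covariance family. A Q x Q covariance is written
# Phi_k = lambda_k Gamma_k Delta_k Gamma_k' (volume / orientation / shape).
# Constraining each component equal (E) or variable (V) across states, or the
# matrix to be axis-aligned (I), gives 14 row structures. The column
# covariance carries the identifiability restriction |Psi| = 1, which removes
# its volume parameter and collapses the 14 structures to 7 two-letter codes.

#' @rdname structure_codes
#' @format NULL
#' @export
row_structure_codes <- c(
  "EII", "VII", "EEI", "VEI", "EVI", "VVI",
  "EEE", "VEE", "EVE", "VVE", "EEV", "VEV", "EVV", "VVV"
)

#' Admissible covariance structure codes
#'
#' `row_structure_codes` are the 14 volume/shape/orientation structures for the
#' row covariance; `col_structure_codes` are the 7 structures left for the
#' column covariance once the restriction \eqn{|\Psi| = 1} removes the volume
#' letter. Combined as `"VEE-EE"` (row code, hyphen, column code) they index
#' the 98 models of the family.
#'
#' @name structure_codes
#' @format NULL
#' @export
col_structure_codes <- c("II", "EI", "VI", "EE", "VE", "EV", "VV")

#' All admissible structure pairs
#'
#' @return A tibble with columns `row_code`, `col_code` and `structure`
#'   (`"<row>-<col>"`), one row per model in the family (98 rows).
#' @export
#' @examples
#' nrow(structure_pairs())  # 98
structure_pairs <- function() {
  grid <- tidyr::expand_grid(row_code = row_structure_codes,
                             col_code = col_structure_codes)
  dplyr::mutate(grid, structure = paste(row_code, col_code, sep = "-"))
}

parse_structure <- function(structure) {
  parts <- strsplit(structure, "-", fixed = TRUE)[[1]]
  if (length(parts) != 2 || !(parts[1] %in% row_structure_codes) ||
      !(parts[2] %in% col_structure_codes)) {
    stop("unknown structure `", structure, "`; row codes: ",
         paste(row_structure_codes, collapse = ", "), "; column codes: ",
         paste(col_structure_codes, collapse = ", "), call. = FALSE)
  }
  list(row_code = parts[1], col_code = parts[2])
}

#' Free-parameter counts for covariance structures
#'
#' `count_row_params()` gives the number of free parameters of a row covariance
#' structure for `K` states and matrices of side `Q`; `count_col_params()`
#' gives the count for a column structure, i.e. the corresponding three-letter
#' count minus the volume parameter(s) removed by the \eqn{|\Psi| = 1}
#' restriction.
#'
#' @param code A structure code (see [structure_codes]).
#' @param K Number of hidden states.
#' @param Q Side length of the covariance matrix.
#'
#' @return An integer count.
#' @export
#' @examples
#' count_row_params("EII", K = 4, Q = 2)  # 1
#' count_col_params("EE", K = 8, Q = 3)   # 5
count_row_params <- function(code, K, Q) {
  stopifnot(K >= 1, Q >= 1)
  switch(match.arg(code, row_structure_codes),
    EII = 1,
    VII = K,
    EEI = Q,
    VEI = K + Q - 1,
    EVI = K * (Q - 1) + 1,
    VVI = K * Q,
    EEE = Q * (Q + 1) / 2,
    VEE = Q * (Q + 1) / 2 + K - 1,
    EVE = Q * (Q - 1) / 2 + K * (Q - 1) + 1,
    VVE = Q * (Q - 1) / 2 + K * Q,
    EEV = K * Q * (Q - 1) / 2 + Q,
    VEV = K * Q * (Q - 1) / 2 + K + Q - 1,
    EVV = K * Q * (Q + 1) / 2 - K + 1,
    VVV = K * Q * (Q + 1) / 2
  )
}

#' @rdname count_row_params
#' @export
count_col_params <- function(code, K, Q) {
  stopifnot(K >= 1, Q >= 1)
  switch(match.arg(code, col_structure_codes),
    II = 0,
    EI = Q - 1,
    VI = K * (Q - 1),
    EE = Q * (Q + 1) / 2 - 1,
    VE = Q * (Q - 1) / 2 + K * (Q - 1),
    EV = K * Q * (Q - 1) / 2 + Q - 1,
    VV = K * Q * (Q + 1) / 2 - K
  )
}

#' Assemble a covariance matrix from its eigen components
#'
#' Returns \eqn{\lambda \Gamma \Delta \Gamma'} for a volume scalar
#' `lam`, orthogonal orientation `Gamma` and unit-determinant diagonal shape
#' `Delta` (given as the diagonal vector `delta`).
#'
#' @param lam Positive volume scalar.
#' @param Gamma Orthogonal `Q x Q` orientation matrix.
#' @param delta Length-`Q` positive shape vector with product 1.
#'
#' @return A symmetric positive-definite `Q x Q` matrix.
#' @export
assemble_cov <- function(lam, Gamma, delta) {
  S <- lam * Gamma %*% (delta * t(Gamma))
  (S + t(S)) / 2
}

#' Eigen decomposition of a covariance into volume, orientation and shape
#'
#' Inverse of [assemble_cov()]: `lam` is \eqn{|\Phi|^{1/Q}}, `Gamma` holds the
#' eigenvectors (descending eigenvalues, each column's largest-magnitude entry
#' made positive so the decomposition is reproducible) and `delta` the scaled
#' eigenvalues with product 1.
#'
#' @param Phi A symmetric positive-definite matrix.
#' @return A list with components `lam`, `Gamma`, `delta`.
#' @export
decompose_cov <- function(Phi) {
  eg <- eigen((Phi + t(Phi)) / 2, symmetric = TRUE)
  vals <- eg$values
  if (any(vals <= 0)) stop("matrix is not positive definite", call. = FALSE)
  Q <- length(vals)
  lam <- exp(mean(log(vals)))
  list(lam = lam, Gamma = fix_eigvec_signs(eg$vectors), delta = vals / lam)
}

# Deterministic sign convention: largest-magnitude entry of each column > 0.
fix_eigvec_signs <- function(V) {
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

# Eigen pieces of a PSD scatter: descending eigenvalues, sign-fixed vectors.
eigen_pieces <- function(S) {
  eg <- eigen((S + t(S)) / 2, symmetric = TRUE)
  list(L = fix_eigvec_signs(eg$vectors), omega = pmax(eg$values, 0))
}
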