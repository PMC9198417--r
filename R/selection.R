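# Model selection over the 98-structure family and the geometric sojourn
# goodness-of-fit test.

#' Number of free parameters of a model specification
#'
#' Chain parameters (`K - 1` initial probabilities, `K(K - 1)` transition
#' probabilities), `K P R` means, plus the structure-specific covariance
#' counts from [count_row_params()] and [count_col_params()].
#'
#' @param row_code,col_code Structure codes.
#' @param K Number of hidden states.
#' @param P,R Matrix dimensions.
#' @return An integer.
#' @export
#' @examples
#' n_params_mvhmm("VEE", "EE", K = 8, P = 2, R = 3)  # 126
n_params_mvhmm <- function(row_code, col_code, K, P, R) {
  (K - 1) + K * (K - 1) + K * P * R +
    count_row_params(row_code, K, P) + count_col_params(col_code, K, R)
}

#' Bayesian information criterion
#'
#' `BIC = -2 loglik + m log(n)`, smaller is better. The sample size `n` is
#' `I * T` matrix observations under the default `"occasions"` convention, or
#' `I` under `"units"`.
#'
#' @param loglik Maximized log-likelihood.
#' @param n_params Number of free parameters.
#' @param n_units,n_times Panel dimensions `I` and `T`.
#' @param nobs Sample-size convention.
#' @return The BIC value.
#' @export
bic_mvhmm <- function(loglik, n_params, n_units, n_times,
                      nobs = c("occasions", "units")) {
  nobs <- match.arg(nobs)
  n <- if (nobs == "occasions") n_units * n_times else n_units
  -2 * loglik + n_params * log(n)
}

#' Fit a grid of models and select by BIC
#'
#' Fits every requested (structure, `K`) combination with [mvhmm()] and ranks
#' the converged fits by BIC (smaller is better; ties break toward fewer
#' parameters, then fewer states). Individual fit failures are recorded
#' without aborting the grid.
#'
#' @inheritParams mvhmm
#' @param structures `"all"` for the whole 98-model family, or a character
#'   vector of structure pairs such as `c("EII-II", "VEE-EE")`.
#' @param K Integer vector of state counts to try.
#' @param jobs Number of worker processes for parallel fitting; results are
#'   identical to sequential execution for a given `seed`.
#' @param verbose Print a one-line summary per fit.
#'
#' @return An object of class `"mvhmm_select"`: a list with `table` (a tibble
#'   with one row per fit: `row_code`, `col_code`, `K`, `loglik`, `n_params`,
#'   `bic`, `converged`, `n_iter`, `seconds`, `error`), `best` (the winning
#'   specification) and `best_fit` (its `"mvhmm"` object).
#' @export
mvhmm_select <- function(data, structures = "all", K = 1:3, jobs = 1,
                         tol = 1e-8, max_iter = 500, init_runs = 100,
                         init_iters = 1, seed = NULL,
                         nobs = c("occasions", "units"), control = list(),
                         verbose = FALSE) {
  nobs <- match.arg(nobs)
  fw <- as_fourway(data)
  if (identical(structures, "all")) {
    structures <- structure_pairs()$structure
  }
  lapply(structures, parse_structure)  # validate early
  grid <- tidyr::expand_grid(structure = structures, K = sort(unique(K)))
  if (nrow(grid) == 0) stop("empty model grid", call. = FALSE)
  seeds <- with_local_seed(seed, sample.int(.Machine$integer.max - 1,
                                            nrow(grid)))

  fit_one <- function(g) {
    spec <- grid[g, ]
    t0 <- proc.time()[["elapsed"]]
    fit <- tryCatch(
      mvhmm(fw, spec$structure, K = spec$K, tol = tol, max_iter = max_iter,
            init_runs = init_runs, init_iters = init_iters,
            seed = seeds[g], nobs = nobs, control = control),
      error = function(e) e
    )
    secs <- proc.time()[["elapsed"]] - t0
    sc <- parse_structure(spec$structure)
    if (inherits(fit, "error")) {
      row <- tibble::tibble(row_code = sc$row_code, col_code = sc$col_code,
                            K = spec$K, loglik = NA_real_,
                            n_params = n_params_mvhmm(sc$row_code, sc$col_code,
                                                      spec$K, dim(fw$values)[3],
                                                      dim(fw$values)[4]),
                            bic = NA_real_, converged = FALSE,
                            n_iter = NA_integer_, seconds = secs,
                            error = conditionMessage(fit))
      return(list(row = row, fit = NULL))
    }
    row <- tibble::tibble(row_code = sc$row_code, col_code = sc$col_code,
                          K = spec$K, loglik = fit$loglik,
                          n_params = fit$n_params, bic = fit$bic,
                          converged = fit$converged, n_iter = fit$n_iter,
                          seconds = secs, error = NA_character_)
    if (verbose) {
      message(sprintf("%s K=%d  loglik=%.2f  BIC=%.2f", spec$structure,
                      spec$K, fit$loglik, fit$bic))
    }
    list(row = row, fit = fit)
  }

  results <- if (jobs > 1) {
    parallel::mclapply(seq_len(nrow(grid)), fit_one, mc.cores = jobs,
                       mc.preschedule = TRUE)
  } else {
    lapply(seq_len(nrow(grid)), fit_one)
  }

  tab <- dplyr::bind_rows(lapply(results, `[[`, "row"))
  ok <- which(tab$converged & is.finite(tab$bic))
  if (length(ok) == 0) {
    ok <- which(is.finite(tab$bic))  # fall back to non-converged fits
  }
  if (length(ok) == 0) {
    stop("every fit in the grid failed; first error: ",
         tab$error[!is.na(tab$error)][1], call. = FALSE)
  }
  best_i <- ok[order(tab$bic[ok], tab$n_params[ok], tab$K[ok])][1]
  structure(list(
    table = tab,
    best = list(row_code = tab$row_code[best_i], col_code = tab$col_code[best_i],
                structure = paste(tab$row_code[best_i], tab$col_code[best_i],
                                  sep = "-"),
                K = tab$K[best_i], bic = tab$bic[best_i]),
    best_fit = results[[best_i]]$fit
  ), class = "mvhmm_select")
}

#' @export
print.mvhmm_select <- function(x, ...) {
  cat("Model selection over ", nrow(x$table), " fits\n", sep = "")
  cat("  best: ", x$best$structure, " with K = ", x$best$K,
      " (BIC = ", format(x$best$bic), ")\n", sep = "")
  print(utils::head(dplyr::arrange(x$table, .data$bic), 5))
  invisible(x)
}

#' Chi-squared test of geometric sojourn times
#'
#' Under a homogeneous hidden Markov model the sojourn (segment) lengths in
#' state `k` are geometric with continuation probability \eqn{\pi_{k|k}}.
#' For each state the observed maximal run lengths of the decoded sequences
#' are compared with the geometric law
#' \eqn{\Pr(L = \ell) = \pi_{k|k}^{\ell-1}(1 - \pi_{k|k})} by a chi-squared
#' goodness-of-fit test (run lengths binned so that every expected count is
#' at least 5; degrees of freedom are bins minus one). The `K` p-values are
#' combined by Holm's step-down adjustment, and the global geometric
#' hypothesis is rejected when the minimum adjusted p-value falls below
#' `alpha`.
#'
#' @param x A fitted `"mvhmm"` object, or an `I x T` integer matrix of
#'   decoded state labels.
#' @param Pi Transition matrix (taken from the fit when `x` is an `"mvhmm"`).
#' @param alpha Significance level for the global decision.
#'
#' @return An object of class `"mvhmm_sojourn"`: a tibble with one row per
#'   tested state (`state`, `n_runs`, `statistic`, `df`, `p_value`,
#'   `p_adjusted`) carrying attributes `min_adjusted_p`, `alpha` and
#'   `reject`.
#' @export
sojourn_test <- function(x, Pi = NULL, alpha = 0.05) {
  if (inherits(x, "mvhmm")) {
    labels <- x$labels
    if (is.null(Pi)) Pi <- x$params$Pi
  } else {
    labels <- as.matrix(x)
    if (is.null(Pi)) stop("`Pi` is required when `x` is a label matrix",
                          call. = FALSE)
  }
  K <- nrow(Pi)
  runs <- state_run_lengths(labels, K)
  visited <- which(vapply(runs, length, integer(1)) > 0)
  if (length(visited) < K) {
    warning("state(s) ", paste(setdiff(seq_len(K), visited), collapse = ", "),
            " never visited; excluded from the adjustment")
  }
  rows <- lapply(visited, function(k) {
    ct <- geometric_chisq(runs[[k]], Pi[k, k])
    tibble::tibble(state = k, n_runs = length(runs[[k]]),
                   statistic = ct$statistic, df = ct$df, p_value = ct$p_value)
  })
  tab <- dplyr::bind_rows(rows)
  tab$p_adjusted <- stats::p.adjust(tab$p_value, method = "holm")
  out <- tab
  attr(out, "min_adjusted_p") <- min(tab$p_adjusted)
  attr(out, "alpha") <- alpha
  attr(out, "reject") <- min(tab$p_adjusted) < alpha
  class(out) <- c("mvhmm_sojourn", class(tab))
  out
}

#' @export
print.mvhmm_sojourn <- function(x, ...) {
  NextMethod()
  cat("min Holm-adjusted p = ", format(attr(x, "min_adjusted_p")),
      "; global geometric hypothesis ",
      if (attr(x, "reject")) "rejected" else "not rejected",
      " at alpha = ", attr(x, "alpha"), "\n", sep = "")
  invisible(x)
}

# Maximal run lengths per state across all units (runs touching the sequence
# boundaries are counted as observed lengths).
state_run_lengths <- function(labels, K) {
  out <- rep(list(integer(0)), K)
  for (i in seq_len(nrow(labels))) {
    r <- rle(labels[i, ])
    for (k in seq_len(K)) {
      out[[k]] <- c(out[[k]], r$lengths[r$values == k])
    }
  }
  out
}

# Chi-squared test of run lengths against Geometric(1 - p_stay), binning
# consecutive lengths until each bin's expected count reaches 5; the final
# bin absorbs the infinite upper tail.
geometric_chisq <- function(run_lengths, p_stay) {
  n <- length(run_lengths)
  p_stay <- min(max(p_stay, 1e-12), 1 - 1e-12)
  lmax <- max(run_lengths)
  probs <- p_stay^(seq_len(lmax) - 1) * (1 - p_stay)  # P(L = l), l = 1..lmax
  tail_prob <- p_stay^lmax                            # P(L > lmax)
  # greedy binning from below: close a bin once its expected count reaches 5;
  # the remainder (including the infinite tail) forms the final open bin
  breaks <- integer(0)
  acc <- 0
  for (l in seq_len(lmax)) {
    acc <- acc + n * probs[l]
    if (acc >= 5 && l < lmax) { breaks <- c(breaks, l); acc <- 0 }
  }
  if (acc + n * tail_prob < 5 && length(breaks) > 0) {
    breaks <- breaks[-length(breaks)]  # merge an undersized tail bin backwards
  }
  nb <- length(breaks) + 1L
  if (nb < 2) {
    return(list(statistic = 0, df = 0L, p_value = 1))
  }
  lo <- c(1L, breaks + 1L)
  hi <- c(breaks, Inf)
  obs <- vapply(seq_len(nb), function(b) {
    sum(run_lengths >= lo[b] & run_lengths <= hi[b])
  }, numeric(1))
  pr <- vapply(seq_len(nb), function(b) {
    if (is.finite(hi[b])) sum(probs[lo[b]:hi[b]]) else p_stay^(lo[b] - 1)
  }, numeric(1))
  ct <- suppressWarnings(stats::chisq.test(obs, p = pr))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}
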