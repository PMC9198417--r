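# broom-style accessors for fitted models and selection objects.

#' Tidy a fitted matrix-variate HMM
#'
#' Returns one row per scalar parameter: initial probabilities, transition
#' probabilities, mean-matrix entries and covariance entries, with the state
#' and matrix position they belong to.
#'
#' @param x A fitted `"mvhmm"` object.
#' @param ... Unused.
#' @return A tibble with columns `term` (`pi`, `Pi`, `M`, `Sigma`, `Psi`),
#'   `state`, `from_state`, `row`, `col`, `estimate`.
#' @method tidy mvhmm
#' @export
tidy.mvhmm <- function(x, ...) {
  p <- x$params
  K <- p$K
  rows <- list(
    tibble::tibble(term = "pi", state = seq_len(K), from_state = NA_integer_,
                   row = NA_character_, col = NA_character_,
                   estimate = p$pi)
  )
  pi_mat <- p$Pi
  rows[[length(rows) + 1]] <- tibble::tibble(
    term = "Pi",
    state = rep(seq_len(K), times = K),       # to-state varies fastest
    from_state = rep(seq_len(K), each = K),
    row = NA_character_, col = NA_character_,
    estimate = as.vector(t(pi_mat))
  )
  mat_rows <- function(term, mats, rn, cn) {
    dplyr::bind_rows(lapply(seq_len(K), function(k) {
      m <- mats[[k]]
      tibble::tibble(term = term, state = k, from_state = NA_integer_,
                     row = rep(rn, times = ncol(m)),
                     col = rep(cn, each = nrow(m)),
                     estimate = as.vector(m))
    }))
  }
  rows[[length(rows) + 1]] <- mat_rows("M", p$M, x$row_names, x$col_names)
  rows[[length(rows) + 1]] <- mat_rows("Sigma", p$Sigma, x$row_names, x$row_names)
  rows[[length(rows) + 1]] <- mat_rows("Psi", p$Psi, x$col_names, x$col_names)
  dplyr::bind_rows(rows)
}

#' One-row summary of a fitted matrix-variate HMM
#'
#' @inheritParams tidy.mvhmm
#' @return A one-row tibble with `structure`, `K`, `logLik`, `n_params`,
#'   `BIC`, `converged`, `n_iter`, `n_restarts`.
#' @method glance mvhmm
#' @export
glance.mvhmm <- function(x, ...) {
  tibble::tibble(
    structure = paste(x$params$row_code, x$params$col_code, sep = "-"),
    K = x$params$K,
    logLik = x$loglik,
    n_params = x$n_params,
    BIC = x$bic,
    converged = x$converged,
    n_iter = x$n_iter,
    n_restarts = x$n_restarts
  )
}

#' Decoded states and memberships per unit and occasion
#'
#' @inheritParams tidy.mvhmm
#' @param data Unused (the fit stores its panel labels).
#' @return A tibble with `unit`, `time`, `.state` (locally decoded label) and
#'   one `.prob_k` column per state with the smoothed membership.
#' @method augment mvhmm
#' @export
augment.mvhmm <- function(x, data = NULL, ...) {
  d <- x$dims
  z <- x$posteriors$z
  out <- tibble::tibble(
    unit = rep(x$unit_ids, times = d["T"]),
    time = rep(x$time_ids, each = d["I"]),
    .state = as.vector(x$labels)
  )
  for (k in seq_len(x$params$K)) {
    out[[paste0(".prob_", k)]] <- as.vector(z[, , k])
  }
  out
}

#' @method tidy mvhmm_select
#' @export
tidy.mvhmm_select <- function(x, ...) x$table

#' @method glance mvhmm_select
#' @export
glance.mvhmm_select <- function(x, ...) {
  tibble::tibble(structure = x$best$structure, K = x$best$K,
                 BIC = x$best$bic, n_fits = nrow(x$table),
                 n_failed = sum(!is.na(x$table$error)))
}

#' Plot a fitted matrix-variate HMM
#'
#' `type = "states"` draws the decoded state sequence of every unit as a
#' unit-by-occasion tile map; `type = "trace"` the log-likelihood trace over
#' ECM sweeps; `type = "means"` a heat map of the estimated state mean
#' matrices.
#'
#' @param object A fitted `"mvhmm"` object.
#' @param type One of `"states"`, `"trace"`, `"means"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mvhmm
#' @export
autoplot.mvhmm <- function(object, type = c("states", "trace", "means"), ...) {
  type <- match.arg(type)
  if (type == "trace") {
    df <- tibble::tibble(sweep = seq_along(object$loglik_trace) - 1,
                         loglik = object$loglik_trace)
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$sweep, y = .data$loglik)) +
        ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
        ggplot2::labs(x = "ECM sweep", y = "log-likelihood") +
        ggplot2::theme_minimal()
    )
  }
  if (type == "states") {
    df <- augment.mvhmm(object)
    df$unit <- factor(df$unit, levels = rev(object$unit_ids))
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$time), y = .data$unit,
                                       fill = factor(.data$.state))) +
        ggplot2::geom_tile() +
        ggplot2::labs(x = "occasion", y = "unit", fill = "state") +
        ggplot2::theme_minimal() +
        ggplot2::theme(axis.text.y = ggplot2::element_blank())
    )
  }
  td <- tidy.mvhmm(object)
  df <- td[td$term == "M", ]
  df$row <- factor(df$row, levels = rev(object$row_names))
  df$col <- factor(df$col, levels = object$col_names)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$estimate)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~state, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "column level", y = "row level", fill = "mean") +
    ggplot2::theme_minimal()
}

#' Plot a model-selection table
#'
#' BIC against the number of states, one line per structure pair; failed
#' fits are dropped.
#'
#' @param object An `"mvhmm_select"` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mvhmm_select
#' @export
autoplot.mvhmm_select <- function(object, ...) {
  df <- object$table
  df <- df[is.finite(df$bic), ]
  df$structure <- paste(df$row_code, df$col_code, sep = "-")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$K, y = .data$bic,
                                   group = .data$structure)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = "number of hidden states K", y = "BIC") +
    ggplot2::theme_minimal()
}
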