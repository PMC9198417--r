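# ECM driver. Each sweep alternates:
#   E-step:   scaled forward-backward -> smoothed z and transition zz
#   CM-step 1: pi, Pi, M (with old Sigma, Psi), then Sigma from row scatters
#              built with the previous Psi iterate
#   CM-step 2: Psi from column scatters built with the freshly updated Sigma
# The log-likelihood is monotone non-decreasing across sweeps. Degenerate
# states (vanishing responsibility mass) trigger a re-initialization.

#' Fit a parsimonious matrix-variate hidden Markov model
#'
#' Maximum likelihood estimation by expectation-conditional maximization for
#' a `K`-state hidden Markov model whose states carry matrix-normal densities
#' with eigen-decomposed covariance structures. Initialization uses short-EM:
#' `init_runs` random starts (hard random memberships followed by one
#' conditional-maximization sweep) are each run for `init_iters` sweeps, and
#' the start with the largest log-likelihood seeds the full algorithm.
#'
#' @param data A long-format data frame with columns `unit`, `time`, `row`,
#'   `col`, `value` (see [as_fourway()]) or a `fourway` object.
#' @param structure Structure pair string, row code, hyphen, column code
#'   (e.g. `"VEE-EE"`); see [structure_pairs()] for the 98 admissible pairs.
#' @param K Number of hidden states (`K >= 1`).
#' @param tol Convergence tolerance on the relative log-likelihood change.
#' @param max_iter Maximum number of ECM sweeps.
#' @param init_runs,init_iters Number of short-EM starts and sweeps per start.
#' @param seed Optional integer seed applied locally to the whole fit.
#' @param nobs Sample-size convention for the BIC penalty:
#'   `"occasions"` uses `I * T` matrix observations (default), `"units"`
#'   uses `I`.
#' @param start Optional [mvhmm_params()] starting value; when supplied the
#'   short-EM initialization is skipped.
#' @param control List of numerical settings: `mm_max_iter`, `mm_tol` for the
#'   inner MM rotation loop, `max_restarts` for degenerate-state restarts.
#'
#' @return An object of class `"mvhmm"` with components `params`
#'   ([mvhmm_params()]), `decomp` (volume/orientation/shape pieces),
#'   `loglik`, `loglik_trace`, `posteriors`, `labels` (decoded `I x T`
#'   states), `n_params`, `bic`, `converged`, `n_iter`, `n_restarts`.
#' @seealso [mvhmm_select()] to search over structures and state counts,
#'   [tidy.mvhmm()], [glance.mvhmm()], [augment.mvhmm()], [autoplot.mvhmm()].
#' @export
#' @examples
#' sim <- simulate_mvhmm(scenario_preset("D1-T1-K2-O2")$params,
#'                       I = 30, T = 5, seed = 1)
#' fit <- mvhmm(sim$data, "EII-II", K = 2, init_runs = 5, seed = 1)
#' glance(fit)
mvhmm <- function(data, structure = "VVV-VV", K = 2, tol = 1e-8,
                  max_iter = 500, init_runs = 100, init_iters = 1,
                  seed = NULL, nobs = c("occasions", "units"),
                  control = list(), start = NULL) {
  nobs <- match.arg(nobs)
  if (K < 1) stop("`K` must be at least 1", call. = FALSE)
  sc <- parse_structure(structure)
  fw <- as_fourway(data)
  d <- dim(fw$values)
  I <- d[1]; T <- d[2]; P <- d[3]; R <- d[4]
  Xf <- flatten_fourway(fw)
  ctrl <- utils::modifyList(list(mm_max_iter = 100, mm_tol = 1e-8,
                                 max_restarts = 5), control)
  cl <- match.call()

  if (!is.null(start) && start$K != K) {
    stop("`start` has K = ", start$K, " but K = ", K, " was requested",
         call. = FALSE)
  }
  res <- with_local_seed(seed, {
    attempt <- 0L
    repeat {
      attempt <- attempt + 1L
      out <- tryCatch({
        st0 <- if (!is.null(start) && attempt == 1L) {
          params_to_state(start)
        } else {
          short_em_init_core(Xf, I, T, P, R, sc$row_code, sc$col_code, K,
                             H = init_runs, s = init_iters, ctrl = ctrl)
        }
        ecm_core(Xf, I, T, P, R, sc$row_code, sc$col_code, K,
                 st0, tol = tol, max_iter = max_iter, ctrl = ctrl)
      }, mvhmm_degenerate = function(e) e)
      if (!inherits(out, "condition")) {
        out$n_restarts <- attempt - 1L
        break
      }
      if (attempt > ctrl$max_restarts) {
        stop("fit of ", structure, " with K = ", K, " failed after ",
             ctrl$max_restarts, " restarts: ", conditionMessage(out),
             call. = FALSE)
      }
    }
    out
  })

  build_mvhmm(res, fw, sc$row_code, sc$col_code, K, nobs, cl)
}

#' Chain and mean updates from posteriors
#'
#' The first part of CM-step 1: the closed-form updates
#' \eqn{\ddot\pi_k = \sum_i \hat z_{i1k} / I},
#' \eqn{\ddot\pi_{k|j} \propto \sum_i \sum_{t\ge2} \hat{zz}_{itjk}} and
#' \eqn{\ddot M_k = \sum_{it} \hat z_{itk} X_{it} / \sum_{it} \hat z_{itk}}.
#'
#' @param post An `"mvhmm_posteriors"` object.
#' @param data The matching `fourway` data (or long data frame).
#' @return A list with `pi`, `Pi` and `M` (list of `K` mean matrices).
#' @export
update_chain_and_means <- function(post, data) {
  fw <- as_fourway(data)
  d <- dim(fw$values)
  I <- d[1]; T <- d[2]; P <- d[3]; R <- d[4]
  K <- dim(post$z)[3]
  Xf <- flatten_fourway(fw)
  z <- z_as_matrix(post$z)
  nk <- colSums(z)
  if (any(nk < 1e-8)) {
    stop(degenerate_error(paste0("state ", which(nk < 1e-8)[1],
                                 " has (near) zero total responsibility")))
  }
  zzsum <- apply(post$zz, c(3, 4), sum)
  pi_new <- colSums(matrix(post$z[, 1, ], I, K)) / I
  Pi_new <- normalize_rows(zzsum)
  M <- lapply(seq_len(K), function(k) {
    matrix(colSums(Xf * z[, k]) / nk[k], P, R)
  })
  list(pi = pi_new, Pi = Pi_new, M = M)
}

#' Short-EM initialization
#'
#' Runs `H` random starts, each advanced for `s` ECM sweeps, and returns the
#' parameter set with the largest log-likelihood. Each random start draws
#' hard random state memberships per (unit, occasion) and computes one
#' conditional-maximization sweep from them.
#'
#' @inheritParams mvhmm
#' @param H Number of short runs.
#' @param s Sweeps per short run.
#' @return An `"mvhmm_params"` object suitable as a starting value.
#' @export
short_em_init <- function(data, structure = "VVV-VV", K = 2, H = 100, s = 1,
                          seed = NULL, control = list()) {
  sc <- parse_structure(structure)
  fw <- as_fourway(data)
  d <- dim(fw$values)
  ctrl <- utils::modifyList(list(mm_max_iter = 100, mm_tol = 1e-8), control)
  st <- with_local_seed(seed, {
    short_em_init_core(flatten_fourway(fw), d[1], d[2], d[3], d[4],
                       sc$row_code, sc$col_code, K, H = H, s = s, ctrl = ctrl)
  })
  mvhmm_params(st$pi, st$Pi, st$M, st$sig$Sigma, st$psi$Psi,
               row_code = sc$row_code, col_code = sc$col_code)
}

#' Relabel states by ascending mean level
#'
#' Reorders the states of a fitted model by the ascending grand mean of their
#' estimated mean matrices, permuting `pi`, `Pi` (both axes), the state
#' parameters, the posterior arrays and the decoded labels consistently; the
#' log-likelihood is unchanged. Exact ties keep the original order.
#'
#' @param x A fitted `"mvhmm"` object.
#' @return The relabeled `"mvhmm"` object.
#' @export
align_labels <- function(x) {
  stopifnot(inherits(x, "mvhmm"))
  key <- vapply(x$params$M, mean, numeric(1))
  ord <- order(key)
  if (all(ord == seq_along(ord))) return(x)
  x$params <- permute_params(x$params, ord)
  x$decomp <- permute_decomp(x$decomp, ord)
  x$posteriors$z <- x$posteriors$z[, , ord, drop = FALSE]
  if (dim(x$posteriors$zz)[2] > 0) {
    x$posteriors$zz <- x$posteriors$zz[, , ord, ord, drop = FALSE]
  }
  x$labels <- matrix(match(x$labels, ord), nrow(x$labels), ncol(x$labels))
  x
}

# ---- internal core ----------------------------------------------------------

# Internal fitting state: list(pi, Pi, M, sig = list(Sigma, lam, Gamma, delta),
# psi = list(Psi, Gamma, delta)).

estep_core <- function(Xf, I, T, P, R, st) {
  logd <- all_state_logdens(Xf, P, R,
                            list(K = length(st$pi), M = st$M,
                                 Sigma = st$sig$Sigma, Psi = st$psi$Psi))
  fb <- fb_core(logd, st$pi, st$Pi, I, T)
  post <- posterior_core(fb, logd, st$Pi, I, T)
  list(post = post, loglik = fb$loglik)
}

cm_core <- function(Xf, I, T, P, R, row_code, col_code,
                    z, z1, zzsum, st_prev, ctrl) {
  K <- ncol(z)
  nk <- colSums(z)
  if (any(nk < 1e-8)) {
    stop(degenerate_error(paste0("state ", which(nk < 1e-8)[1],
                                 " has (near) zero total responsibility")))
  }
  pi_new <- colSums(z1) / I
  Pi_new <- if (T > 1) normalize_rows(zzsum) else st_prev$Pi
  M <- vector("list", K)
  Cs <- vector("list", K)
  for (k in seq_len(K)) {
    vm <- colSums(Xf * z[, k]) / nk[k]
    M[[k]] <- matrix(vm, P, R)
    E <- Xf - rep(vm, each = nrow(Xf))
    Cs[[k]] <- crossprod(E, E * z[, k])
  }
  Yk <- lapply(seq_len(K), function(k) {
    symmetrize(row_scatter_from_cross(Cs[[k]], solve(st_prev$psi$Psi[[k]]), P, R))
  })
  sig <- update_sigma(row_code, Yk, nk, dims = list(P = P, R = R, T = T, I = I),
                      prev = st_prev$sig, control = ctrl)
  Wk <- lapply(seq_len(K), function(k) {
    symmetrize(col_scatter_from_cross(Cs[[k]], solve(sig$Sigma[[k]]), P, R))
  })
  psi <- update_psi(col_code, Wk, nk, prev = st_prev$psi, control = ctrl)
  list(pi = pi_new, Pi = Pi_new, M = M, sig = sig, psi = psi)
}

# Y_k[p, q] = sum_{r, s} PsiInv[r, s] * C[(r-1)P + p, (s-1)P + q]
row_scatter_from_cross <- function(C, PsiInv, P, R) {
  Y <- matrix(0, P, P)
  for (r in seq_len(R)) {
    ri <- ((r - 1L) * P + 1L):(r * P)
    for (s in seq_len(R)) {
      w <- PsiInv[r, s]
      if (w != 0) {
        Y <- Y + w * C[ri, ((s - 1L) * P + 1L):(s * P)]
      }
    }
  }
  Y
}

# W_k[r, s] = sum_{p, q} SigmaInv[p, q] * C[(r-1)P + p, (s-1)P + q]
col_scatter_from_cross <- function(C, SigmaInv, P, R) {
  W <- matrix(0, R, R)
  for (r in seq_len(R)) {
    ri <- ((r - 1L) * P + 1L):(r * P)
    for (s in seq_len(R)) {
      W[r, s] <- sum(SigmaInv * C[ri, ((s - 1L) * P + 1L):(s * P)])
    }
  }
  W
}

ecm_core <- function(Xf, I, T, P, R, row_code, col_code, K,
                     st0, tol, max_iter, ctrl) {
  st <- st0
  trace <- numeric(0)
  converged <- FALSE
  ll_prev <- -Inf
  post <- NULL
  for (iter in seq_len(max_iter)) {
    e <- estep_core(Xf, I, T, P, R, st)
    trace <- c(trace, e$loglik)
    post <- e$post
    if (iter > 1 &&
        abs(e$loglik - ll_prev) < tol * (abs(ll_prev) + 1e-3)) {
      converged <- TRUE
      break
    }
    ll_prev <- e$loglik
    st <- cm_core(Xf, I, T, P, R, row_code, col_code,
                  z_as_matrix(post$z), matrix(post$z[, 1, ], I, K),
                  apply(post$zz, c(3, 4), sum), st, ctrl)
  }
  if (!converged) {
    e <- estep_core(Xf, I, T, P, R, st)
    trace <- c(trace, e$loglik)
    post <- e$post
  }
  list(st = st, post = post, loglik = trace[length(trace)],
       loglik_trace = trace, converged = converged,
       n_iter = length(trace) - 1L)
}

random_start_core <- function(Xf, I, T, P, R, row_code, col_code, K, ctrl) {
  N <- I * T
  labels <- NULL
  for (try in 1:50) {
    cand <- sample.int(K, N, replace = TRUE)
    if (length(unique(cand)) == K) { labels <- cand; break }
  }
  if (is.null(labels)) {
    stop(degenerate_error("could not draw a start occupying all states"))
  }
  z <- matrix(0, N, K)
  z[cbind(seq_len(N), labels)] <- 1
  lab_mat <- matrix(labels, T, I)   # column i = unit i's path, t down rows
  # lightly smoothed chain estimates so no state is structurally excluded
  p1 <- table(factor(lab_mat[1, ], levels = seq_len(K)))
  pi0 <- (as.numeric(p1) + 0.5) / (I + 0.5 * K)
  counts <- matrix(0.5, K, K)
  if (T > 1) {
    from <- as.vector(lab_mat[-T, , drop = FALSE])
    to <- as.vector(lab_mat[-1, , drop = FALSE])
    for (n in seq_along(from)) counts[from[n], to[n]] <- counts[from[n], to[n]] + 1
  }
  Pi0 <- normalize_rows(counts)
  st_prev <- list(pi = pi0, Pi = Pi0, M = NULL,
                  sig = default_decomp(NULL, K, P), psi = default_decomp(NULL, K, R))
  st_prev$sig$Sigma <- shared(diag(P), K)
  st_prev$psi$Psi <- shared(diag(R), K)
  z1 <- z[seq(1L, N, by = T), , drop = FALSE]
  st <- cm_core(Xf, I, T, P, R, row_code, col_code, z, z1, counts, st_prev, ctrl)
  st$pi <- pi0   # smoothed chain estimates replace the raw hard-count ones
  st$Pi <- Pi0
  # place the state means at K randomly drawn observations (random exemplar
  # positions); membership-averaged means collapse to the grand mean once
  # I*T is moderately large, which strands every start at a merged optimum
  ex <- sample.int(N, K)
  st$M <- lapply(seq_len(K), function(k) matrix(Xf[ex[k], ], P, R))
  st
}

short_em_init_core <- function(Xf, I, T, P, R, row_code, col_code, K,
                               H, s, ctrl) {
  best <- NULL
  best_ll <- -Inf
  failures <- 0L
  for (h in seq_len(H)) {
    st <- tryCatch({
      st_h <- random_start_core(Xf, I, T, P, R, row_code, col_code, K, ctrl)
      for (j in seq_len(s)) {
        e <- estep_core(Xf, I, T, P, R, st_h)
        st_h <- cm_core(Xf, I, T, P, R, row_code, col_code,
                        z_as_matrix(e$post$z),
                        matrix(e$post$z[, 1, ], I, K),
                        apply(e$post$zz, c(3, 4), sum), st_h, ctrl)
      }
      st_h$loglik <- estep_core(Xf, I, T, P, R, st_h)$loglik
      st_h
    }, mvhmm_degenerate = function(e) NULL)
    if (is.null(st)) { failures <- failures + 1L; next }
    if (st$loglik > best_ll) { best <- st; best_ll <- st$loglik }
  }
  if (is.null(best)) {
    stop(degenerate_error(paste0("all ", H, " short-EM starts degenerated")))
  }
  best
}

build_mvhmm <- function(res, fw, row_code, col_code, K, nobs, call) {
  d <- dim(fw$values)
  st <- res$st
  params <- mvhmm_params(st$pi, st$Pi, st$M, st$sig$Sigma, st$psi$Psi,
                         row_code = row_code, col_code = col_code)
  m <- n_params_mvhmm(row_code, col_code, K, d[3], d[4])
  n_eff <- if (nobs == "occasions") d[1] * d[2] else d[1]
  out <- structure(list(
    params = params,
    decomp = list(sig = st$sig[c("lam", "Gamma", "delta")],
                  psi = st$psi[c("Gamma", "delta")]),
    loglik = res$loglik,
    loglik_trace = res$loglik_trace,
    posteriors = res$post,
    labels = NULL,
    n_params = m,
    bic = bic_mvhmm(res$loglik, m, d[1], d[2], nobs = nobs),
    converged = res$converged,
    n_iter = res$n_iter,
    n_restarts = res$n_restarts,
    dims = c(I = d[1], T = d[2], P = d[3], R = d[4]),
    unit_ids = fw$unit_ids, time_ids = fw$time_ids,
    row_names = fw$row_names, col_names = fw$col_names,
    nobs = n_eff, nobs_convention = nobs,
    call = call
  ), class = "mvhmm")
  out$labels <- decode_local(out$posteriors)
  align_labels(out)
}

# Internal fitting state from a parameter object (used for warm starts).
params_to_state <- function(params) {
  dcs <- lapply(params$Sigma, decompose_cov)
  dcp <- lapply(params$Psi, decompose_cov)
  list(pi = params$pi, Pi = params$Pi, M = params$M,
       sig = list(Sigma = params$Sigma,
                  lam = vapply(dcs, `[[`, numeric(1), "lam"),
                  Gamma = lapply(dcs, `[[`, "Gamma"),
                  delta = lapply(dcs, `[[`, "delta")),
       psi = list(Psi = params$Psi,
                  Gamma = lapply(dcp, `[[`, "Gamma"),
                  delta = lapply(dcp, `[[`, "delta")))
}

permute_params <- function(p, ord) {
  mvhmm_params(p$pi[ord], p$Pi[ord, ord, drop = FALSE], p$M[ord],
               p$Sigma[ord], p$Psi[ord],
               row_code = p$row_code, col_code = p$col_code)
}

permute_decomp <- function(dc, ord) {
  list(sig = list(lam = dc$sig$lam[ord], Gamma = dc$sig$Gamma[ord],
                  delta = dc$sig$delta[ord]),
       psi = list(Gamma = dc$psi$Gamma[ord], delta = dc$psi$delta[ord]))
}

z_as_matrix <- function(z) {
  d <- dim(z)
  m <- aperm(z, c(2, 1, 3))
  dim(m) <- c(d[1] * d[2], d[3])
  m
}

normalize_rows <- function(m) {
  rs <- rowSums(m)
  bad <- rs <= 0
  m[bad, ] <- 1
  rs[bad] <- ncol(m)
  m / rs
}

#' @export
print.mvhmm <- function(x, ...) {
  cat("Matrix-variate HMM (", x$params$row_code, "-", x$params$col_code,
      "), K = ", x$params$K, "\n", sep = "")
  cat("  data: I = ", x$dims["I"], ", T = ", x$dims["T"], ", P = ",
      x$dims["P"], ", R = ", x$dims["R"], "\n", sep = "")
  cat("  log-likelihood = ", format(x$loglik), ", parameters = ", x$n_params,
      ", BIC = ", format(x$bic), "\n", sep = "")
  cat("  converged: ", x$converged, " after ", x$n_iter, " sweeps",
      if (x$n_restarts > 0) paste0(" (", x$n_restarts, " restarts)"),
      "\n", sep = "")
  invisible(x)
}

#' @export
logLik.mvhmm <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$nobs,
            class = "logLik")
}
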