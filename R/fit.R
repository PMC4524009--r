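#' Tally error run lengths
#'
#' Builds the run-length histogram used for model fitting. The indexing
#' convention travels with the data: mismatch runs are zero-indexed,
#' indel runs one-indexed (interarrival times of failures).
#'
#' @param lengths Integer vector of observed run lengths (already on the
#'   stated index convention, e.g. from [sample_run_lengths()]).
#' @param type One of `"mismatch"`, `"insertion"`, `"deletion"`.
#' @return A `fragment_tally`: tibble `length`, `count`, with attributes
#'   `type` and `indexing` (`0` or `1`).
#' @export
fragment_tally <- function(lengths, type = c("mismatch", "insertion",
                                             "deletion")) {
  type <- match.arg(type)
  lo <- if (type == "mismatch") 0L else 1L
  stopifnot(all(lengths >= lo))
  tb <- dplyr::count(tibble::tibble(length = as.integer(lengths)),
                     .data$length, name = "count")
  structure(tb, class = c("fragment_tally", class(tb)),
            type = type, indexing = lo)
}

# Weighted negative log-likelihood of the mixture over a tally, on the
# unconstrained scale th = (logit a, log mean-ish, logit p[, log shape]).
mixture_nll <- function(th, tally, type) {
  cmp <- if (type == "mismatch") {
    list(a = stats::plogis(th[1]), lambda = exp(th[2]),
         p = stats::plogis(th[3]))
  } else {
    list(a = stats::plogis(th[1]), scale = exp(th[2]),
         p = stats::plogis(th[3]), shape = exp(th[4]))
  }
  pmf <- mixture_pmf(tally$length, cmp, type)
  -sum(tally$count * log(pmax(pmf, 1e-300)))
}

# One-sample KS of a tally against the fitted discrete CDF; plain
# (conservative) statistic with the asymptotic Kolmogorov p-value.
ks_tally <- function(tally, cmp, type) {
  n <- sum(tally$count)
  lo <- if (type == "mismatch") 0L else 1L
  # both ECDF and the fitted CDF are step functions on the integer grid, so
  # the supremum is attained on the grid (including unobserved values)
  grid <- lo:max(tally$length)
  cnt <- integer(length(grid))
  cnt[match(tally$length, grid)] <- tally$count
  ecdf <- cumsum(cnt) / n
  Fx <- cumsum(mixture_pmf(grid, cmp, type))
  D <- max(abs(ecdf - Fx))
  x <- sqrt(n) * D
  j <- 1:100
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * x^2))
  list(statistic = D, p.value = min(1, max(0, p)))
}

#' Fit the run-length mixture by maximum likelihood
#'
#' Estimates the two-component mixture for one error type from a run-length
#' tally by numerical optimization (Nelder-Mead on transformed parameters,
#' multiple restarts) and tests the fit with a Kolmogorov-Smirnov test of
#' the empirical distribution against the fitted mixture (plain KS, which
#' is conservative on discrete data). A mixture weight within 0.05 of the
#' 0/1 boundary is flagged degenerate (the data are explained by a single
#' component).
#'
#' @param tally A `fragment_tally` (or an integer vector of run lengths)
#'   with at least 100 observations.
#' @param type Error type; defaults to the tally's own.
#' @param n_restarts Number of random optimizer restarts (default 8).
#' @param seed Optional integer seed for the restart draws.
#' @return A `run_length_fit` list: `type`, `params` (named estimates),
#'   `ks_stat`, `ks_p`, `logLik`, `n`, `converged`, `degenerate`.
#'   Non-convergence after all restarts is an explicit error.
#' @export
fit_mixture <- function(tally, type = NULL, n_restarts = 8, seed = NULL) {
  if (!inherits(tally, "fragment_tally")) {
    stopifnot(!is.null(type))
    tally <- fragment_tally(tally, type)
  }
  type <- type %||% attr(tally, "type")
  n <- sum(tally$count)
  if (n < 100) stop("need >= 100 observations to fit the mixture (have ", n, ")")

  mu <- sum(tally$length * tally$count) / n
  npar <- if (type == "mismatch") 3L else 4L
  with_opt_seed(seed, {
    inits <- lapply(seq_len(n_restarts), function(i) {
      a0 <- stats::runif(1, 0.2, 0.8)
      if (type == "mismatch") {
        c(stats::qlogis(a0), log(max(mu * stats::runif(1, 0.5, 2), 0.1)),
          stats::qlogis(stats::runif(1, 0.2, 0.8)))
      } else {
        c(stats::qlogis(a0), log(max(mu * stats::runif(1, 0.5, 2), 0.5)),
          stats::qlogis(stats::runif(1, 0.1, 0.7)),
          log(stats::runif(1, 0.7, 2)))
      }
    })
    fits <- lapply(inits, function(th0) {
      tryCatch(stats::optim(th0, mixture_nll, tally = tally, type = type,
                            method = "Nelder-Mead",
                            control = list(maxit = 2000)),
               error = function(e) NULL)
    })
    fits <- Filter(function(f) !is.null(f) && f$convergence == 0, fits)
    if (length(fits) == 0) {
      stop("mixture optimizer failed to converge after ", n_restarts,
           " restarts (", type, ")")
    }
    best <- fits[[which.min(vapply(fits, `[[`, double(1), "value"))]]
    th <- best$par
    params <- if (type == "mismatch") {
      c(a = stats::plogis(th[1]), lambda = exp(th[2]),
        p = stats::plogis(th[3]))
    } else {
      c(a = stats::plogis(th[1]), scale = exp(th[2]),
        p = stats::plogis(th[3]), shape = exp(th[4]))
    }
    cmp <- as.list(params)
    ks <- ks_tally(tally, cmp, type)
    structure(list(type = type, params = params,
                   ks_stat = ks$statistic, ks_p = ks$p.value,
                   logLik = -best$value, n = n, converged = TRUE,
                   degenerate = params[["a"]] < 0.05 || params[["a"]] > 0.95),
              class = "run_length_fit")
  })
}

#' @export
print.run_length_fit <- function(x, ...) {
  cat("<run_length_fit>", x$type, "| n =", x$n, "\n")
  print(round(x$params, 4))
  cat("KS D =", signif(x$ks_stat, 3), ", p =", signif(x$ks_p, 3),
      if (x$degenerate) "(degenerate mixture weight)" else "", "\n")
  invisible(x)
}

#' Tidy a run-length mixture fit
#'
#' @param x A `run_length_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`).
#' @importFrom generics tidy
#' @export
tidy.run_length_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params), estimate = unname(x$params))
}

#' Glance at a run-length mixture fit
#'
#' @param x A `run_length_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `type`, `n`, `logLik`, `ks_stat`, `ks_p`,
#'   `converged`, `degenerate`.
#' @importFrom generics glance
#' @export
glance.run_length_fit <- function(x, ...) {
  tibble::tibble(type = x$type, n = x$n, logLik = x$logLik,
                 ks_stat = x$ks_stat, ks_p = x$ks_p,
                 converged = x$converged, degenerate = x$degenerate)
}

#' @export
generics::tidy

#' @export
generics::glance
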