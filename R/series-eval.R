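# Numeric evaluation of truncated series on space-time grids, partial-sum
# convergence diagnostics, and the closed-form limit of the exponential-data
# example.

#' Space-time evaluation grid
#'
#' @param x_values strictly ascending numeric vector.
#' @param t_values strictly ascending nonnegative numeric vector.
#' @return an `eval_grid` object.
#' @export
eval_grid <- function(x_values, t_values) {
  stopifnot(length(x_values) >= 1, length(t_values) >= 1,
            all(is.finite(x_values)), all(is.finite(t_values)),
            all(diff(x_values) > 0) || length(x_values) == 1,
            all(diff(t_values) > 0) || length(t_values) == 1,
            all(t_values >= 0))
  structure(list(x_values = x_values, t_values = t_values), class = "eval_grid")
}

# numeric parameter bindings for substitution (paper symbols m, n)
.param_env <- function(params) {
  stopifnot(inherits(params, "ks_parameters"))
  list(a = params$a, b = params$b, c = params$c, d = params$d,
       m = params$amp_u, n = params$amp_rho)
}

# evaluate one expression on the |x| x |t| grid
.grid_eval <- function(e, params, grid) {
  env <- .param_env(params)
  nx <- length(grid$x_values); nt <- length(grid$t_values)
  out <- matrix(0, nx, nt)
  for (j in seq_len(nt)) {
    env$x <- grid$x_values; env$t <- grid$t_values[j]
    out[, j] <- px_eval(e, env)
  }
  out
}

#' Evaluate a truncated series on a grid
#'
#' Sums the series terms pointwise with the given parameter values.  Each
#' point where the magnitude of the last term exceeds the magnitude of the
#' previous term is flagged as (heuristically) outside the truncated
#' series' validity region; non-finite sums are flagged too, never fatal.
#'
#' @param series an `hdm_series` (fields `u`, `rho`).
#' @param params a [ks_parameters()] object binding `a, b, c, d, m, n`.
#' @param grid an [eval_grid()].
#' @param N highest order to sum (defaults to the series truncation).
#' @return an `hdm_eval` object: matrices `u_values`, `rho_values`
#'   (`|x| x |t|`), logical matrices `diverged_u`, `diverged_rho`, plus the
#'   grid and truncation used.  `as.data.frame()` gives the long form with
#'   columns `x, t, u, rho, diverged`.
#' @export
hdm_evaluate <- function(series, params, grid, N = series$truncation) {
  stopifnot(inherits(series, "hdm_series"), inherits(grid, "eval_grid"),
            N >= 0, N <= series$truncation)
  res <- list()
  for (f in series$fields) {
    term_vals <- lapply(0:N, function(k)
      .grid_eval(as_pexpr(series$terms[[k + 1]][[f]]), params, grid))
    total <- Reduce(`+`, term_vals)
    if (N >= 1) {
      flag <- abs(term_vals[[N + 1]]) > abs(term_vals[[N]])
    } else flag <- matrix(FALSE, nrow(total), ncol(total))
    flag <- flag | !is.finite(total)
    res[[paste0(f, "_values")]] <- total
    res[[paste0("diverged_", f)]] <- flag
  }
  structure(c(res, list(x_values = grid$x_values, t_values = grid$t_values,
                        truncation = N, fields = series$fields)),
            class = "hdm_eval")
}

#' @export
as.data.frame.hdm_eval <- function(x, ...) {
  nx <- length(x$x_values); nt <- length(x$t_values)
  df <- data.frame(
    x = rep(x$x_values, times = nt),
    t = rep(x$t_values, each = nx),
    u = as.vector(x$u_values),
    rho = as.vector(x$rho_values),
    diverged = as.vector(x$diverged_u | x$diverged_rho))
  df
}

#' Closed-form limit of the amoebae series for exponential initial data
#'
#' For the linear-sensitivity model with `u(x,0) = m e^{-x}`,
#' `rho(x,0) = n e^{-x}`, the amoebae series sums in closed form to
#' `u(x,t) = m e^{a t - x}`.
#'
#' @param params a [ks_parameters()] object (uses `a` and `amp_u`).
#' @param x,t evaluation points (vectorised).
#' @return numeric.
#' @export
closed_form_u <- function(params, x, t) {
  stopifnot(inherits(params, "ks_parameters"))
  params$amp_u * exp(params$a * t - x)
}

#' Partial-sum convergence report
#'
#' For every order `k = 1..N` reports the largest partial-sum increment
#' `max |S_k - S_{k-1}|` over the grid per field, and — when a closed form
#' is supplied — the largest remaining distance `max |S_k - closed|` for the
#' amoebae field.
#'
#' @param series an `hdm_series` with truncation at least 2.
#' @param params a [ks_parameters()].
#' @param grid an [eval_grid()].
#' @param closed_form optional function `(params, x, t)` giving the exact
#'   amoebae field (e.g. [closed_form_u()] for the exponential-data example).
#' @return tibble with columns `order`, `field`, `max_delta`,
#'   `max_closed_err` (`NA` where no closed form applies).
#' @export
convergence_report <- function(series, params, grid, closed_form = NULL) {
  stopifnot(series$truncation >= 2)
  rows <- list()
  xg <- rep(grid$x_values, times = length(grid$t_values))
  tg <- rep(grid$t_values, each = length(grid$x_values))
  closed <- if (!is.null(closed_form)) closed_form(params, xg, tg)
  for (f in series$fields) {
    S <- .grid_eval(as_pexpr(series$terms[[1]][[f]]), params, grid)
    for (k in seq_len(series$truncation)) {
      term <- .grid_eval(as_pexpr(series$terms[[k + 1]][[f]]), params, grid)
      S <- S + term
      rows[[length(rows) + 1]] <- tibble::tibble(
        order = k, field = f, max_delta = max(abs(term)),
        max_closed_err = if (f == "u" && !is.null(closed))
          max(abs(as.vector(S) - closed)) else NA_real_)
    }
  }
  do.call(rbind, rows)
}

#' Converged partial sum of the amoebae series at a point
#'
#' Sums the amoebae terms at a single `(x, t)` until the increment falls
#' below `tol` (or orders run out).
#'
#' @param series an `hdm_series`.
#' @param params a [ks_parameters()].
#' @param x,t scalars.
#' @param tol increment threshold.
#' @param field field to sum.
#' @return list with `value`, `orders_used`, `converged`, `last_increment`.
#' @export
series_limit <- function(series, params, x, t, tol = 1e-9, field = "u") {
  env <- .param_env(params); env$x <- x; env$t <- t
  total <- 0; inc <- Inf; used <- 0
  for (k in 0:series$truncation) {
    inc <- px_eval(as_pexpr(series$terms[[k + 1]][[field]]), env)
    total <- total + inc
    used <- k
    if (k >= 1 && abs(inc) < tol) break
  }
  list(value = total, orders_used = used,
       converged = abs(inc) < tol, last_increment = abs(inc))
}

#' Quick-look plot of an evaluated series
#'
#' Line plot of both fields against `x`, one facet per field, coloured by
#' time slice.  Requires ggplot2.
#'
#' @param object an `hdm_eval`.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export autoplot.hdm_eval
autoplot.hdm_eval <- function(object, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- as.data.frame(object)
  long <- rbind(
    data.frame(x = df$x, t = df$t, field = "u", value = df$u),
    data.frame(x = df$x, t = df$t, field = "rho", value = df$rho))
  ggplot2::ggplot(long, ggplot2::aes(x = x, y = value, colour = factor(t))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~field, scales = "free_y") +
    ggplot2::labs(colour = "t", y = "concentration")
}

utils::globalVariables(c("x", "value", "t", "field"))
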