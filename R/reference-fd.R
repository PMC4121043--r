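# Independent numerical oracle: method-of-lines finite differences for the
# full Keller-Segel boundary-value problem with zero-flux Neumann
# boundaries, integrated with deSolve.
#
# Discretisation: nodes include both endpoints; all transport terms are
# written in flux form at the midpoints between nodes with zero boundary
# fluxes, which preserves the mass invariant the Neumann problem implies
# (boundary control volumes are half cells).  Second order in space.

#' Configuration of the finite-difference reference solver
#'
#' @param n_points number of spatial nodes (>= 11), endpoints included.
#' @param domain a [ks_domain()].
#' @param rel_tol,abs_tol integrator tolerances, in `(0, 1e-2]`.
#' @param t_end time horizon.
#' @return an `fd_config` object.
#' @export
fd_config <- function(n_points = 401, domain = ks_domain(-10, 10),
                      rel_tol = 1e-8, abs_tol = 1e-10, t_end = 0.1) {
  stopifnot(n_points >= 11, inherits(domain, "ks_domain"),
            rel_tol > 0, rel_tol <= 1e-2, abs_tol > 0, abs_tol <= 1e-2,
            t_end > 0)
  structure(list(n_points = as.integer(n_points), domain = domain,
                 rel_tol = rel_tol, abs_tol = abs_tol, t_end = t_end),
            class = "fd_config")
}

#' Solve a Keller-Segel model by the method of lines
#'
#' Integrates the coupled system on the configured grid with a stiff solver
#' (banded-Jacobian LSODA).  The model must use the conservative chemotactic
#' sign variant: the mixed-sign expansions of the worked nonlinear examples
#' are not divergence-form PDEs and are excluded from the oracle (the
#' constant sensitivity is accepted under either variant since its
#' chemotactic term vanishes).
#'
#' On integrator failure (e.g. chemotactic blow-up) the snapshots reached
#' are returned with `blowup = TRUE`.
#'
#' @param model a `ks_model`.
#' @param config an [fd_config()].
#' @param times snapshot times (defaults to 11 equispaced times from 0 to
#'   `t_end`).
#' @return an `fd_solution`: `x_grid`, `t_snapshots`, matrices `u_field`,
#'   `rho_field` (`n_points x length(times)`), `mass_u` (trapezoidal
#'   integral of `u` per snapshot) and `blowup`.
#' @export
fd_solve <- function(model, config, times = NULL) {
  stopifnot(inherits(model, "ks_model"), inherits(config, "fd_config"))
  if (model$sensitivity$form != "constant" &&
      model$sensitivity$sign_variant != "conservative")
    stop("fd_solve requires the conservative sign variant: ",
         "the as-printed expansions are not divergence-form PDEs")
  if (is.null(times)) times <- seq(0, config$t_end, length.out = 11)
  stopifnot(all(times >= 0), all(diff(times) > 0))
  if (times[1] > 0) times <- c(0, times)

  K <- config$n_points
  xg <- seq(config$domain$alpha, config$domain$beta, length.out = K)
  dx <- xg[2] - xg[1]
  pe <- .param_env(model$parameters)
  pe$x <- xg
  u0 <- px_eval(model$init_u, pe)
  r0 <- px_eval(model$init_rho, pe)
  chip <- chi_prime_fn(model$sensitivity)
  a <- model$parameters$a; b <- model$parameters$b
  cc <- model$parameters$c; d <- model$parameters$d

  # state interleaved (u_1, rho_1, u_2, rho_2, ...) so the Jacobian is banded
  iu <- seq(1, 2 * K, by = 2); ir <- iu + 1
  y0 <- numeric(2 * K); y0[iu] <- u0; y0[ir] <- r0
  w <- c(0.5, rep(1, K - 2), 0.5)      # control-volume widths / dx

  rhs <- function(t, y, parms) {
    u <- y[iu]; r <- y[ir]
    du <- diff(u); dr <- diff(r)
    Fu <- a * du / dx                              # diffusive flux of u at faces
    Fr <- b * dr / dx
    G <- 0.5 * (u[-K] + u[-1]) * chip(0.5 * (r[-K] + r[-1])) * dr / dx
    flux_u <- c(0, Fu - G, 0)                      # zero-flux boundaries
    flux_r <- c(0, Fr, 0)
    dudt <- diff(flux_u) / (dx * w)
    drdt <- diff(flux_r) / (dx * w) + cc * u - d * r
    dy <- numeric(2 * K); dy[iu] <- dudt; dy[ir] <- drdt
    list(dy)
  }

  sol <- tryCatch(
    deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                 method = "lsoda", jactype = "bandint", bandup = 3L,
                 banddown = 3L, rtol = config$rel_tol, atol = config$abs_tol,
                 maxsteps = 20000L),
    error = function(e) NULL)
  blowup <- is.null(sol) || nrow(sol) < length(times) ||
    any(!is.finite(sol[, -1]))
  if (is.null(sol)) sol <- matrix(c(0, y0), nrow = 1)
  tt <- sol[, 1]
  u_field <- t(sol[, 1 + iu, drop = FALSE])
  rho_field <- t(sol[, 1 + ir, drop = FALSE])
  trap <- function(v) sum(0.5 * (v[-K] + v[-1]) * dx)
  mass_u <- apply(u_field, 2, trap)
  structure(list(x_grid = xg, t_snapshots = tt, u_field = u_field,
                 rho_field = rho_field, mass_u = mass_u, blowup = blowup,
                 config = config),
            class = "fd_solution")
}

#' @export
as.data.frame.fd_solution <- function(x, ...) {
  nx <- length(x$x_grid); nt <- length(x$t_snapshots)
  data.frame(x = rep(x$x_grid, times = nt),
             t = rep(x$t_snapshots, each = nx),
             u = as.vector(x$u_field), rho = as.vector(x$rho_field))
}

#' Compare a truncated series with the finite-difference reference
#'
#' Evaluates the series on the reference solver's space-time grid and
#' reports, per field, the maximum and mean absolute difference scaled by
#' the field's maximum reference magnitude over the compared grid (sup-norm
#' relative error: pointwise ratios are ill-posed where both fields decay to
#' the floating-point floor, e.g. Gaussian tails).
#'
#' @param series an `hdm_series` (typically from [ks_solve()]).
#' @param model the `ks_model` to solve numerically (conservative variant
#'   for nonlinear sensitivities).
#' @param config an [fd_config()].
#' @param t_max compare snapshots with `t <= t_max` (default `config$t_end`).
#' @param times snapshot times passed to [fd_solve()].
#' @return tibble with columns `field`, `max_rel_err`, `mean_rel_err`,
#'   `scale`, `n_x`, `n_t`, `t_max`, `blowup`.
#' @export
compare_series_fd <- function(series, model, config, t_max = config$t_end,
                              times = NULL) {
  fd <- fd_solve(model, config, times)
  keep <- fd$t_snapshots <= t_max + 1e-12
  stopifnot(any(keep))
  grid <- eval_grid(fd$x_grid, fd$t_snapshots[keep])
  ev <- hdm_evaluate(series, model$parameters, grid)
  rows <- list()
  for (f in c("u", "rho")) {
    ref <- (if (f == "u") fd$u_field else fd$rho_field)[, keep, drop = FALSE]
    got <- if (f == "u") ev$u_values else ev$rho_values
    scale <- max(abs(ref))
    err <- abs(got - ref) / scale
    rows[[f]] <- tibble::tibble(
      field = f, max_rel_err = max(err), mean_rel_err = mean(err),
      scale = scale, n_x = length(fd$x_grid), n_t = sum(keep),
      t_max = t_max, blowup = fd$blowup)
  }
  do.call(rbind, rows)
}
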