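# Keller-Segel model definitions: parameters, sensitivity functions, the
# chemotactic-term expansions per sensitivity, and the coupled u/rho
# homotopy decomposition recursion.
#
# The system solved is
#   u_t   = a u_xx - (u * chi'(rho) * rho_x)_x        (amoebae density)
#   rho_t = b rho_xx + c u - d rho                    (chemoattractant)
# on a bounded interval with zero-flux Neumann boundaries.  Two sign
# conventions for the chemotactic expansion are supported: "as_printed"
# reproduces the worked examples' mixed-sign expansions term for term, and
# "conservative" is the self-consistent divergence form (the only variant
# admissible in the finite-difference oracle).

#' Keller-Segel model parameters
#'
#' @param a amoebae diffusivity (> 0).
#' @param b chemical diffusivity (> 0).
#' @param c chemical production rate (> 0 in the biological model; 0 is
#'   admitted for degenerate diagnostic configurations such as
#'   mass-conservation checks).
#' @param d chemical decay rate (> 0, or 0 as for `c`).
#' @param amp_u initial amplitude of the amoebae field (rendered as symbol
#'   `m` in expressions).
#' @param amp_rho initial amplitude of the chemical field (symbol `n`).
#' @return a `ks_parameters` object (named list).
#' @export
ks_parameters <- function(a, b, c, d, amp_u = 1, amp_rho = 1) {
  vals <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(vals)) || a <= 0 || b <= 0 || c < 0 || d < 0)
    stop("diffusivities a, b must be strictly positive and rates c, d nonnegative")
  if (!is.finite(amp_u) || !is.finite(amp_rho))
    stop("initial amplitudes must be finite")
  structure(list(a = a, b = b, c = c, d = d, amp_u = amp_u, amp_rho = amp_rho),
            class = "ks_parameters")
}

#' Chemotactic sensitivity specification
#'
#' @param form one of `"constant"` (`chi = 1`), `"linear"` (`chi = rho`),
#'   `"quadratic"` (`chi = rho^2`), or `"generic"` with `chi` supplied.
#' @param sign_variant `"as_printed"` (the worked examples' expansion, the
#'   default for fixture verification) or `"conservative"` (the divergence
#'   form `-(u chi'(rho) rho_x)_x`, required by the reference solver).  The
#'   two coincide for the constant sensitivity.
#' @param chi for `form = "generic"`: a quoted R expression or string in
#'   `rho`, smooth on `(0, Inf)`.
#' @return a `ks_sensitivity` object.
#' @export
ks_sensitivity <- function(form = c("constant", "linear", "quadratic", "generic"),
                           sign_variant = c("as_printed", "conservative"),
                           chi = NULL) {
  form <- match.arg(form)
  sign_variant <- match.arg(sign_variant)
  if (form == "generic") {
    if (is.null(chi)) stop("generic sensitivity requires a chi expression in rho")
    if (is.character(chi)) chi <- str2lang(chi)
    if (!"rho" %in% all.vars(chi)) stop("generic chi must be an expression in rho")
  }
  structure(list(form = form, sign_variant = sign_variant, chi = chi),
            class = "ks_sensitivity")
}

# chi'(rho) as a numeric function (used by the finite-difference solver)
chi_prime_fn <- function(sensitivity) {
  switch(sensitivity$form,
    constant  = function(rho) rep(0, length(rho)),
    linear    = function(rho) rep(1, length(rho)),
    quadratic = function(rho) 2 * rho,
    generic   = {
      dchi <- stats::D(sensitivity$chi, "rho")
      function(rho) eval(dchi, list(rho = rho))
    })
}

#' Spatial domain with zero-flux boundaries
#'
#' @param alpha,beta interval endpoints, `alpha < beta`.  The boundary
#'   condition is Neumann zero-flux for both fields at both endpoints.
#' @return a `ks_domain` object.
#' @export
ks_domain <- function(alpha, beta) {
  stopifnot(is.finite(alpha), is.finite(beta), alpha < beta)
  structure(list(alpha = alpha, beta = beta, boundary = "neumann_zero_flux"),
            class = "ks_domain")
}

#' Assemble a Keller-Segel model instance
#'
#' @param parameters a [ks_parameters()] object.
#' @param sensitivity a [ks_sensitivity()] object.
#' @param domain a [ks_domain()] object.
#' @param init_u,init_rho initial conditions: expressions in `x` (strings or
#'   parsed).  The amplitude symbols `m`, `n` may appear; they are bound to
#'   `amp_u`, `amp_rho` at numeric evaluation time.
#' @return a `ks_model` object.
#' @export
ks_model <- function(parameters, sensitivity, domain, init_u, init_rho) {
  stopifnot(inherits(parameters, "ks_parameters"),
            inherits(sensitivity, "ks_sensitivity"),
            inherits(domain, "ks_domain"))
  structure(list(parameters = parameters, sensitivity = sensitivity,
                 domain = domain,
                 init_u = as_pexpr(init_u), init_rho = as_pexpr(init_rho)),
            class = "ks_model")
}

#' Registry of the worked examples
#'
#' Returns the model for one of the worked examples, with the published
#' parameter sets: `ex1` uses the constant sensitivity with Gaussian initial
#' data and `{m = 120, n = 160, a = 0.5, b = 3, c = 1, d = 2}`; `ex2_case1`
#' (exponential data) and `ex2_case2` (Gaussian data) use the linear
#' sensitivity and `ex3` (sinusoidal data) the quadratic one, all with
#' `{m = 120, n = 160, a = 0.5, b = 0.001, c = 1, d = 2}`.
#'
#' @param example_id one of `"ex1"`, `"ex2_case1"`, `"ex2_case2"`, `"ex3"`.
#' @param sign_variant chemotactic sign convention, see [ks_sensitivity()].
#' @return a `ks_model`.
#' @export
ks_example <- function(example_id = c("ex1", "ex2_case1", "ex2_case2", "ex3"),
                       sign_variant = "as_printed") {
  example_id <- match.arg(example_id)
  pars <- switch(example_id,
    ex1 = ks_parameters(a = 0.5, b = 3, c = 1, d = 2, amp_u = 120, amp_rho = 160),
    ks_parameters(a = 0.5, b = 0.001, c = 1, d = 2, amp_u = 120, amp_rho = 160))
  form <- switch(example_id, ex1 = "constant",
                 ex2_case1 = , ex2_case2 = "linear", ex3 = "quadratic")
  dom <- switch(example_id,
    ex1 = , ex2_case2 = ks_domain(-10, 10),
    ex2_case1 = ks_domain(0, 20),
    ex3 = ks_domain(-pi, pi))
  init <- switch(example_id,
    ex1 = , ex2_case2 = c("m*exp(-x^2)", "n*exp(-x^2)"),
    ex2_case1 = c("m*exp(-x)", "n*exp(-x)"),
    ex3 = c("m*sin(x)", "n*sin(x)"))
  ks_model(pars, ks_sensitivity(form, sign_variant), dom,
           init_u = init[1], init_rho = init[2])
}

## ---- chemotactic term ----------------------------------------------------

#' Order-n chemotactic contribution to the u-recursion
#'
#' Returns the order-`n` chemotactic integrand (the order `n - 1` He
#' polynomial of the chemotactic operator) for the configured sensitivity
#' and sign variant, by discrete convolution over term orders.
#'
#' For the constant sensitivity the term is identically zero.  For the
#' linear sensitivity, `as_printed` yields
#' `-sum_j u_j' rho'_{n-1-j} + sum_j u_j rho''_{n-1-j}` and `conservative`
#' yields `-sum_j (u_j' rho'_{n-1-j} + u_j rho''_{n-1-j})`.  For the
#' quadratic sensitivity the sums are double convolutions of the trilinear
#' factors.  Generic sensitivities have no closed convolution; use
#' [he_polynomial_quoted()] on the divergence form instead.
#'
#' @param model a `ks_model`.
#' @param terms per-order named lists of expressions with fields `u`, `rho`,
#'   orders `0 .. n-1` at least.
#' @param n order (positive integer).
#' @return expression.
#' @export
chemotactic_integrand <- function(model, terms, n) {
  stopifnot(inherits(model, "ks_model"), n >= 1)
  spec <- chemotactic_spec(model$sensitivity)
  if (is.null(spec)) return(px_zero())
  he_polynomial_convolution(spec, terms, n - 1, fields = c("u", "rho"))
}

# product-form factor spec of the chemotactic operator, or NULL when the
# term vanishes identically (constant sensitivity)
chemotactic_spec <- function(sensitivity) {
  form <- sensitivity$form
  variant <- sensitivity$sign_variant
  if (form == "constant") return(NULL)
  f <- function(field, deriv) list(field = field, deriv = deriv)
  if (form == "linear") {
    if (variant == "as_printed")
      return(list(
        list(coef = -1, factors = list(f("u", 1), f("rho", 1))),
        list(coef = +1, factors = list(f("u", 0), f("rho", 2)))))
    return(list(  # -(u rho_x)_x = -u_x rho_x - u rho_xx
      list(coef = -1, factors = list(f("u", 1), f("rho", 1))),
      list(coef = -1, factors = list(f("u", 0), f("rho", 2)))))
  }
  if (form == "quadratic") {
    if (variant == "as_printed")
      return(list(
        list(coef = -2, factors = list(f("rho", 0), f("u", 1), f("rho", 1))),
        list(coef = +2, factors = list(f("u", 0), f("rho", 0), f("rho", 2))),
        list(coef = +2, factors = list(f("u", 0), f("rho", 1), f("rho", 1)))))
    return(list(  # -(2 u rho rho_x)_x
      list(coef = -2, factors = list(f("u", 1), f("rho", 0), f("rho", 1))),
      list(coef = -2, factors = list(f("u", 0), f("rho", 1), f("rho", 1))),
      list(coef = -2, factors = list(f("u", 0), f("rho", 0), f("rho", 2)))))
  }
  stop("no closed convolution form for generic sensitivity; ",
       "use he_polynomial_quoted() on the divergence form")
}

#' Build the coupled homotopy decomposition problem for a Keller-Segel model
#'
#' The u-equation has linear part `a u_xx` and the chemotactic nonlinearity
#' per the model's sensitivity spec; the rho-equation is linear:
#' `b rho_xx + c u - d rho`.
#'
#' @param model a `ks_model`.
#' @return an `hdm_problem` over fields `u`, `rho`, symbolic in
#'   `a, b, c, d, m, n`.
#' @export
build_problem <- function(model) {
  stopifnot(inherits(model, "ks_model"))
  a <- px_sym("a"); b <- px_sym("b"); cc <- px_sym("c"); d <- px_sym("d")
  linear <- function(prev) list(
    u = px_mul(a, px_deriv(as_pexpr(prev$u), "x", 2)),
    rho = px_add(px_mul(b, px_deriv(as_pexpr(prev$rho), "x", 2)),
                 px_sub(px_mul(cc, as_pexpr(prev$u)),
                        px_mul(d, as_pexpr(prev$rho)))))
  nonlinear <- if (model$sensitivity$form == "constant") NULL else
    function(terms, n) list(u = chemotactic_integrand(model, terms, n))
  general_problem(fields = c("u", "rho"),
                  initial = list(u = model$init_u, rho = model$init_rho),
                  linear = linear, nonlinear = nonlinear,
                  time_order = 1, check_linearity = FALSE)
}

#' Solve a Keller-Segel model to a truncation order
#'
#' Convenience wrapper: [build_problem()] then [hdm_solve()].
#'
#' @param model a `ks_model` (or example id string).
#' @param N truncation order.
#' @return an `hdm_series`.
#' @export
ks_solve <- function(model, N = 4) {
  if (is.character(model)) model <- ks_example(model)
  hdm_solve(build_problem(model), N)
}
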