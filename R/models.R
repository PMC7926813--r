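#' Dispersive dielectric model constructors
#'
#' Constructors for the dielectric models used throughout the package.
#' `cole_cole()` builds a multi-pole Cole-Cole dispersion (the standard
#' description of biological tissues), `debye()` a single-pole Debye
#' relaxation (used for Triton X-100), `saline()` a salinity- and
#' temperature-parametric Debye model of NaCl solutions, and
#' `tissue_blend()` a volume-weighted blend of tissue models (e.g. the brain
#' modelled as 75 % white and 25 % grey matter).
#'
#' All models share the sign convention `eps = eps' - j eps''` with
#' `eps'' >= 0` (time factor `e^{+j w t}`); evaluations return R complex
#' numbers with non-positive imaginary part.
#'
#' @param eps_inf Optical (infinite-frequency) relative permittivity,
#'   dimensionless, `>= 1`.
#' @param delta_eps Numeric vector of pole amplitudes (dimensionless,
#'   `>= 0`), one per dispersion pole.
#' @param tau Numeric vector of relaxation times in seconds (`> 0`), same
#'   length as `delta_eps`.
#' @param alpha Numeric vector of Cole-Cole broadening exponents in
#'   `[0, 1)`; `alpha = 0` reduces a pole to a Debye term. Recycled to the
#'   length of `delta_eps`.
#' @param sigma_static Static (ionic) conductivity in S/m, `>= 0`.
#' @param label Optional human-readable name carried through to printing.
#'
#' @return An object of class `"cole_cole"`, `"debye"`, `"saline"` or
#'   `"tissue_blend"`; all inherit class `"diel_model"` and can be passed to
#'   [permittivity()] and [dielectric_spectrum()].
#'
#' @examples
#' m <- cole_cole(4, delta_eps = c(65, 40), tau = c(7.958e-12, 1.592e-9),
#'                alpha = c(0.1, 0), sigma_static = 2)
#' permittivity(m, 1e9)
#' @export
cole_cole <- function(eps_inf, delta_eps, tau, alpha = 0, sigma_static = 0,
                      label = NULL) {
  check_number(eps_inf, "eps_inf", lower = 1)
  if (length(delta_eps) != length(tau)) {
    abort("`delta_eps` and `tau` must have the same length (one entry per pole).")
  }
  alpha <- rep_len(alpha, length(delta_eps))
  check_numeric(delta_eps, "delta_eps", lower = 0)
  check_numeric(tau, "tau", lower = 0, strict = TRUE)
  check_numeric(alpha, "alpha", lower = 0, upper = 1, upper_open = TRUE)
  check_number(sigma_static, "sigma_static", lower = 0)
  structure(
    list(eps_inf = eps_inf, delta_eps = delta_eps, tau = tau, alpha = alpha,
         sigma_static = sigma_static, label = label),
    class = c("cole_cole", "diel_model")
  )
}

#' @rdname cole_cole
#' @param eps_static Static relative permittivity of the Debye model,
#'   `>= eps_inf`.
#' @export
debye <- function(eps_static, eps_inf, tau, sigma_static = 0, label = NULL) {
  check_number(eps_static, "eps_static", lower = 1)
  check_number(eps_inf, "eps_inf", lower = 1)
  if (eps_static < eps_inf) {
    abort("`eps_static` must be >= `eps_inf` for a passive Debye model.")
  }
  check_number(tau, "tau", lower = 0, strict = TRUE)
  check_number(sigma_static, "sigma_static", lower = 0)
  structure(
    list(eps_static = eps_static, eps_inf = eps_inf, tau = tau,
         sigma_static = sigma_static, label = label),
    class = c("debye", "diel_model")
  )
}

# declared validity window of the parametric saline model
SALINE_NACL_RANGE <- c(0, 160)  # g/L
SALINE_TEMP_RANGE <- c(0, 50)   # degrees C

#' @rdname cole_cole
#' @param nacl_g_l NaCl concentration in grams per litre of solution,
#'   within `[0, 160]` g/L.
#' @param temperature_c Temperature in degrees Celsius, within `[0, 50]`.
#' @export
saline <- function(nacl_g_l, temperature_c = 25) {
  check_number(nacl_g_l, "nacl_g_l")
  check_number(temperature_c, "temperature_c")
  if (nacl_g_l < SALINE_NACL_RANGE[1] || nacl_g_l > SALINE_NACL_RANGE[2]) {
    abort(sprintf(
      "`nacl_g_l` = %g is outside the declared validity window [%g, %g] g/L.",
      nacl_g_l, SALINE_NACL_RANGE[1], SALINE_NACL_RANGE[2]))
  }
  if (temperature_c < SALINE_TEMP_RANGE[1] || temperature_c > SALINE_TEMP_RANGE[2]) {
    abort(sprintf(
      "`temperature_c` = %g is outside the declared validity window [%g, %g] C.",
      temperature_c, SALINE_TEMP_RANGE[1], SALINE_TEMP_RANGE[2]))
  }
  structure(
    list(nacl_g_l = nacl_g_l, temperature_c = temperature_c),
    class = c("saline", "diel_model")
  )
}

#' @rdname cole_cole
#' @param models List of dielectric model objects to blend.
#' @param weights Volume fractions, non-negative, summing to 1 within 1e-9.
#' @export
tissue_blend <- function(models, weights, label = NULL) {
  if (!is.list(models) || !all(vapply(models, inherits, logical(1), "diel_model"))) {
    abort("`models` must be a list of dielectric model objects.")
  }
  check_numeric(weights, "weights", lower = 0)
  if (length(models) != length(weights)) {
    abort("`models` and `weights` must have the same length.")
  }
  if (abs(sum(weights) - 1) > 1e-9) {
    abort(sprintf("`weights` must sum to 1 (got %.12g).", sum(weights)))
  }
  structure(
    list(models = models, weights = weights, label = label),
    class = c("tissue_blend", "diel_model")
  )
}

#' @export
print.diel_model <- function(x, ...) {
  lab <- x$label %||% class(x)[1]
  cat("<", class(x)[1], "> ", lab, "\n", sep = "")
  switch(class(x)[1],
    cole_cole = cat(sprintf(
      "  eps_inf = %g, %d pole(s), sigma_static = %g S/m\n",
      x$eps_inf, length(x$delta_eps), x$sigma_static)),
    debye = cat(sprintf(
      "  eps_static = %g, eps_inf = %g, tau = %g s, sigma_static = %g S/m\n",
      x$eps_static, x$eps_inf, x$tau, x$sigma_static)),
    saline = cat(sprintf("  NaCl = %g g/L at %g C\n", x$nacl_g_l, x$temperature_c)),
    tissue_blend = cat(sprintf(
      "  %d components, weights: %s\n",
      length(x$models), paste(signif(x$weights, 4), collapse = ", ")))
  )
  invisible(x)
}

# -- internal validators ------------------------------------------------------

check_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict && x <= lower) abort(sprintf("`%s` must be > %g.", name, lower))
  if (!strict && x < lower) abort(sprintf("`%s` must be >= %g.", name, lower))
  invisible(x)
}

check_numeric <- function(x, name, lower = -Inf, upper = Inf,
                          strict = FALSE, upper_open = FALSE) {
  if (!is.numeric(x) || anyNA(x)) {
    abort(sprintf("`%s` must be numeric without missing values.", name))
  }
  bad <- if (strict) any(x <= lower) else any(x < lower)
  if (bad) {
    abort(sprintf("all elements of `%s` must be %s %g.",
                  name, if (strict) ">" else ">=", lower))
  }
  bad_up <- if (upper_open) any(x >= upper) else any(x > upper)
  if (bad_up) {
    abort(sprintf("all elements of `%s` must be %s %g.",
                  name, if (upper_open) "<" else "<=", upper))
  }
  invisible(x)
}
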