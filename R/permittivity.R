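#' Frequency grids
#'
#' Build a frequency grid in Hz. The default is the band used for recipe
#' fitting: 26 linearly spaced points over 0.5-3 GHz.
#'
#' @param f_min,f_max Band edges in Hz, `0 < f_min < f_max`.
#' @param n_points Number of samples, `>= 2`.
#' @param spacing `"linear"` or `"log"`.
#' @return Strictly increasing numeric vector of frequencies in Hz.
#' @examples
#' freq_band()
#' freq_band(1e9, 1e9, n_points = 1)
#' @export
freq_band <- function(f_min = 0.5e9, f_max = 3e9, n_points = 26,
                      spacing = c("linear", "log")) {
  spacing <- match.arg(spacing)
  check_number(f_min, "f_min", lower = 0, strict = TRUE)
  check_number(f_max, "f_max", lower = 0, strict = TRUE)
  if (n_points == 1 && f_min == f_max) return(f_min)
  if (f_min >= f_max) abort("`f_min` must be < `f_max`.")
  if (n_points < 2) abort("`n_points` must be >= 2.")
  if (spacing == "linear") seq(f_min, f_max, length.out = n_points)
  else exp(seq(log(f_min), log(f_max), length.out = n_points))
}

#' Evaluate complex relative permittivity
#'
#' Evaluates a dielectric model on a frequency grid under the
#' `eps = eps' - j eps''` convention (`Im <= 0` for passive media).
#'
#' @param model A model built by [cole_cole()], [debye()], [saline()] or
#'   [tissue_blend()].
#' @param frequencies Frequencies in Hz, all `> 0`.
#' @param ... Passed on to methods.
#' @return Complex vector, one value per frequency.
#' @export
permittivity <- function(model, frequencies, ...) {
  check_numeric(frequencies, "frequencies", lower = 0, strict = TRUE)
  UseMethod("permittivity")
}

#' @export
permittivity.cole_cole <- function(model, frequencies, ...) {
  w <- 2 * pi * frequencies
  eps <- rep(model$eps_inf + 0i, length(w))
  for (k in seq_along(model$delta_eps)) {
    eps <- eps + model$delta_eps[k] /
      (1 + (1i * w * model$tau[k])^(1 - model$alpha[k]))
  }
  eps + model$sigma_static / (1i * w * EPS0)
}

#' @export
permittivity.debye <- function(model, frequencies, ...) {
  w <- 2 * pi * frequencies
  model$eps_inf + (model$eps_static - model$eps_inf) / (1 + 1i * w * model$tau) +
    model$sigma_static / (1i * w * EPS0)
}

#' @export
permittivity.saline <- function(model, frequencies, ...) {
  p <- saline_parameters(model$nacl_g_l, model$temperature_c)
  w <- 2 * pi * frequencies
  p$eps_inf + (p$eps_static - p$eps_inf) / (1 + 1i * w * p$tau) +
    p$sigma / (1i * w * EPS0)
}

#' @export
permittivity.tissue_blend <- function(model, frequencies, ...) {
  acc <- rep(0 + 0i, length(frequencies))
  for (k in seq_along(model$models)) {
    acc <- acc + model$weights[k] * permittivity(model$models[[k]], frequencies)
  }
  acc
}

# Parametric saline model (Stogryn 1971 style): Debye parameters and ionic
# conductivity as polynomials in normality N and temperature T.  The
# user-facing concentration unit is g/L; normality is N = c / 58.44 (molar
# mass of NaCl).  Returns the parameters and their derivatives w.r.t. the
# g/L concentration (needed by the recipe optimizer).
saline_parameters <- function(nacl_g_l, temperature_c) {
  N <- nacl_g_l / NACL_MOLAR_MASS
  dN <- 1 / NACL_MOLAR_MASS
  T <- temperature_c

  es0 <- 87.74 - 0.40008 * T + 9.398e-4 * T^2 + 1.410e-6 * T^3
  aN <- 1 - 0.2551 * N + 5.151e-2 * N^2 - 6.889e-3 * N^3
  daN <- -0.2551 + 2 * 5.151e-2 * N - 3 * 6.889e-3 * N^2

  # 2*pi*tau of salt-free water, then salinity factor
  tpt0 <- 1.1109e-10 - 3.824e-12 * T + 6.938e-14 * T^2 - 5.096e-16 * T^3
  bN <- 1 + 1.463e-3 * N * T - 4.896e-2 * N - 2.967e-2 * N^2 + 5.644e-3 * N^3
  dbN <- 1.463e-3 * T - 4.896e-2 - 2 * 2.967e-2 * N + 3 * 5.644e-3 * N^2

  s25 <- N * (10.394 - 2.3776 * N + 0.68258 * N^2 - 0.13538 * N^3 +
                1.0086e-2 * N^4)
  ds25 <- 10.394 - 2 * 2.3776 * N + 3 * 0.68258 * N^2 - 4 * 0.13538 * N^3 +
    5 * 1.0086e-2 * N^4
  D <- 25 - T
  bet <- 2.033e-2 + 1.266e-4 * D + 2.464e-6 * D^2 -
    N * (1.849e-5 - 2.551e-7 * D + 2.551e-8 * D^2)
  dbet <- -(1.849e-5 - 2.551e-7 * D + 2.551e-8 * D^2)
  att <- exp(-D * bet)

  list(
    eps_inf = 4.9,
    eps_static = es0 * aN,
    tau = tpt0 * bN / (2 * pi),
    sigma = s25 * att,
    d_eps_static = es0 * daN * dN,
    d_tau = tpt0 * dbN / (2 * pi) * dN,
    d_sigma = (ds25 * att + s25 * att * (-D) * dbet) * dN
  )
}

#' Salinity derivative of the saline permittivity
#'
#' Analytic derivative of the saline complex permittivity with respect to
#' the NaCl concentration (in g/L), at each frequency. This is the
#' `d eps2 / d S` term that the recipe optimizer chains through the mixing
#' law; it matches a central finite difference of [permittivity()] to better
#' than 1e-6 relative.
#'
#' @inheritParams permittivity
#' @param model A [saline()] model.
#' @return Complex vector, one derivative per frequency (units: 1/(g/L)).
#' @export
saline_salinity_derivative <- function(model, frequencies) {
  if (!inherits(model, "saline")) abort("`model` must be a `saline` model.")
  check_numeric(frequencies, "frequencies", lower = 0, strict = TRUE)
  p <- saline_parameters(model$nacl_g_l, model$temperature_c)
  w <- 2 * pi * frequencies
  den <- 1 + 1i * w * p$tau
  p$d_eps_static / den -
    (p$eps_static - p$eps_inf) * (1i * w * p$d_tau) / den^2 +
    p$d_sigma / (1i * w * EPS0)
}

#' Tabulate a dielectric spectrum
#'
#' Evaluates a model on a grid and returns a tibble with one row per
#' frequency: `frequency_hz`, `eps_real` (dielectric constant), `eps_imag`
#' (loss part, `>= 0`) and `sigma_s_m` (effective conductivity
#' `2 pi f eps0 eps''`).
#'
#' @inheritParams permittivity
#' @return A tibble of class `"diel_spectrum"`.
#' @examples
#' dielectric_spectrum(saline(9, 25), freq_band())
#' @export
dielectric_spectrum <- function(model, frequencies = freq_band(), ...) {
  eps <- permittivity(model, frequencies, ...)
  spectrum_tbl(frequencies, eps, label = model$label %||% class(model)[1])
}

spectrum_tbl <- function(frequencies, eps, label = NULL) {
  out <- tibble::tibble(
    frequency_hz = frequencies,
    eps_real = Re(eps),
    eps_imag = -Im(eps),
    sigma_s_m = 2 * pi * frequencies * EPS0 * -Im(eps)
  )
  class(out) <- c("diel_spectrum", class(out))
  attr(out, "label") <- label
  out
}

# Recover the complex permittivity column from a spectrum tibble.
spectrum_eps <- function(spectrum) {
  complex(real = spectrum$eps_real, imaginary = -spectrum$eps_imag)
}

#' Write a spectrum to CSV
#'
#' @param spectrum A [dielectric_spectrum()] tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  utils::write.csv(
    data.frame(frequency_Hz = spectrum$frequency_hz,
               eps_real = spectrum$eps_real,
               eps_imag = spectrum$eps_imag,
               sigma_S_per_m = spectrum$sigma_s_m),
    path, row.names = FALSE)
  invisible(path)
}

#' @exportS3Method ggplot2::autoplot
autoplot.diel_spectrum <- function(object, ...) {
  df <- rbind(
    data.frame(frequency_ghz = object$frequency_hz / 1e9,
               value = object$eps_real, quantity = "dielectric constant"),
    data.frame(frequency_ghz = object$frequency_hz / 1e9,
               value = object$sigma_s_m, quantity = "conductivity (S/m)")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frequency_ghz, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "frequency (GHz)", y = NULL,
                  title = attr(object, "label"))
}

#' @importFrom ggplot2 .data
NULL
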