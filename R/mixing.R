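#' Binary liquid mixing laws
#'
#' `mixing_laws()` lists the five supported binary mixing laws.
#' `mix_permittivity()` computes the complex permittivity of a two-component
#' mixture from the component permittivities `eps1` (Triton X-100) and
#' `eps2` (saline) and the volume fraction `v2` of component 2
#' (`v1 = 1 - v2`).
#'
#' The Kraszewski law is square-root linear,
#' `eps_m = (sqrt(eps1) + v2 (sqrt(eps2) - sqrt(eps1)))^2`, using principal
#' complex square roots (all physical permittivities here lie in the right
#' half-plane, so the branch is unambiguous). Lichtenecker is the
#' logarithmic rule and Looyenga the 1/3-power rule, again with principal
#' branches. The Bottcher and Bruggeman effective-medium laws are implicit
#' quadratics solved in closed form; the admissible root is the passive one
#' (`eps'' >= 0`, positive real part) continuous with the `v2 -> 0` limit
#' `eps_m = eps1`.
#'
#' @param eps1,eps2 Complex permittivities of components 1 and 2 (convention
#'   `eps' - j eps''`, `Im <= 0`). Vectors are recycled against each other
#'   and against `v2`.
#' @param v2 Volume fraction(s) of component 2 in `[0, 1]`.
#' @param law One of `mixing_laws()`.
#' @return Complex vector of mixture permittivities.
#' @examples
#' mix_permittivity(4, 81, 0.5, "kraszewski")  # (2 + 0.5*(9-2))^2 = 30.25
#' @export
mixing_laws <- function() {
  c("kraszewski", "bottcher", "lichtenecker", "looyenga", "bruggeman")
}

#' @rdname mixing_laws
#' @export
mix_permittivity <- function(eps1, eps2, v2, law = "kraszewski") {
  law <- match.arg(law, mixing_laws())
  check_numeric(v2, "v2", lower = 0, upper = 1)
  n <- max(length(eps1), length(eps2), length(v2))
  eps1 <- rep_len(as.complex(eps1), n)
  eps2 <- rep_len(as.complex(eps2), n)
  v2 <- rep_len(v2, n)

  out <- switch(law,
    kraszewski = (sqrt(eps1) + v2 * (sqrt(eps2) - sqrt(eps1)))^2,
    lichtenecker = exp((1 - v2) * log(eps1) + v2 * log(eps2)),
    looyenga = ((1 - v2) * eps1^(1 / 3) + v2 * eps2^(1 / 3))^3,
    bottcher = solve_quadratic_law(eps1, eps2, v2, bottcher = TRUE, law = law),
    bruggeman = solve_quadratic_law(eps1, eps2, v2, bottcher = FALSE, law = law)
  )
  # pure-component limits are exact for every law
  out[v2 == 0] <- eps1[v2 == 0]
  out[v2 == 1] <- eps2[v2 == 1]
  out
}

# Bottcher: (em - e1)(e2 + 2 em) = 3 em v2 (e2 - e1)
#   => 2 em^2 + b em - e1 e2 = 0,  b = e2 - 2 e1 - 3 v2 (e2 - e1)
# Bruggeman (symmetric): (1-v2)(e1-em)/(e1+2em) + v2(e2-em)/(e2+2em) = 0
#   => 2 em^2 - c em - e1 e2 = 0,  c = (1-v2)(2 e1 - e2) + v2 (2 e2 - e1)
solve_quadratic_law <- function(eps1, eps2, v2, bottcher, law) {
  b <- if (bottcher) {
    eps2 - 2 * eps1 - 3 * v2 * (eps2 - eps1)
  } else {
    -((1 - v2) * (2 * eps1 - eps2) + v2 * (2 * eps2 - eps1))
  }
  disc <- sqrt(b^2 + 8 * eps1 * eps2)
  r1 <- (-b + disc) / 4
  r2 <- (-b - disc) / 4
  pick_passive_root(r1, r2, eps1, eps2, v2, law)
}

pick_passive_root <- function(r1, r2, eps1, eps2, v2, law) {
  tol <- 1e-9
  lin <- (1 - v2) * eps1 + v2 * eps2
  ok1 <- Im(r1) <= tol & Re(r1) > 0
  ok2 <- Im(r2) <= tol & Re(r2) > 0
  if (any(!ok1 & !ok2)) {
    i <- which(!ok1 & !ok2)[1]
    abort(sprintf(
      "no admissible (passive) root for the %s law at eps1 = %s, eps2 = %s, v2 = %g",
      law, format(eps1[i]), format(eps2[i]), v2[i]))
  }
  d1 <- ifelse(ok1, abs(r1 - lin), Inf)
  d2 <- ifelse(ok2, abs(r2 - lin), Inf)
  out <- r1
  swap <- d2 < d1
  out[swap] <- r2[swap]
  out
}

#' Mixture permittivity of a TX-100/saline composition
#'
#' Evaluates the binary-mixture permittivity for a given saline volume
#' fraction and NaCl concentration, using the vendored TX-100 Debye fixture
#' and the parametric saline model. `mixture_spectrum()` returns the result
#' as a [dielectric_spectrum()] tibble.
#'
#' @inheritParams permittivity
#' @param v2_saline Saline volume fraction in `[0, 1]` (the TX-100 fraction
#'   is `1 - v2_saline`).
#' @param nacl_g_l NaCl concentration of the saline phase in g/L.
#' @param temperature_c Temperature in Celsius (saline model parameter).
#' @param law One of [mixing_laws()].
#' @param tx100 TX-100 dielectric model; defaults to the vendored fixture.
#' @return Complex vector ([mixture_permittivity()]) or a spectrum tibble
#'   ([mixture_spectrum()]).
#' @examples
#' mixture_permittivity(1e9, v2_saline = 0.95, nacl_g_l = 13.9)
#' @export
mixture_permittivity <- function(frequencies, v2_saline, nacl_g_l,
                                 temperature_c = 25, law = "kraszewski",
                                 tx100 = tx100_model()) {
  check_number(v2_saline, "v2_saline", lower = 0)
  if (v2_saline > 1) abort("`v2_saline` must be <= 1.")
  eps1 <- permittivity(tx100, frequencies)
  eps2 <- permittivity(saline(nacl_g_l, temperature_c), frequencies)
  mix_permittivity(eps1, eps2, v2_saline, law)
}

#' @rdname mixture_permittivity
#' @export
mixture_spectrum <- function(frequencies, v2_saline, nacl_g_l,
                             temperature_c = 25, law = "kraszewski",
                             tx100 = tx100_model()) {
  eps <- mixture_permittivity(frequencies, v2_saline, nacl_g_l,
                              temperature_c, law, tx100)
  out <- spectrum_tbl(frequencies, eps,
                      label = sprintf("%s mixture: %.1f vol%% TX-100, %.1f g/L NaCl",
                                      law, 100 * (1 - v2_saline), nacl_g_l))
  attr(out, "composition") <- list(v2_saline = v2_saline, nacl_g_l = nacl_g_l,
                                   temperature_c = temperature_c, law = law)
  out
}

#' Analytic mixture derivatives
#'
#' Per-frequency derivatives of the mixture permittivity with respect to the
#' two optimization unknowns: the saline volume fraction `v2` and the NaCl
#' concentration `S` (g/L). The salinity derivative chains through
#' [saline_salinity_derivative()]. All five laws have closed-form
#' derivatives (implicit differentiation for Bottcher/Bruggeman); they match
#' central finite differences of [mixture_permittivity()] to better than
#' 1e-6 relative.
#'
#' @inheritParams mixture_permittivity
#' @return A tibble with complex columns `d_eps_d_v2` and `d_eps_d_nacl`
#'   and column `frequency_hz`.
#' @export
mixture_derivatives <- function(frequencies, v2_saline, nacl_g_l,
                                temperature_c = 25, law = "kraszewski",
                                tx100 = tx100_model()) {
  law <- match.arg(law, mixing_laws())
  sal <- saline(nacl_g_l, temperature_c)
  eps1 <- permittivity(tx100, frequencies)
  eps2 <- permittivity(sal, frequencies)
  de2_dS <- saline_salinity_derivative(sal, frequencies)
  v2 <- v2_saline

  if (law == "kraszewski") {
    s1 <- sqrt(eps1); s2 <- sqrt(eps2)
    g <- s1 + v2 * (s2 - s1)
    d_v2 <- 2 * g * (s2 - s1)
    d_e2 <- g * v2 / s2
  } else if (law == "lichtenecker") {
    em <- exp((1 - v2) * log(eps1) + v2 * log(eps2))
    d_v2 <- em * (log(eps2) - log(eps1))
    d_e2 <- em * v2 / eps2
  } else if (law == "looyenga") {
    h <- (1 - v2) * eps1^(1 / 3) + v2 * eps2^(1 / 3)
    d_v2 <- 3 * h^2 * (eps2^(1 / 3) - eps1^(1 / 3))
    d_e2 <- h^2 * v2 * eps2^(-2 / 3)
  } else if (law == "bottcher") {
    em <- mix_permittivity(eps1, eps2, v2, law)
    # F = (em - e1)(e2 + 2 em) - 3 em v2 (e2 - e1) = 0
    dF_dem <- (eps2 + 2 * em) + 2 * (em - eps1) - 3 * v2 * (eps2 - eps1)
    dF_dv2 <- -3 * em * (eps2 - eps1)
    dF_de2 <- (em - eps1) - 3 * em * v2
    d_v2 <- -dF_dv2 / dF_dem
    d_e2 <- -dF_de2 / dF_dem
  } else { # bruggeman
    em <- mix_permittivity(eps1, eps2, v2, law)
    # F = 2 em^2 - c em - e1 e2,  c = (1-v2)(2 e1 - e2) + v2 (2 e2 - e1)
    cc <- (1 - v2) * (2 * eps1 - eps2) + v2 * (2 * eps2 - eps1)
    dF_dem <- 4 * em - cc
    dF_dv2 <- -em * 3 * (eps2 - eps1)
    dF_de2 <- -em * (3 * v2 - 1) - eps1
    d_v2 <- -dF_dv2 / dF_dem
    d_e2 <- -dF_de2 / dF_dem
  }

  tibble::tibble(
    frequency_hz = frequencies,
    d_eps_d_v2 = d_v2,
    d_eps_d_nacl = d_e2 * de2_dS
  )
}
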