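# 1D normal-incidence transfer-matrix explorer for layered head stacks.
# This is a desk-scale qualitative proxy for full-wave simulation: one
# polarization, plane waves, flat layers.

#' Resolve a material permittivity at a frequency
#'
#' Accepts a vendored tissue name (evaluated via its dispersion model), an
#' inline specification string `"eps=3,sigma=0.004"`, or a complex/numeric
#' permittivity which is passed through.
#'
#' @param material Tissue name, inline `"eps=..,sigma=.."` string, or a
#'   (complex) permittivity value.
#' @param f Frequency in Hz.
#' @return A single complex permittivity (`eps' - j eps''`).
#' @examples
#' material_permittivity("csf", 1e9)
#' material_permittivity("eps=3,sigma=0.004", 1e9)
#' @export
material_permittivity <- function(material, f) {
  if (is.numeric(material) || is.complex(material)) {
    return(as.complex(material))
  }
  if (!is.character(material) || length(material) != 1) {
    abort("`material` must be a tissue name, an 'eps=..,sigma=..' string, or a permittivity.")
  }
  num <- suppressWarnings(as.numeric(material))
  if (!is.na(num)) return(as.complex(num))
  if (grepl("=", material)) {
    parts <- strsplit(material, ",")[[1]]
    kv <- list(eps = NA_real_, sigma = 0)
    for (pt in parts) {
      bits <- strsplit(trimws(pt), "=")[[1]]
      if (length(bits) != 2) abort(sprintf("cannot parse material spec '%s'", material))
      kv[[trimws(bits[1])]] <- as.numeric(bits[2])
    }
    if (is.na(kv$eps)) abort(sprintf("material spec '%s' must set eps", material))
    return(complex(real = kv$eps, imaginary = -kv$sigma / (2 * pi * f * EPS0)))
  }
  tissue_permittivity(material, f)
}

#' Plane-wave transfer through a layered stack
#'
#' Standard 2x2 transfer-matrix solution for a normally incident plane wave
#' crossing a stack of finite layers between two semi-infinite media, with
#' complex wavenumbers `k = (2 pi f / c0) sqrt(eps)` (principal square
#' root, so passive layers attenuate). Amplitudes are normalized to a unit
#' incident field.
#'
#' @param layers A data frame with columns `name`, `thickness_mm` (all
#'   `> 0`) and `eps` (complex permittivity at `f`; alternatively a
#'   `material` column resolvable by [material_permittivity()]).
#' @param f Frequency in Hz.
#' @param incidence_eps Permittivity of the semi-infinite incidence
#'   (coupling) medium; default vacuum/air.
#' @param exit_eps Permittivity of the semi-infinite exit medium.
#' @return A list of class `"tmm_transfer"`: `reflection` and
#'   `transmission` complex coefficients, `reflectance`, `transmittance`
#'   (impedance-weighted power fractions), and an `interfaces` tibble of
#'   forward/backward field amplitudes at the entry of every region.
#' @examples
#' st <- data.frame(name = "slab", thickness_mm = 10, material = "eps=4")
#' transfer_1d(st, 1e9)
#' @export
transfer_1d <- function(layers, f, incidence_eps = 1 + 0i, exit_eps = NULL) {
  check_number(f, "f", lower = 0, strict = TRUE)
  layers <- as.data.frame(layers)
  if (nrow(layers) && is.null(layers$eps)) {
    layers$eps <- vapply(layers$material, material_permittivity,
                         complex(1), f = f)
  }
  if (nrow(layers) && any(layers$thickness_mm <= 0)) {
    abort("all layer thicknesses must be > 0 mm.")
  }
  inc <- as.complex(incidence_eps)
  ext <- as.complex(exit_eps %||% (if (nrow(layers)) layers$eps[nrow(layers)] else inc))

  eps_seq <- c(inc, if (nrow(layers)) layers$eps, ext)
  d_m <- c(NA_real_, if (nrow(layers)) layers$thickness_mm / 1000, NA_real_)
  eta <- 1 / sqrt(eps_seq)           # impedance relative to vacuum
  k <- 2 * pi * f / C0 * sqrt(eps_seq)

  interface_matrix <- function(i) {
    rho <- (eta[i + 1] - eta[i]) / (eta[i + 1] + eta[i])
    tau <- 1 + rho
    matrix(c(1, rho, rho, 1), 2, 2) / tau
  }
  prop_matrix <- function(i) {
    ph <- 1i * k[i] * d_m[i]
    matrix(c(exp(ph), 0, 0, exp(-ph)), 2, 2)
  }

  n_region <- length(eps_seq)
  # cumulative matrices from each region entry to the exit medium
  M <- interface_matrix(n_region - 1)
  partials <- vector("list", n_region - 1)
  partials[[n_region - 1]] <- M
  if (n_region > 2) {
    for (i in rev(seq_len(n_region - 2))) {
      M <- interface_matrix(i) %*% prop_matrix(i + 1) %*% M
      partials[[i]] <- M
    }
  }

  refl <- M[2, 1] / M[1, 1]
  trans <- 1 / M[1, 1]

  # amplitudes at the entry (left edge) of each region, unit incident field:
  # propagate the previous region's state across its thickness, then cross
  # the interface (I maps the right-side state to the left-side state).
  amp <- matrix(NA_complex_, n_region, 2)
  amp[1, ] <- c(1, refl)
  for (i in 2:n_region) {
    prev <- amp[i - 1, ]
    if (i - 1 >= 2) {
      ph <- 1i * k[i - 1] * d_m[i - 1]
      prev <- c(prev[1] * exp(-ph), prev[2] * exp(ph))
    }
    Ii <- interface_matrix(i - 1)
    amp[i, ] <- solve(Ii, prev)
  }

  pow_in <- Re(1 / eta[1])
  refl_pow <- Mod(refl)^2
  trans_pow <- Mod(trans)^2 * Re(1 / eta[n_region]) / pow_in

  interfaces <- tibble::tibble(
    region = c("incidence",
               if (nrow(layers)) as.character(layers$name), "exit"),
    eps_real = Re(eps_seq), eps_imag = -Im(eps_seq),
    forward = amp[, 1], backward = amp[, 2],
    forward_abs = Mod(amp[, 1])
  )

  structure(
    list(frequency_hz = f, reflection = refl, transmission = trans,
         reflectance = refl_pow, transmittance = trans_pow,
         interfaces = interfaces,
         det_M = M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1],
         eta_ratio = eta[1] / eta[n_region]),
    class = "tmm_transfer"
  )
}

#' @export
print.tmm_transfer <- function(x, ...) {
  cat(sprintf("<tmm_transfer> f = %.3g GHz\n", x$frequency_hz / 1e9))
  cat(sprintf("  |reflection| = %.4f   |transmission| = %.4f\n",
              Mod(x$reflection), Mod(x$transmission)))
  cat(sprintf("  reflectance = %.4f   transmittance = %.4f\n",
              x$reflectance, x$transmittance))
  print(x$interfaces)
  invisible(x)
}

#' Rank coupling media by field penetration
#'
#' Recomputes the layered transfer for each candidate coupling medium
#' (incidence permittivity) and ranks them by the transmitted field
#' amplitude into the exit medium (e.g. the brain). The report includes the
#' min-max normalized module `(x - min) / (max - min)`.
#'
#' @inheritParams transfer_1d
#' @param couplings Complex/numeric vector (length `>= 2`) of coupling
#'   permittivities, or a character vector resolvable by
#'   [material_permittivity()].
#' @return A tibble sorted by decreasing transmitted amplitude with columns
#'   `coupling`, `eps_real`, `eps_imag`, `transmitted_amplitude`,
#'   `transmittance` and `normalized_module`.
#' @export
compare_coupling <- function(layers, couplings, f, exit_eps = NULL) {
  if (length(couplings) < 2) abort("need at least 2 coupling media to compare.")
  eps_c <- vapply(couplings, material_permittivity, complex(1), f = f)
  res <- purrr::map(seq_along(eps_c), function(i) {
    tr <- transfer_1d(layers, f, incidence_eps = eps_c[i], exit_eps = exit_eps)
    tibble::tibble(
      coupling = as.character(couplings[i]),
      eps_real = Re(eps_c[i]), eps_imag = -Im(eps_c[i]),
      transmitted_amplitude = Mod(tr$transmission),
      transmittance = tr$transmittance
    )
  })
  out <- dplyr::bind_rows(res)
  rng <- range(out$transmitted_amplitude)
  out$normalized_module <- if (diff(rng) > 0) {
    (out$transmitted_amplitude - rng[1]) / diff(rng)
  } else {
    rep(1, nrow(out))
  }
  dplyr::arrange(out, dplyr::desc(.data$transmitted_amplitude))
}

#' Default skull/CSF layered head stack
#'
#' Convenience constructor for the canonical skull + CSF stack over a
#' semi-infinite brain, with layer permittivities pulled from the vendored
#' tissue fixtures at the evaluation frequency.
#'
#' @param f Frequency in Hz.
#' @param skull_mm,csf_mm Layer thicknesses in mm (skull thickness varies
#'   roughly between 2 and 8 mm in adults; 7 mm default).
#' @return A data frame of layers for [transfer_1d()] plus an
#'   `"exit_eps"` attribute holding the brain permittivity.
#' @export
head_stack <- function(f = 1e9, skull_mm = 7, csf_mm = 2) {
  layers <- data.frame(
    name = c("skull", "csf"),
    thickness_mm = c(skull_mm, csf_mm)
  )
  layers$eps <- c(tissue_permittivity("bone_cortical", f),
                  tissue_permittivity("csf", f))
  attr(layers, "exit_eps") <- tissue_permittivity("brain", f)
  layers
}
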