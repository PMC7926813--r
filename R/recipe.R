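#' Turn a fitted composition into a bench recipe
#'
#' Converts a composition (a [fit_recipe()] result or explicit
#' `v2_saline`/`nacl_g_l` values) into masses per batch volume. The batch
#' splits by volume into `1 - v2_saline` of Triton X-100 and `v2_saline` of
#' saline; TX-100 mass uses its density fixture (1.07 g/mL at 25 C), the
#' saline volume is approximated by its water volume (the NaCl volume
#' increment is neglected, consistent with the g/L concentration
#' definition), and the NaCl mass is concentration times saline volume.
#' A viscosity warning is attached when the TX-100 fraction falls in the
#' closed 40-60 vol % band (see [viscosity_warning()]).
#'
#' @param x A `"tmm_fit"` object, or a list/vector with elements
#'   `v2_saline` and `nacl_g_l`.
#' @param batch_volume_l Batch volume in litres, `> 0`.
#' @return An object of class `"tmm_recipe"`: batch and component volumes
#'   (L), masses (g), `warnings` (character vector) and the numbered
#'   preparation `protocol`. [tidy()] returns the component table.
#' @examples
#' r <- build_recipe(list(v2_saline = 0.95, nacl_g_l = 13.9), 1)
#' tidy(r)
#' @export
build_recipe <- function(x, batch_volume_l = 1) {
  check_number(batch_volume_l, "batch_volume_l", lower = 0, strict = TRUE)
  if (inherits(x, "tmm_fit")) {
    comp <- list(v2_saline = x$v2_saline, nacl_g_l = x$nacl_g_l,
                 label = x$problem$label)
  } else {
    comp <- as.list(x)
    comp$label <- comp$label %||% NULL
  }
  check_number(comp$v2_saline, "v2_saline", lower = 0)
  if (comp$v2_saline > 1) abort("`v2_saline` must be <= 1.")
  check_number(comp$nacl_g_l, "nacl_g_l", lower = 0)

  saline_volume_l <- comp$v2_saline * batch_volume_l
  tx100_volume_l <- (1 - comp$v2_saline) * batch_volume_l
  tx_pct <- 100 * (1 - comp$v2_saline)

  recipe <- structure(
    list(
      label = comp$label,
      v2_saline = comp$v2_saline,
      nacl_g_l = comp$nacl_g_l,
      tx100_vol_pct = tx_pct,
      batch_volume_l = batch_volume_l,
      tx100_volume_l = tx100_volume_l,
      saline_volume_l = saline_volume_l,
      tx100_mass_g = tx100_volume_l * 1000 * TX100_DENSITY,
      water_mass_g = saline_volume_l * 1000 * WATER_DENSITY,
      nacl_mass_g = comp$nacl_g_l * saline_volume_l,
      warnings = viscosity_warning(tx_pct),
      protocol = protocol_steps()
    ),
    class = "tmm_recipe"
  )
  recipe
}

#' Viscosity warning for mid-range TX-100 fractions
#'
#' TX-100/saline mixtures are hard to homogenize at room temperature when
#' the TX-100 volume fraction lies in the closed interval \[40, 60\] vol %
#' (the nerve-mimicking mixture at 44 % is the canonical case). Inside that
#' band a warning with the standard mitigation is returned; outside it, an
#' empty character vector.
#'
#' @param tx100_vol_pct TX-100 volume percentage in `[0, 100]`.
#' @return A character vector (length 1 inside the band, 0 outside).
#' @export
viscosity_warning <- function(tx100_vol_pct) {
  check_number(tx100_vol_pct, "tx100_vol_pct", lower = 0)
  if (tx100_vol_pct >= 40 && tx100_vol_pct <= 60) {
    sprintf(paste0(
      "TX-100 fraction %.1f vol%% lies in the viscous 40-60%% band at 25 C: ",
      "expect a hard-to-homogenize mixture. Mitigation: warm the components ",
      "separately, then mix, stir vigorously, and rest at 45 C until air ",
      "bubbles vanish; experimental fine-tuning of salt and TX-100 amounts ",
      "may be needed."), tx100_vol_pct)
  } else {
    character(0)
  }
}

protocol_steps <- function() {
  c(
    "Place the empty beaker on the balance and tare.",
    "Add the NaCl mass, then the deionized water mass, taring between additions.",
    "Stir with a magnetic bar until the saline is homogeneous, then tare again.",
    "Add the TX-100 mass; first warm the TX-100 in a 45 C water bath so the viscous liquid flows.",
    "Stir with the magnetic bar while the beaker sits in the hot water bath until the mixture is homogeneous.",
    "Store the mixture in a closed container at room temperature, away from light, for conservation."
  )
}

#' @export
print.tmm_recipe <- function(x, ...) {
  cat(recipe_sheet(x), sep = "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.tmm_recipe <- function(x, ...) {
  tibble::tibble(
    component = c("TX-100", "deionized water", "NaCl"),
    volume_l = c(x$tx100_volume_l, x$saline_volume_l, NA_real_),
    mass_g = c(x$tx100_mass_g, x$water_mass_g, x$nacl_mass_g)
  )
}

#' Render a recipe as a plain-text bench sheet or JSON
#'
#' @param recipe A `"tmm_recipe"` object.
#' @param path For `recipe_json()`, an optional output path; with `NULL`
#'   the JSON string is returned.
#' @return `recipe_sheet()`: a character vector of lines. `recipe_json()`:
#'   the JSON string (invisibly, when written to `path`).
#' @export
recipe_sheet <- function(recipe) {
  lines <- c(
    sprintf("TMM recipe%s", if (!is.null(recipe$label)) paste0(": ", recipe$label) else ""),
    sprintf("  batch volume:  %.3f L", recipe$batch_volume_l),
    sprintf("  composition:   %.1f vol%% TX-100, saline at %.2f g/L NaCl",
            recipe$tx100_vol_pct, recipe$nacl_g_l),
    "  masses:",
    sprintf("    TX-100:           %8.2f g  (%.3f L)", recipe$tx100_mass_g, recipe$tx100_volume_l),
    sprintf("    deionized water:  %8.2f g  (%.3f L)", recipe$water_mass_g, recipe$saline_volume_l),
    sprintf("    NaCl:             %8.2f g", recipe$nacl_mass_g)
  )
  if (length(recipe$warnings)) {
    lines <- c(lines, "  !! WARNING !!", paste0("    ", recipe$warnings))
  }
  lines <- c(lines, "  protocol:",
             sprintf("    %d. %s", seq_along(recipe$protocol), recipe$protocol))
  lines
}

#' @rdname recipe_sheet
#' @export
recipe_json <- function(recipe, path = NULL) {
  obj <- unclass(recipe)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = 12, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
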