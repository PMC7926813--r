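# Phantom manifest: binds STL cavity geometry to tissues and fitted recipes
# in a versioned JSON document that downstream EM tooling can consume.

#' Build a phantom cavity configuration
#'
#' @param phantom Phantom name.
#' @param cavities A data frame with columns `cavity` (unique names), `stl`
#'   (file paths) and `tissue` (names from [tissue_names()]).
#' @param law Mixing law for the recipe fits.
#' @param f_min,f_max,n_points Frequency band for the fits, in Hz.
#' @param temperature_c Mixture temperature.
#' @param batch_volume_l Batch volume used for the attached recipes.
#' @return A list of class `"phantom_config"`.
#' @export
phantom_config <- function(phantom, cavities, law = "kraszewski",
                           f_min = 0.5e9, f_max = 3e9, n_points = 26,
                           temperature_c = 25, batch_volume_l = 1) {
  cavities <- as.data.frame(cavities)
  need <- c("cavity", "stl", "tissue")
  if (!all(need %in% names(cavities))) {
    abort("`cavities` needs columns cavity, stl, tissue.")
  }
  if (anyDuplicated(cavities$cavity)) abort("duplicate cavity names in config.")
  structure(
    list(phantom = phantom, cavities = cavities,
         law = match.arg(law, mixing_laws()),
         f_min = f_min, f_max = f_max, n_points = n_points,
         temperature_c = temperature_c, batch_volume_l = batch_volume_l),
    class = "phantom_config"
  )
}

#' @rdname phantom_config
#' @param path JSON config file mirroring the `phantom_config()` fields.
#' @export
read_phantom_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  phantom_config(
    phantom = obj$phantom,
    cavities = as.data.frame(obj$cavities),
    law = obj$law %||% "kraszewski",
    f_min = obj$f_min %||% 0.5e9, f_max = obj$f_max %||% 3e9,
    n_points = obj$n_points %||% 26,
    temperature_c = obj$temperature_c %||% 25,
    batch_volume_l = obj$batch_volume_l %||% 1
  )
}

#' Build a phantom manifest
#'
#' Validates the configuration (tissue names against the fixture library,
#' STL files by parsing them), runs the recipe fit once per distinct
#' tissue, attaches bench recipes, and returns the manifest. When `out` is
#' given the manifest is written as deterministic JSON (atomically: nothing
#' is written if any validation fails).
#'
#' @param config A [phantom_config()] (or a path to a JSON config).
#' @param out Optional output path for the manifest JSON.
#' @return The manifest list (invisibly when written to `out`).
#' @export
build_manifest <- function(config, out = NULL) {
  if (is.character(config)) config <- read_phantom_config(config)
  if (!inherits(config, "phantom_config")) {
    abort("`config` must be a phantom_config or a path to one.")
  }
  cav <- config$cavities

  unknown <- setdiff(unique(cav$tissue), tissue_names())
  if (length(unknown)) {
    abort(sprintf("unknown tissue(s) %s; the fixture library provides: %s",
                  paste(unknown, collapse = ", "),
                  paste(tissue_names(), collapse = ", ")))
  }
  missing_stl <- cav$stl[!file.exists(cav$stl)]
  if (length(missing_stl)) {
    abort(sprintf("missing STL file(s): %s (no manifest written)",
                  paste(missing_stl, collapse = ", ")))
  }
  stl_summaries <- lapply(cav$stl, read_stl)

  frequencies <- freq_band(config$f_min, config$f_max, config$n_points)
  fits <- lapply(unique(cav$tissue), function(tn) {
    fit_recipe(tn, law = config$law, frequencies = frequencies,
               temperature_c = config$temperature_c)
  })
  names(fits) <- unique(cav$tissue)

  entries <- lapply(seq_len(nrow(cav)), function(i) {
    fit <- fits[[cav$tissue[i]]]
    rec <- build_recipe(fit, config$batch_volume_l)
    ss <- stl_summaries[[i]]
    list(
      cavity = cav$cavity[i],
      stl = cav$stl[i],
      stl_summary = list(
        n_triangles = ss$n_triangles, format = ss$format,
        watertight = ss$watertight,
        bbox_mm = list(min = unname(ss$bbox[, 1]), max = unname(ss$bbox[, 2]))
      ),
      tissue = cav$tissue[i],
      composition = list(
        v2_saline = fit$v2_saline, nacl_g_l = fit$nacl_g_l,
        tx100_vol_pct = fit$tx100_vol_pct,
        converged = fit$converged, cost = fit$cost
      ),
      recipe = list(
        batch_volume_l = rec$batch_volume_l,
        tx100_mass_g = rec$tx100_mass_g,
        water_mass_g = rec$water_mass_g,
        nacl_mass_g = rec$nacl_mass_g,
        warnings = rec$warnings
      )
    )
  })

  manifest <- list(
    schema_version = "1.0",
    phantom = config$phantom,
    law = config$law,
    band_hz = list(f_min = config$f_min, f_max = config$f_max,
                   n_points = config$n_points),
    temperature_c = config$temperature_c,
    entries = entries
  )
  if (!is.null(out)) {
    tmp <- tempfile(tmpdir = dirname(out), fileext = ".json")
    jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = 12,
                         pretty = TRUE)
    file.rename(tmp, out)
    return(invisible(manifest))
  }
  manifest
}
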