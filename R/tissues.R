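# Vendored tissue fixture library.  One JSON file per tissue under
# inst/extdata/tissues; each file records its literature provenance.

the <- new.env(parent = emptyenv())

fixture_dir <- function() {
  system.file("extdata", package = "phantomix", mustWork = TRUE)
}

load_tissue_file <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (identical(obj$model, "cole_cole")) {
    cole_cole(
      eps_inf = obj$eps_inf,
      delta_eps = vapply(obj$poles, function(p) p$delta_eps, numeric(1)),
      tau = vapply(obj$poles, function(p) p$tau_s, numeric(1)),
      alpha = vapply(obj$poles, function(p) p$alpha, numeric(1)),
      sigma_static = obj$sigma_static_s_m,
      label = obj$label
    )
  } else if (identical(obj$model, "blend")) {
    tissue_blend(
      models = lapply(obj$components, function(cm) tissue_model(cm$tissue)),
      weights = vapply(obj$components, function(cm) cm$weight, numeric(1)),
      label = obj$label
    )
  } else {
    abort(sprintf("unknown fixture model type '%s' in %s", obj$model, path))
  }
}

tissue_files <- function() {
  dir <- file.path(fixture_dir(), "tissues")
  files <- list.files(dir, pattern = "\\.json$", full.names = TRUE)
  setNames(files, sub("\\.json$", "", basename(files)))
}

#' The vendored tissue library
#'
#' `tissue_names()` lists the tissues shipped with the package (nine
#' Cole-Cole parameter sets from the standard literature compilation plus a
#' white/grey-matter brain blend). `tissue_model()` returns the dielectric
#' model for one tissue; `tissue_permittivity()` is a shortcut that
#' evaluates it on a grid.
#'
#' @param name Tissue name, one of `tissue_names()`.
#' @return `tissue_model()` returns a [cole_cole()] or [tissue_blend()]
#'   object; `tissue_names()` a character vector;
#'   `tissue_permittivity()` a complex vector.
#' @examples
#' tissue_names()
#' tissue_model("csf")
#' @export
tissue_names <- function() {
  sort(names(tissue_files()))
}

#' @rdname tissue_names
#' @export
tissue_model <- function(name) {
  if (!is.character(name) || length(name) != 1) {
    abort("`name` must be a single tissue name string.")
  }
  key <- paste0("tissue_", name)
  if (!is.null(the[[key]])) return(the[[key]])
  files <- tissue_files()
  if (!name %in% names(files)) {
    abort(sprintf("unknown tissue '%s'; available tissues: %s",
                  name, paste(sort(names(files)), collapse = ", ")))
  }
  the[[key]] <- load_tissue_file(files[[name]])
  the[[key]]
}

#' @rdname tissue_names
#' @inheritParams permittivity
#' @export
tissue_permittivity <- function(name, frequencies = freq_band()) {
  permittivity(tissue_model(name), frequencies)
}

#' The Triton X-100 Debye model fixture
#'
#' Loads the vendored Debye parameters for pure Triton X-100 at 25 C. The
#' parameter file (`tx100_debye_synthetic.json`) is an editable synthetic
#' stand-in documented in its provenance field: the values lie in the
#' published range for polyethoxylated surfactants and were validated
#' against published 1 GHz mixture properties.
#'
#' @return A [debye()] model.
#' @export
tx100_model <- function() {
  if (!is.null(the$tx100)) return(the$tx100)
  obj <- jsonlite::read_json(file.path(fixture_dir(), "tx100_debye_synthetic.json"))
  the$tx100 <- debye(obj$eps_static, obj$eps_inf, obj$tau_s,
                     obj$sigma_static_s_m, label = obj$label)
  the$tx100
}

phantomix_constants <- function() {
  if (!is.null(the$constants)) return(the$constants)
  the$constants <- jsonlite::read_json(file.path(fixture_dir(), "constants.json"))
  the$constants
}
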