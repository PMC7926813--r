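#' Define a recipe-fitting problem
#'
#' Packages a target tissue spectrum, a mixing law, a frequency grid and
#' per-frequency weights into a fit problem for [fit_recipe()]. The cost is
#' the weighted complex misfit
#' `J = sum_f w_f |eps_m(x) - eps_t|_f^2`, with the default relative weights
#' `w_f = 1 / |eps_t|_f^2`.
#'
#' @param target A tissue name (see [tissue_names()]), a dielectric model
#'   object, or a [dielectric_spectrum()] tibble (in which case its own
#'   frequency grid is used).
#' @param law One of [mixing_laws()].
#' @param frequencies Frequency grid in Hz (ignored when `target` is a
#'   spectrum tibble).
#' @param temperature_c Mixture temperature in Celsius.
#' @param weights Optional positive per-frequency weights overriding the
#'   default `1/|eps_t|^2`.
#' @param tx100 TX-100 model; defaults to the vendored fixture.
#' @return A list of class `"fit_problem"`.
#' @export
fit_problem <- function(target, law = "kraszewski", frequencies = freq_band(),
                        temperature_c = 25, weights = NULL,
                        tx100 = tx100_model()) {
  law <- match.arg(law, mixing_laws())
  label <- NULL
  if (is.character(target)) {
    label <- target
    target <- tissue_model(target)
  }
  if (inherits(target, "diel_spectrum")) {
    frequencies <- target$frequency_hz
    eps_t <- spectrum_eps(target)
    label <- label %||% attr(target, "label")
  } else if (inherits(target, "diel_model")) {
    eps_t <- permittivity(target, frequencies)
    label <- label %||% target$label
  } else {
    abort("`target` must be a tissue name, a dielectric model, or a spectrum tibble.")
  }
  w <- weights %||% (1 / Mod(eps_t)^2)
  check_numeric(w, "weights", lower = 0, strict = TRUE)
  if (length(w) != length(frequencies)) {
    abort("`weights` must have one entry per frequency.")
  }
  structure(
    list(frequencies = frequencies, eps_t = eps_t, weights = w, law = law,
         temperature_c = temperature_c, tx100 = tx100, label = label),
    class = "fit_problem"
  )
}

as_fit_problem <- function(target, ...) {
  if (inherits(target, "fit_problem")) target else fit_problem(target, ...)
}

#' Cost, gradient and Gauss-Newton Hessian of a fit problem
#'
#' `recipe_cost()` evaluates the weighted complex misfit `J` at a
#' composition `x = (v2_saline, nacl_g_l)`. `recipe_grad_hessian()` returns
#' the analytic gradient `g = 2 sum_f w_f Re[(eps_m - eps_t)* deps_m]` and
#' the Gauss-Newton approximate Hessian
#' `H = 2 sum_f w_f Re(deps_m* deps_m^T)`, a symmetric positive
#' semidefinite 2x2 matrix.
#'
#' @param problem A [fit_problem()] (or anything accepted as its `target`).
#' @param v2_saline,nacl_g_l The composition at which to evaluate.
#' @return `recipe_cost()`: a single non-negative number.
#'   `recipe_grad_hessian()`: a list with `gradient` (length-2 vector,
#'   components d/d v2 and d/d nacl) and `hessian` (2x2 matrix).
#' @export
recipe_cost <- function(problem, v2_saline, nacl_g_l) {
  p <- as_fit_problem(problem)
  em <- mixture_permittivity(p$frequencies, v2_saline, nacl_g_l,
                             p$temperature_c, p$law, p$tx100)
  sum(p$weights * Mod(em - p$eps_t)^2)
}

#' @rdname recipe_cost
#' @export
recipe_grad_hessian <- function(problem, v2_saline, nacl_g_l) {
  p <- as_fit_problem(problem)
  em <- mixture_permittivity(p$frequencies, v2_saline, nacl_g_l,
                             p$temperature_c, p$law, p$tx100)
  d <- mixture_derivatives(p$frequencies, v2_saline, nacl_g_l,
                           p$temperature_c, p$law, p$tx100)
  r <- em - p$eps_t
  J1 <- d$d_eps_d_v2
  J2 <- d$d_eps_d_nacl
  g <- 2 * c(sum(p$weights * Re(Conj(r) * J1)),
             sum(p$weights * Re(Conj(r) * J2)))
  h11 <- 2 * sum(p$weights * Re(Conj(J1) * J1))
  h12 <- 2 * sum(p$weights * Re(Conj(J1) * J2))
  h22 <- 2 * sum(p$weights * Re(Conj(J2) * J2))
  list(gradient = g, hessian = matrix(c(h11, h12, h12, h22), 2, 2))
}

# feasible box for the iterates
FIT_BOX <- list(v2 = c(0, 1), nacl = c(0, 100))

project_box <- function(x) {
  c(min(max(x[1], FIT_BOX$v2[1]), FIT_BOX$v2[2]),
    min(max(x[2], FIT_BOX$nacl[1]), FIT_BOX$nacl[2]))
}

projected_gnorm <- function(p, x, lo, hi) {
  g <- recipe_grad_hessian(p, x[1], x[2])$gradient
  g[(x <= lo + 1e-12 & g > 0) | (x >= hi - 1e-12 & g < 0)] <- 0
  sqrt(sum(g^2))
}

#' Fit a mimicking mixture composition by damped Gauss-Newton
#'
#' Finds the saline volume fraction and NaCl concentration whose binary
#' mixture best matches a target tissue spectrum over the frequency band, by
#' iterating `x_{k+1} = x_k - H^{-1} g` with analytic gradient and
#' Gauss-Newton Hessian. Plain steps are safeguarded: the step is halved
#' whenever the cost would increase, and iterates are projected onto the box
#' `v2 in [0, 1]`, `nacl in [0, 100]` g/L. Iteration stops when the scaled
#' gradient norm falls below `gtol * (1 + J)`, the step falls below
#' `steptol`, or `max_iter` is reached; non-convergence is reported in the
#' result, never as an error.
#'
#' @inheritParams recipe_cost
#' @param ... Passed to [fit_problem()] when `problem` is a target rather
#'   than a prepared problem (`law`, `frequencies`, `temperature_c`, ...).
#' @param init Length-2 numeric start `(v2_saline, nacl_g_l)`; the default
#'   `(0.5, 5)` is a mid-box start.
#' @param max_iter Iteration cap.
#' @param gtol,steptol Convergence tolerances on the scaled gradient norm
#'   and on the step size.
#' @return An object of class `"tmm_fit"` with elements `v2_saline`,
#'   `nacl_g_l`, `tx100_vol_pct`, `iterations`, `cost_trace`, `cost`,
#'   `converged`, `final_gradient_norm`, `singular_hessian` and the
#'   underlying `problem`. [tidy()] and [glance()] methods are provided.
#' @examples
#' \donttest{
#' fit <- fit_recipe("csf")
#' tidy(fit)
#' glance(fit)
#' }
#' @export
fit_recipe <- function(problem, ..., init = c(0.5, 5), max_iter = 100,
                       gtol = 1e-10, steptol = 1e-12) {
  p <- as_fit_problem(problem, ...)
  x <- project_box(as.numeric(init))
  J <- recipe_cost(p, x[1], x[2])
  trace <- J
  converged <- FALSE
  singular <- FALSE
  gnorm <- NA_real_
  iter <- 0

  lo <- c(FIT_BOX$v2[1], FIT_BOX$nacl[1])
  hi <- c(FIT_BOX$v2[2], FIT_BOX$nacl[2])

  while (iter < max_iter) {
    gh <- recipe_grad_hessian(p, x[1], x[2])
    g <- gh$gradient
    H <- gh$hessian
    # active-set handling at the box: freeze coordinates pinned at a bound
    # whose gradient pushes outward, and test stationarity on the
    # projected gradient
    active <- (x <= lo + 1e-12 & g > 0) | (x >= hi - 1e-12 & g < 0)
    g_proj <- g
    g_proj[active] <- 0
    gnorm <- sqrt(sum(g_proj^2))
    if (gnorm < gtol * (1 + J)) {
      converged <- TRUE
      break
    }
    free <- which(!active)
    Hf <- H[free, free, drop = FALSE]
    step_f <- tryCatch(solve(Hf, g[free]), error = function(e) NULL)
    if (is.null(step_f) || !all(is.finite(step_f))) {
      # rank-deficient Gauss-Newton Hessian: fall back to a pseudo-inverse
      singular <- TRUE
      sv <- svd(Hf)
      keep <- sv$d > max(sv$d) * 1e-12
      step_f <- sv$v[, keep, drop = FALSE] %*%
        ((t(sv$u[, keep, drop = FALSE]) %*% g[free]) / sv$d[keep])
      step_f <- as.numeric(step_f)
    }
    step <- c(0, 0)
    step[free] <- step_f
    # damped update: halve until the cost does not increase
    t_damp <- 1
    repeat {
      x_try <- project_box(x - t_damp * step)
      J_try <- recipe_cost(p, x_try[1], x_try[2])
      if (J_try <= J + 1e-15 || t_damp < 1e-8) break
      t_damp <- t_damp / 2
    }
    step_size <- sqrt(sum((x_try - x)^2))
    x <- x_try
    J <- J_try
    iter <- iter + 1
    trace <- c(trace, J)
    if (step_size < steptol) {
      converged <- TRUE
      gnorm <- projected_gnorm(p, x, lo, hi)
      break
    }
  }
  if (!converged && iter >= max_iter) {
    gnorm <- projected_gnorm(p, x, lo, hi)
  }

  structure(
    list(
      v2_saline = x[1], nacl_g_l = x[2],
      tx100_vol_pct = 100 * (1 - x[1]),
      iterations = iter, cost_trace = trace, cost = J,
      converged = converged, final_gradient_norm = gnorm,
      singular_hessian = singular, problem = p
    ),
    class = "tmm_fit"
  )
}

#' @export
print.tmm_fit <- function(x, ...) {
  cat("<tmm_fit>", x$problem$label %||% "custom target", "\n")
  cat(sprintf("  law: %s over %g-%g GHz (%d points)\n", x$problem$law,
              min(x$problem$frequencies) / 1e9, max(x$problem$frequencies) / 1e9,
              length(x$problem$frequencies)))
  cat(sprintf("  TX-100: %.1f vol%%   NaCl: %.2f g/L\n",
              x$tx100_vol_pct, x$nacl_g_l))
  cat(sprintf("  J = %.3e after %d iteration(s), converged: %s\n",
              x$cost, x$iterations, x$converged))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.tmm_fit <- function(x, ...) {
  tibble::tibble(
    term = c("v2_saline", "nacl_g_l", "tx100_vol_pct"),
    estimate = c(x$v2_saline, x$nacl_g_l, x$tx100_vol_pct),
    unit = c("volume fraction", "g/L", "vol %")
  )
}

#' @exportS3Method generics::glance
glance.tmm_fit <- function(x, ...) {
  tibble::tibble(
    cost = x$cost, iterations = x$iterations, converged = x$converged,
    final_gradient_norm = x$final_gradient_norm, law = x$problem$law,
    n_freq = length(x$problem$frequencies)
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.tmm_fit <- function(object, ...) {
  p <- object$problem
  fit_sp <- mixture_spectrum(p$frequencies, object$v2_saline, object$nacl_g_l,
                             p$temperature_c, p$law, p$tx100)
  tgt_sp <- spectrum_tbl(p$frequencies, p$eps_t)
  df <- rbind(
    data.frame(frequency_ghz = p$frequencies / 1e9, value = tgt_sp$eps_real,
               quantity = "dielectric constant", which = "target"),
    data.frame(frequency_ghz = p$frequencies / 1e9, value = fit_sp$eps_real,
               quantity = "dielectric constant", which = "fitted mixture"),
    data.frame(frequency_ghz = p$frequencies / 1e9, value = tgt_sp$sigma_s_m,
               quantity = "conductivity (S/m)", which = "target"),
    data.frame(frequency_ghz = p$frequencies / 1e9, value = fit_sp$sigma_s_m,
               quantity = "conductivity (S/m)", which = "fitted mixture")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frequency_ghz, y = .data$value,
                                   colour = .data$which)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "frequency (GHz)", y = NULL, colour = NULL,
                  title = p$label)
}

#' Brute-force grid search over compositions
#'
#' Exhaustively evaluates the fit cost on a rectangular composition grid.
#' Used as an independent optimality check of [fit_recipe()] (the fitted
#' minimizer should land within one grid cell of the grid minimum).
#'
#' @inheritParams recipe_cost
#' @param v2_grid,nacl_grid Numeric grids of saline volume fractions and
#'   NaCl concentrations (both non-empty).
#' @return A list with the best `v2_saline`, `nacl_g_l`, `cost`, and the
#'   full `grid` tibble of costs.
#' @export
grid_search_recipe <- function(problem, v2_grid, nacl_grid) {
  p <- as_fit_problem(problem)
  if (length(v2_grid) < 1 || length(nacl_grid) < 1) {
    abort("`v2_grid` and `nacl_grid` must be non-empty.")
  }
  check_numeric(v2_grid, "v2_grid", lower = 0, upper = 1)
  check_numeric(nacl_grid, "nacl_grid", lower = 0)
  eps1 <- permittivity(p$tx100, p$frequencies)
  n_v <- length(v2_grid)
  n_f <- length(p$frequencies)
  # expand v2 x frequency once; loop over the salinity axis
  v2_rep <- rep(v2_grid, each = n_f)
  eps1_rep <- rep(eps1, times = n_v)
  eps_t_rep <- rep(p$eps_t, times = n_v)
  w_rep <- rep(p$weights, times = n_v)
  cost <- matrix(NA_real_, n_v, length(nacl_grid))
  for (j in seq_along(nacl_grid)) {
    eps2 <- permittivity(saline(nacl_grid[j], p$temperature_c), p$frequencies)
    em <- mix_permittivity(eps1_rep, rep(eps2, times = n_v), v2_rep, p$law)
    r2 <- w_rep * Mod(em - eps_t_rep)^2
    cost[, j] <- colSums(matrix(r2, n_f, n_v))
  }
  best <- arrayInd(which.min(cost), dim(cost))
  grid <- tibble::tibble(
    v2_saline = rep(v2_grid, times = length(nacl_grid)),
    nacl_g_l = rep(nacl_grid, each = n_v),
    cost = as.numeric(cost)
  )
  list(v2_saline = v2_grid[best[1]], nacl_g_l = nacl_grid[best[2]],
       cost = cost[best[1], best[2]], grid = grid)
}

#' Fit all head tissues and tabulate the results
#'
#' Runs [fit_recipe()] for a set of tissues and reports, per tissue, the
#' fitted concentrations (TX-100 vol % rounded to the nearest integer, NaCl
#' to 0.1 g/L) alongside the mixture and target dielectric properties at a
#' reporting frequency.
#'
#' @param tissues Character vector of tissue names.
#' @inheritParams fit_problem
#' @param report_f Reporting frequency in Hz (default 1 GHz).
#' @return A tibble with one row per tissue.
#' @export
design_table <- function(tissues = c("brain", "csf", "muscle",
                                     "bone_cortical", "blood"),
                         law = "kraszewski", frequencies = freq_band(),
                         temperature_c = 25, report_f = 1e9) {
  rows <- purrr::map(tissues, function(tn) {
    fit <- fit_recipe(tn, law = law, frequencies = frequencies,
                      temperature_c = temperature_c)
    em <- mixture_permittivity(report_f, fit$v2_saline, fit$nacl_g_l,
                               temperature_c, law)
    et <- tissue_permittivity(tn, report_f)
    tibble::tibble(
      tissue = tn,
      tx100_vol_pct = round(fit$tx100_vol_pct),
      nacl_g_l = round(fit$nacl_g_l, 1),
      eps_r_mixture = Re(em),
      sigma_mixture = 2 * pi * report_f * EPS0 * -Im(em),
      eps_r_target = Re(et),
      sigma_target = 2 * pi * report_f * EPS0 * -Im(et),
      cost = fit$cost,
      iterations = fit$iterations,
      converged = fit$converged
    )
  })
  dplyr::bind_rows(rows)
}

#' Write a JSON fit report
#'
#' Serializes a fitted recipe (composition, convergence diagnostics,
#' per-frequency residuals and fitted-vs-target spectra) to JSON.
#'
#' @param fit A `"tmm_fit"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  p <- fit$problem
  em <- mixture_permittivity(p$frequencies, fit$v2_saline, fit$nacl_g_l,
                             p$temperature_c, p$law, p$tx100)
  report <- list(
    target = p$label %||% "custom target",
    law = p$law,
    temperature_c = p$temperature_c,
    composition = list(v2_saline = fit$v2_saline, nacl_g_l = fit$nacl_g_l,
                       tx100_vol_pct = fit$tx100_vol_pct),
    convergence = list(iterations = fit$iterations, converged = fit$converged,
                       final_gradient_norm = fit$final_gradient_norm,
                       cost_trace = fit$cost_trace),
    spectra = list(
      frequency_hz = p$frequencies,
      mixture_eps_real = Re(em), mixture_eps_imag = -Im(em),
      target_eps_real = Re(p$eps_t), target_eps_imag = -Im(p$eps_t),
      residual_abs = Mod(em - p$eps_t)
    )
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = 12)
  invisible(path)
}
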