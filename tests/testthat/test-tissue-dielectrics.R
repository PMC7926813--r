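test_that("Debye evaluation has the textbook limits", {
  m <- debye(eps_static = 78, eps_inf = 5, tau = 8e-12)
  # static limit
  expect_equal(Re(permittivity(m, 1)), 78, tolerance = 1e-9)
  expect_equal(-Im(permittivity(m, 1)), 0, tolerance = 1e-6)
  # loss peak at f = 1/(2 pi tau): eps'' = (eps_s - eps_inf)/2
  f_peak <- 1 / (2 * pi * m$tau)
  expect_equal(-Im(permittivity(m, f_peak)), (78 - 5) / 2, tolerance = 1e-12)
  # degenerate pole: eps_static == eps_inf leaves only the sigma term
  m0 <- debye(10, 10, 1e-10, sigma_static = 0.5)
  f <- freq_band()
  eps <- permittivity(m0, f)
  expect_equal(Re(eps), rep(10, length(f)))
  expect_equal(sigma_at(eps, f), rep(0.5, length(f)), tolerance = 1e-12)
})

test_that("Cole-Cole evaluation: static limit, conductivity pass-through, Debye equivalence", {
  m <- cole_cole(5, delta_eps = 40, tau = 1e-11, alpha = 0)
  expect_equal(Re(permittivity(m, 1)), 45, tolerance = 1e-9)

  # sigma_static appears exactly as effective conductivity when dispersion is off
  m2 <- cole_cole(12, delta_eps = 0, tau = 1e-11, alpha = 0, sigma_static = 0.2)
  expect_equal(sigma_at(permittivity(m2, 1e9), 1e9), 0.2, tolerance = 1e-14)

  # alpha = 0 Cole-Cole is a sum of Debye relaxations (random models)
  set.seed(11)
  f <- freq_band(0.1e9, 10e9, 15)
  for (k in 1:5) {
    de <- runif(3, 1, 60)
    ta <- 10^runif(3, -12, -9)
    sg <- runif(1, 0, 2)
    cc <- cole_cole(4, de, ta, alpha = 0, sigma_static = sg)
    eps_cc <- permittivity(cc, f)
    eps_db <- permittivity(debye(4 + de[1], 4, ta[1], sigma_static = sg), f)
    for (i in 2:3) {
      eps_db <- eps_db + permittivity(debye(1 + de[i], 1, ta[i]), f) - 1
    }
    expect_equal(eps_cc, eps_db, tolerance = 1e-12)
  }
})

test_that("model constructors reject non-physical parameters by name", {
  expect_error(cole_cole(0.5, 10, 1e-11), "eps_inf")
  expect_error(cole_cole(4, -1, 1e-11), "delta_eps")
  expect_error(cole_cole(4, 10, 0), "tau")
  expect_error(cole_cole(4, 10, 1e-11, alpha = 1), "alpha")
  expect_error(cole_cole(4, 10, 1e-11, sigma_static = -1), "sigma_static")
  expect_error(debye(3, 5, 1e-11), "eps_static")
  expect_error(saline(200), "validity window")
  expect_error(saline(10, temperature_c = 80), "validity window")
})

test_that("saline model: pure-water anchor, conductivity monotone in salinity", {
  # frozen regression anchor: implemented parametric model at S = 0, 25 C, 1 GHz
  eps <- permittivity(saline(0, 25), 1e9)
  expect_equal(Re(eps), 78.1576840785, tolerance = 1e-9)
  expect_equal(Im(eps), -3.7280835428, tolerance = 1e-8)
  expect_gt(Re(eps), 77)  # pure-water range at 25 C
  expect_lt(Re(eps), 80)

  s_grid <- seq(0, 20, by = 1)
  sig <- vapply(s_grid, function(s) sigma_at(permittivity(saline(s, 25), 1e9), 1e9),
                numeric(1))
  expect_true(all(diff(sig) > 0))
})

test_that("salinity derivative matches the finite-difference oracle and is smooth", {
  f <- freq_band()
  for (s in c(1, 5, 13.9, 30)) {
    d <- saline_salinity_derivative(saline(s, 25), f)
    h <- s * 1e-4
    fd <- (permittivity(saline(s + h, 25), f) -
             permittivity(saline(s - h, 25), f)) / (2 * h)
    expect_lt(max(Mod(d - fd) / Mod(fd)), 1e-6)
    # conductivity depends on salinity: imaginary part must be non-zero
    expect_true(all(Mod(Im(d)) > 0))
  }
  # continuity: derivative at two nearby salinities stays within oracle tolerance
  d1 <- saline_salinity_derivative(saline(10, 25), f)
  d2 <- saline_salinity_derivative(saline(10 + 1e-6, 25), f)
  expect_lt(max(Mod(d1 - d2) / Mod(d1)), 1e-6)
})

test_that("tissue blends behave as volume-weighted averages", {
  wm <- tissue_model("brain_white_matter")
  gm <- tissue_model("brain_grey_matter")
  f <- freq_band()
  # degenerate blend
  b1 <- tissue_blend(list(wm, gm), c(1, 0))
  expect_equal(permittivity(b1, f), permittivity(wm, f))
  # blend of two copies of the same model is that model
  b2 <- tissue_blend(list(wm, wm), c(0.5, 0.5))
  expect_equal(permittivity(b2, f), permittivity(wm, f))
  expect_error(tissue_blend(list(wm, gm), c(0.7, 0.2)), "sum to 1")

  # 75/25 white/grey brain blend at 1 GHz reproduces the published value
  eps <- tissue_permittivity("brain", 1e9)
  expect_equal(Re(eps), 42, tolerance = 2 / 42)
})

test_that("all vendored tissue fixtures are passive and have dispersive conductivity", {
  f_wide <- freq_band(0.1e9, 10e9, 40)
  f_band <- freq_band()
  for (tn in tissue_names()) {
    eps <- tissue_permittivity(tn, f_wide)
    expect_true(all(-Im(eps) >= 0), label = paste(tn, "passivity"))
    expect_true(all(Re(eps) >= 1), label = paste(tn, "eps' >= 1"))
    sig <- sigma_at(tissue_permittivity(tn, f_band), f_band)
    expect_true(all(diff(sig) >= 0),
                label = paste(tn, "sigma_eff non-decreasing over the band"))
  }
})

test_that("spectrum tibbles are internally consistent and write CSV", {
  sp <- dielectric_spectrum(saline(9, 25), freq_band())
  expect_s3_class(sp, "diel_spectrum")
  expect_equal(sp$sigma_s_m,
               2 * pi * sp$frequency_hz * EPS0_T * sp$eps_imag,
               tolerance = 1e-14)
  expect_true(all(sp$eps_imag >= 0))
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum_csv(sp, path)
  back <- utils::read.csv(path)
  expect_named(back, c("frequency_Hz", "eps_real", "eps_imag", "sigma_S_per_m"))
  expect_equal(back$eps_real, sp$eps_real, tolerance = 1e-10)
})
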