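test_that("template curve is peak-normalized with the maximum at lambda_max", {
  crv <- pigment_template(500)
  expect_equal(max(crv$value), 1)
  expect_true(all(crv$value >= 0 & crv$value <= 1))
  # raw template peaks a few hundredths of a nm below lambda_max, so at 0.1 nm
  # resolution the argmax sits within one grid step of lambda_max
  peak_wl <- crv$wavelength[which.max(crv$value)]
  expect_lte(abs(peak_wl - 500), 0.1)
  expect_equal(crv$value[abs(crv$wavelength - 500) < 1e-9], 1, tolerance = 1e-6)
  # far-red tail of the template is negligible
  expect_lt(crv$value[length(crv$value)], 0.01)
})

test_that("template matches an independent transcription pointwise", {
  spots <- c(300, 350, 400, 450, 500, 560, 600, 650, 700, 750)
  crv <- pigment_template(560, normalize = FALSE)
  got <- crv$value[match(spots, crv$wavelength)]
  expect_true(all(is.finite(got)))
  expect_equal(got, oracle_pigment_absorbance(spots, 560), tolerance = 1e-9)
})

test_that("lambda_max and grid preconditions are enforced", {
  expect_error(pigment_template(250), "300 and 700")
  expect_error(pigment_template(720), "300 and 700")
  expect_error(pigment_template(500, grid = wavelength_grid(400, 600)),
               "modelling window")
})

test_that("half-max crossings recover the closed-form Gaussian half width", {
  g <- wavelength_grid()
  crv <- spectral_curve(g, exp(-((g - 500) / 30)^2 / 2))
  vr <- half_max_crossings(crv)
  half_width <- 30 * sqrt(2 * log(2))
  expect_equal(vr$min, 500 - half_width, tolerance = 0.05)
  expect_equal(vr$max, 500 + half_width, tolerance = 0.05)
  expect_false(vr$gap)
})

test_that("crossings are interpolated and window edges warn", {
  g <- wavelength_grid(400, 600)
  ramp <- spectral_curve(g, (g - 400) / 200)
  expect_warning(vr <- half_max_crossings(ramp), "window edge")
  expect_equal(vr$min, 500, tolerance = 1e-9)
  expect_equal(vr$max, 600)
})

test_that("degenerate curves are rejected", {
  g <- wavelength_grid(400, 600)
  expect_error(half_max_crossings(spectral_curve(g, rep(0.2, length(g)))),
               "never reaches")
  # exactly one grid point at the level -> zero-width interval
  v <- rep(0, length(g))
  v[1000] <- 0.5
  expect_error(half_max_crossings(spectral_curve(g, v), level = 0.5),
               "zero width")
  expect_error(half_max_crossings(pigment_template(500), level = 1.5),
               "between 0 and 1")
})

test_that("increasing lambda_max shifts both half-max limits redward", {
  vrs <- lapply(seq(400, 600, by = 50), pigment_visual_range)
  mins <- vapply(vrs, `[[`, numeric(1), "min")
  maxs <- vapply(vrs, `[[`, numeric(1), "max")
  expect_true(all(diff(mins) > 0))
  expect_true(all(diff(maxs) > 0))
})

test_that("pipeline crossings agree with the dense-grid brute-force oracle", {
  set.seed(11)
  for (lmax in round(runif(10, 330, 620), 1)) {
    vr <- pigment_visual_range(lmax)
    expected <- oracle_dense_crossings(lmax)
    expect_equal(vr$min, expected[["min"]], tolerance = 0.05)
    expect_equal(vr$max, expected[["max"]], tolerance = 0.05)
  }
})

test_that("frozen dense-grid crossings for a 500 nm pigment are reproduced", {
  # values frozen from oracle_dense_crossings(500) at 0.01 nm resolution
  vr <- pigment_visual_range(500)
  expect_equal(vr$min, 444.26, tolerance = 0.05)
  expect_equal(vr$max, 545.73, tolerance = 0.05)
})

test_that("species range is the envelope of per-pigment ranges", {
  r1 <- visual_range(350, 450)
  r2 <- visual_range(440, 560)
  expect_identical(species_visual_range(list(r1)), r1)
  env <- species_visual_range(list(r1, r2))
  expect_equal(c(env$min, env$max), c(350, 560))
  expect_error(species_visual_range(list()), "at least one")
})

test_that("tetrachromat species range composes the per-pigment oracle ranges", {
  lmaxes <- c(370, 445, 508, 565)
  tbl <- dplyr::bind_rows(lapply(lmaxes, function(lm) {
    make_species_row(species_id = "tetra", class = "Aves",
                     receptor_label = paste0("R", lm), lambda_max_nm = lm)
  }))
  ranges <- species_visual_ranges(tbl)
  per_pigment <- vapply(lmaxes, oracle_dense_crossings, numeric(2))
  expect_equal(ranges$min_lambda_half_nm, min(per_pigment["min", ]),
               tolerance = 0.05)
  expect_equal(ranges$max_lambda_half_nm, max(per_pigment["max", ]),
               tolerance = 0.05)
  # envelope contains every per-pigment range
  for (lm in lmaxes) {
    vr <- pigment_visual_range(lm)
    expect_lte(ranges$min_lambda_half_nm, vr$min)
    expect_gte(ranges$max_lambda_half_nm, vr$max)
  }
})

test_that("species with missing lambda_max are flagged and excluded", {
  tbl <- dplyr::bind_rows(
    make_species_row("ok", lambda_max_nm = 530),
    make_species_row("broken", lambda_max_nm = NA_real_)
  )
  expect_warning(ranges <- species_visual_ranges(tbl), "broken")
  expect_identical(ranges$species_id, "ok")
  expect_error(
    suppressWarnings(species_visual_ranges(
      make_species_row("only", lambda_max_nm = NA_real_))),
    "no species left")
})
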