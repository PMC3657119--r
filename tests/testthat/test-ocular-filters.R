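test_that("droplet constructor enforces the clear-XOR-parameter invariant", {
  expect_error(oil_droplet(), "needs")
  expect_error(oil_droplet(lambda_cut = 500, clear = TRUE), "clear droplet")
  expect_error(oil_droplet(lambda_mid = 100), "300 and 700")
  expect_s3_class(oil_droplet(lambda_cut = 550), "oil_droplet")
})

test_that("clear droplets are the identity filter", {
  clear <- oil_droplet(clear = TRUE)
  expect_error(droplet_transmittance(clear), "clear droplet")
  with_clear <- pigment_visual_range(565, oil = clear)
  without <- pigment_visual_range(565)
  expect_identical(with_clear, without)
})

test_that("transmittance is a long-pass with half maximum at lambda_mid", {
  tr <- droplet_transmittance(oil_droplet(lambda_mid = 520))
  expect_equal(tr$value[abs(tr$wavelength - 520) < 1e-9], 0.5,
               tolerance = 1e-6)
  expect_true(all(diff(tr$value) >= 0))
  expect_gt(tr$value[length(tr$value)], 0.99)
  # well below lambda_cut (= mid - 12.5 at the default slope) it vanishes
  expect_lt(tr$value[abs(tr$wavelength - 460) < 1e-9], 1e-6)
})

test_that("transmittance matches an independent Gompertz transcription", {
  spots <- c(480, 500, 520, 540, 600)
  tr <- droplet_transmittance(oil_droplet(lambda_mid = 520))
  got <- tr$value[match(spots, tr$wavelength)]
  expect_equal(got, oracle_droplet_transmittance(spots, 520), tolerance = 1e-9)
})

test_that("lambda_cut converts to lambda_mid by tangent geometry", {
  expect_equal(lambda_mid_from_cut(550, slope = 0.04), 562.5)
  # a cut-parameterized droplet crosses 0.5 at the converted lambda_mid
  tr <- droplet_transmittance(oil_droplet(lambda_cut = 550), slope = 0.04)
  expect_equal(tr$value[abs(tr$wavelength - 562.5) < 1e-9], 0.5,
               tolerance = 1e-6)
})

test_that("apply_filter is a pointwise product with renormalization", {
  crv <- pigment_template(530)
  ident <- spectral_curve(crv$wavelength, rep(1, length(crv$wavelength)))
  expect_equal(apply_filter(crv, ident)$value, crv$value)
  other_grid <- pigment_template(530, grid = wavelength_grid(step = 0.5))
  expect_error(apply_filter(crv, other_grid), "different wavelength grids")
})

test_that("a long-pass filter pushes the sensitivity peak redward", {
  crv <- pigment_template(500)
  tr <- droplet_transmittance(oil_droplet(lambda_mid = 560))
  filtered <- apply_filter(crv, tr)
  expect_equal(max(filtered$value), 1)
  peak_raw <- crv$wavelength[which.max(crv$value)]
  peak_filt <- filtered$wavelength[which.max(filtered$value)]
  expect_gt(peak_filt, peak_raw)
})

test_that("filtered LWS pigment reproduces the frozen dense-grid oracle", {
  # frozen from oracle_dense_crossings(565, oil_mid = 560): 558.71, 620.92;
  # unfiltered: 502.74, 616.83
  unfiltered <- pigment_visual_range(565)
  filtered <- pigment_visual_range(565, oil = oil_droplet(lambda_mid = 560))
  expect_gt(filtered$min, unfiltered$min)
  expect_equal(filtered$min, 558.71, tolerance = 0.05)
  expect_equal(filtered$max, 620.92, tolerance = 0.05)
})

test_that("filtering never lowers the short-wavelength half-max limit", {
  unfiltered_min <- pigment_visual_range(565)$min
  for (mid in seq(480, 580, by = 20)) {
    filtered <- pigment_visual_range(565, oil = oil_droplet(lambda_mid = mid))
    expect_gte(filtered$min, unfiltered_min)
  }
})

test_that("droplets route only to non-UV receptors of birds and diurnal reptiles", {
  expect_true(droplet_applies("Aves", "LWS"))
  expect_false(droplet_applies("Aves", "UVS"))
  expect_true(droplet_applies("Reptilia", "LWS", diurnal = TRUE))
  expect_false(droplet_applies("Reptilia", "LWS", diurnal = FALSE))
  expect_false(droplet_applies("Reptilia", "LWS", diurnal = NA))
  expect_false(droplet_applies("Mammalia", "LWS"))
  expect_false(droplet_applies("Insecta", "MWS"))
  expect_false(droplet_applies("Arachnida", "MWS"))
})

test_that("droplet columns are inert for classes that bypass filtering", {
  for (cls in c("Mammalia", "Insecta", "Arachnida")) {
    plain <- species_visual_ranges(make_species_row(class = cls))
    with_cols <- species_visual_ranges(
      make_species_row(class = cls, oil_lambda_cut_nm = 500))
    expect_equal(with_cols$min_lambda_half_nm, plain$min_lambda_half_nm)
    expect_equal(with_cols$max_lambda_half_nm, plain$max_lambda_half_nm)
  }
  # nocturnal reptiles bypass, diurnal reptiles do not
  nocturnal <- species_visual_ranges(
    make_species_row(class = "Reptilia", lambda_max_nm = 560,
                     oil_lambda_cut_nm = 550, diurnal = FALSE))
  diurnal <- species_visual_ranges(
    make_species_row(class = "Reptilia", lambda_max_nm = 560,
                     oil_lambda_cut_nm = 550, diurnal = TRUE))
  plain <- species_visual_ranges(
    make_species_row(class = "Reptilia", lambda_max_nm = 560, diurnal = FALSE))
  expect_equal(nocturnal$min_lambda_half_nm, plain$min_lambda_half_nm)
  expect_gt(diurnal$min_lambda_half_nm, nocturnal$min_lambda_half_nm)
  # bird UV receptors bypass even with droplet columns populated
  uv_plain <- species_visual_ranges(
    make_species_row(class = "Aves", receptor_label = "UVS",
                     lambda_max_nm = 370))
  uv_cols <- species_visual_ranges(
    make_species_row(class = "Aves", receptor_label = "UVS",
                     lambda_max_nm = 370, oil_lambda_cut_nm = 400))
  expect_equal(uv_cols$min_lambda_half_nm, uv_plain$min_lambda_half_nm)
})
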