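#' Receptor profile for the synthetic species generator
#'
#' Describes one photoreceptor type within a class profile: the truncated
#' normal from which lambda_max is drawn, and whether (and how) an oil
#' droplet is attached for droplet-bearing classes.
#'
#' @param label Receptor label (labels containing "UV" are treated as UV
#'   receptors and never receive a pigmented droplet).
#' @param mean,sd Mean and standard deviation of lambda_max (nm).
#' @param bounds Length-2 truncation bounds for the lambda_max draw (nm).
#' @param droplet `"none"`, or which droplet parameter the generated table
#'   reports: `"cut"` (lambda_cut) or `"mid"` (lambda_mid).
#' @param droplet_offset Mean of `lambda_max - lambda_cut` (nm) for generated
#'   droplets; drawn with sd `droplet_offset_sd`.
#' @param droplet_offset_sd Spread of the droplet offset draw (nm).
#' @return A `pigment_profile` list.
#' @export
pigment_profile <- function(label, mean, sd, bounds,
                            droplet = c("none", "cut", "mid"),
                            droplet_offset = NA, droplet_offset_sd = 3) {
  droplet <- match.arg(droplet)
  stopifnot(sd >= 0, length(bounds) == 2, bounds[1] < bounds[2])
  if (droplet != "none" && !is.finite(droplet_offset)) {
    stop("droplet-bearing receptor profiles need a `droplet_offset`",
         call. = FALSE)
  }
  structure(list(label = label, mean = mean, sd = sd, bounds = bounds,
                 droplet = droplet, droplet_offset = droplet_offset,
                 droplet_offset_sd = droplet_offset_sd),
            class = "pigment_profile")
}

#' Class profile for the synthetic species generator
#'
#' @param taxon_class One of Arachnida, Insecta, Aves, Reptilia, Mammalia.
#' @param n_species Number of species to generate (>= 1).
#' @param pigments List of [pigment_profile()]s (>= 1).
#' @param diurnal_fraction Fraction of species flagged diurnal (reptiles
#'   only; droplets are generated only for diurnal reptiles and birds).
#' @return A `class_profile` list.
#' @export
class_profile <- function(taxon_class, n_species, pigments,
                          diurnal_fraction = NA) {
  taxon_class <- match.arg(taxon_class, TAXON_CLASSES[TAXON_CLASSES != "custom"])
  stopifnot(n_species >= 1, length(pigments) >= 1)
  structure(list(taxon_class = taxon_class, n_species = as.integer(n_species),
                 pigments = pigments, diurnal_fraction = diurnal_fraction),
            class = "class_profile")
}

#' Default class profiles of the synthetic species fleet
#'
#' Package defaults emulating the qualitative structure of published
#' lambda_max collations: 7 arachnids, 112 insects, 16 birds, 32 reptiles and
#' 46 mammals (213 species). Arachnids, insects and reptiles carry UV
#' receptors near 350--365 nm; bird UV sensitivity sits at longer wavelengths
#' (UVS ~370 nm); mammals are dichromats whose short cone lies at or above
#' 400 nm, so their visual range is the narrowest and excludes the UV. Birds
#' and the diurnal half of the reptiles carry pigmented oil droplets on their
#' non-UV cones, reported as lambda_cut for MWS/LWS and lambda_mid for SWS so
#' both ingest paths are exercised. The lambda_max spreads are broad for the
#' speciose classes (insects, mammals) and tight for the homogeneous bird
#' receptor set, as in real collations.
#'
#' @return Named list of [class_profile()]s.
#' @export
default_class_profiles <- function() {
  list(
    Arachnida = class_profile("Arachnida", 7, list(
      pigment_profile("UV", 358, 12, c(330, 390)),
      pigment_profile("MWS", 520, 25, c(470, 570))
    )),
    Insecta = class_profile("Insecta", 112, list(
      pigment_profile("UV", 350, 15, c(320, 390)),
      pigment_profile("SWS", 440, 18, c(400, 480)),
      pigment_profile("MWS", 530, 20, c(480, 575))
    )),
    Aves = class_profile("Aves", 16, list(
      pigment_profile("UVS", 370, 8, c(355, 390)),
      pigment_profile("SWS", 445, 10, c(420, 470), droplet = "mid",
                      droplet_offset = 27),
      pigment_profile("MWS", 505, 10, c(480, 530), droplet = "cut",
                      droplet_offset = 5),
      pigment_profile("LWS", 565, 8, c(545, 585), droplet = "cut",
                      droplet_offset = 10)
    )),
    Reptilia = class_profile("Reptilia", 32, list(
      pigment_profile("UVS", 365, 10, c(340, 390)),
      pigment_profile("SWS", 445, 12, c(415, 475), droplet = "mid",
                      droplet_offset = 27),
      pigment_profile("MWS", 495, 12, c(465, 525), droplet = "cut",
                      droplet_offset = 5),
      pigment_profile("LWS", 560, 10, c(535, 585), droplet = "cut",
                      droplet_offset = 10)
    ), diurnal_fraction = 0.5),
    Mammalia = class_profile("Mammalia", 46, list(
      pigment_profile("SWS", 430, 15, c(400, 465)),
      pigment_profile("LWS", 545, 20, c(500, 585))
    ))
  )
}

# truncated normal draw by rejection; profile error after `retries` failures
rtrunc_norm <- function(mean, sd, bounds, retries = 100) {
  for (i in seq_len(retries)) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= bounds[1] && x <= bounds[2]) return(x)
  }
  stop("lambda_max draw outside bounds after ", retries,
       " retries; check the profile mean/sd/bounds", call. = FALSE)
}

#' Generate a synthetic species photoreceptor table
#'
#' Draws a reproducible species table (one row per photoreceptor, one entry
#' per species) from class profiles. Per-class species counts are exactly as
#' configured; lambda_max values are truncated-normal draws rounded to whole
#' nm; birds and the diurnal fraction of reptiles receive oil-droplet
#' parameters on their non-UV receptors. Reptile diurnal flags are assigned
#' deterministically (the first `round(diurnal_fraction * n)` species are
#' diurnal) so counts are exact.
#'
#' @param profiles Named list of [class_profile()]s; defaults to
#'   [default_class_profiles()].
#' @param seed Integer seed.
#' @return A tibble passing [validate_species_table()].
#' @export
generate_species_table <- function(profiles = default_class_profiles(),
                                   seed = 1) {
  set.seed(seed)
  rows <- list()
  for (prof in profiles) {
    n_diurnal <- if (is.finite(prof$diurnal_fraction)) {
      round(prof$diurnal_fraction * prof$n_species)
    } else NA_integer_
    for (i in seq_len(prof$n_species)) {
      sid <- sprintf("%s_%03d", tolower(prof$taxon_class), i)
      diurnal <- if (is.na(n_diurnal)) NA else i <= n_diurnal
      for (pg in prof$pigments) {
        lmax <- round(rtrunc_norm(pg$mean, pg$sd, pg$bounds))
        cut <- mid <- NA_real_
        if (pg$droplet != "none" &&
            droplet_applies(prof$taxon_class, pg$label, diurnal)) {
          cut_raw <- lmax - max(stats::rnorm(1, pg$droplet_offset,
                                             pg$droplet_offset_sd), 0)
          if (pg$droplet == "cut") {
            cut <- round(cut_raw)
          } else {
            mid <- round(lambda_mid_from_cut(cut_raw))
          }
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          species_id = sid, class = prof$taxon_class,
          receptor_label = pg$label, lambda_max_nm = lmax,
          oil_lambda_cut_nm = cut, oil_lambda_mid_nm = mid,
          diurnal = diurnal
        )
      }
    }
  }
  validate_species_table(dplyr::bind_rows(rows))
}

#' Street-lamp spectral archetype
#'
#' Parametric stand-in for a measured lamp spectrum: a set of Gaussian
#' emission lines plus an optional broad continuum (implemented as a Gaussian
#' centred midway between `lo` and `hi` with sigma `(hi - lo) / 4`, so the
#' stated bounds sit near the +/- 2 sigma points).
#'
#' @param lamp_type One of `"LPS"`, `"HPS"`, `"LED"`, `"MH"`, `"custom"`.
#' @param lines Tibble/data frame with columns `centre` (nm, within 300--750),
#'   `width` (Gaussian sigma, nm) and `height` (> 0).
#' @param continuum Optional list with `lo`, `hi` (nm) and `height`.
#' @return A `lamp_archetype` list.
#' @export
lamp_archetype <- function(lamp_type, lines, continuum = NULL) {
  lamp_type <- match.arg(lamp_type, LAMP_TYPES)
  lines <- tibble::as_tibble(lines)
  stopifnot(all(c("centre", "width", "height") %in% names(lines)),
            all(lines$centre >= 300 & lines$centre <= 750),
            all(lines$height > 0), all(lines$width > 0))
  if (!is.null(continuum)) {
    stopifnot(all(c("lo", "hi", "height") %in% names(continuum)),
              continuum$lo < continuum$hi, continuum$height > 0)
  }
  structure(list(lamp_type = lamp_type, lines = lines, continuum = continuum),
            class = "lamp_archetype")
}

#' Default archetypes of the four street-lamp technologies
#'
#' Stand-ins for the three technology categories: a narrow non-UV source
#' (LPS: sodium doublet at 589 nm with weak satellite lines), two broad
#' non-UV sources with matched short-wavelength cut-ons near 423 nm (HPS:
#' yellow-orange lines on a red-shifted continuum; LED: 450 nm blue pump plus
#' a phosphor hump) and a broad UV-emitting source (MH: mercury/halide lines
#' at 365--436 nm on a wide continuum).
#'
#' @return Named list of [lamp_archetype()]s.
#' @export
default_lamp_archetypes <- function() {
  list(
    LPS = lamp_archetype("LPS", tibble::tibble(
      centre = c(589, 589.6, 568, 615),
      width = c(5, 5, 3, 3),
      height = c(1, 0.9, 0.04, 0.03)
    )),
    HPS = lamp_archetype("HPS", tibble::tibble(
      centre = c(435, 460, 498, 569, 589, 615),
      width = c(5, 4, 4, 5, 8, 6),
      height = c(0.30, 0.06, 0.10, 0.9, 1, 0.7)
    ), continuum = list(lo = 525, hi = 665, height = 0.55)),
    LED = lamp_archetype("LED", tibble::tibble(
      centre = 450, width = 9, height = 1
    ), continuum = list(lo = 475, hi = 655, height = 0.55)),
    MH = lamp_archetype("MH", tibble::tibble(
      centre = c(365, 405, 436, 546, 578, 620),
      width = c(4, 4, 5, 5, 5, 6),
      height = c(0.35, 0.45, 0.5, 0.8, 0.7, 0.3)
    ), continuum = list(lo = 410, hi = 630, height = 0.45))
  )
}

#' Generate a synthetic lamp spectrum from an archetype
#'
#' Sum of the archetype's Gaussian lines and continuum, plus a small
#' non-negative noise floor emulating spectrometer read noise (folded normal,
#' sd `noise_sd` relative to the clean peak).
#'
#' @param archetype A [lamp_archetype()].
#' @param grid Wavelength grid (nm).
#' @param seed Integer seed for the noise draw.
#' @param noise_sd Relative noise level; default 2e-4.
#' @return A [lamp_spectrum].
#' @export
generate_lamp_spectrum <- function(archetype, grid = wavelength_grid(),
                                   seed = 1, noise_sd = 2e-4) {
  stopifnot(inherits(archetype, "lamp_archetype"))
  set.seed(seed)
  v <- numeric(length(grid))
  for (i in seq_len(nrow(archetype$lines))) {
    ln <- archetype$lines[i, ]
    v <- v + ln$height * exp(-((grid - ln$centre) / ln$width)^2 / 2)
  }
  if (!is.null(archetype$continuum)) {
    cn <- archetype$continuum
    centre <- (cn$lo + cn$hi) / 2
    sigma <- (cn$hi - cn$lo) / 4
    v <- v + cn$height * exp(-((grid - centre) / sigma)^2 / 2)
  }
  v <- v + abs(stats::rnorm(length(grid), 0, noise_sd * max(v)))
  lamp_spectrum(grid, v, archetype$lamp_type)
}

#' Write a lamp spectrum as a two-column spectrometer text file
#'
#' @param spectrum A [lamp_spectrum].
#' @param path Output path; a `#` comment header records the lamp type.
#' @return `path`, invisibly.
#' @export
write_lamp_spectrum <- function(spectrum, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# lamp_type: %s", spectrum$lamp_type), con)
  writeLines(sprintf("%.4f %.12g", spectrum$wavelength, spectrum$irradiance),
             con)
  invisible(path)
}
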