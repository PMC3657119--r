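#' Visual pigment absorbance from the A1 alpha+beta band template
#'
#' Evaluates the standard A1 visual pigment template at each grid wavelength
#' for a pigment with peak absorbance at `lambda_max`. The alpha band is a
#' sum-of-exponentials in `x = lambda_max / lambda`; the beta band is a
#' Gaussian whose centre and half-bandwidth are linear in `lambda_max`. The
#' returned curve is the alpha + beta sum, by default renormalized so its
#' maximum is exactly 1 (half-maximum sensitivity is defined relative to the
#' pigment's own peak).
#'
#' @param lambda_max Wavelength of peak absorbance in nm; must lie in
#'   \[300, 700\], the calibration range of the template for pigments in scope.
#' @param grid Wavelength grid (nm); must cover at least 300--700 nm so that
#'   half-maximum crossings of any admissible pigment fall inside the window.
#' @param normalize If `TRUE` (default) rescale so `max(value) == 1`; the raw
#'   alpha + beta sum can marginally exceed 1 near the peak.
#' @return A [spectral_curve] of relative absorbance.
#' @seealso [half_max_crossings()], [species_visual_range()]
#' @examples
#' crv <- pigment_template(500)
#' crv$value[crv$wavelength == 500]
#' @export
pigment_template <- function(lambda_max, grid = wavelength_grid(), normalize = TRUE) {
  check_lambda_max(lambda_max)
  if (min(grid) > 300 || max(grid) < 700) {
    stop("wavelength grid does not cover the 300-700 nm modelling window",
         call. = FALSE)
  }
  v <- a1_template_raw(grid, lambda_max)
  if (normalize) v <- v / max(v)
  spectral_curve(grid, v)
}

check_lambda_max <- function(lambda_max) {
  if (!is.numeric(lambda_max) || length(lambda_max) != 1 || !is.finite(lambda_max) ||
      lambda_max < 300 || lambda_max > 700) {
    stop("`lambda_max` must be a single wavelength between 300 and 700 nm",
         call. = FALSE)
  }
  invisible(lambda_max)
}

# A1 template: alpha band S(x) = 1 / (exp(A(a - x)) + exp(B(b - x)) +
# exp(C(c - x)) + D) with x = lambda_max/lambda, A = 69.7, B = 28, C = -14.9,
# D = 0.674, b = 0.922, c = 1.104 and a = 0.8795 + 0.0459 exp(-(lambda_max -
# 300)^2 / 11940); beta band 0.26 exp(-((lambda - (189 + 0.315 lambda_max)) /
# (-40.5 + 0.195 lambda_max))^2).
a1_template_raw <- function(lambda, lambda_max) {
  x <- lambda_max / lambda
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  alpha <- 1 / (exp(69.7 * (a - x)) +
                exp(28 * (0.922 - x)) +
                exp(-14.9 * (1.104 - x)) +
                0.674)
  beta_centre <- 189 + 0.315 * lambda_max
  beta_width <- -40.5 + 0.195 * lambda_max
  beta <- 0.26 * exp(-((lambda - beta_centre) / beta_width)^2)
  alpha + beta
}

#' Outermost half-maximum crossings of a sensitivity curve
#'
#' Locates the outermost wavelengths at which a peak-normalized curve crosses
#' a given fractional level (default 0.5, the lambda_0.5 convention). Crossing
#' positions are refined by linear interpolation between the bracketing grid
#' points. If the curve is still at or above the level at a window edge, the
#' edge wavelength is returned with a boundary warning. Interior dips below
#' the level between the outermost crossings do not split the interval (the
#' visual range is reported as one enveloping interval); such gaps are
#' reported via a message and recorded in the `gap` field.
#'
#' @param curve A [spectral_curve], normalized so its maximum is 1.
#' @param level Fraction of the maximum in (0, 1); default 0.5.
#' @return A `visual_range` object: list with `min`, `max` (nm) and logical
#'   `gap`.
#' @export
half_max_crossings <- function(curve, level = 0.5) {
  stopifnot(inherits(curve, "spectral_curve"))
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    stop("`level` must be a fraction strictly between 0 and 1", call. = FALSE)
  }
  w <- curve$wavelength
  v <- curve$value
  if (max(v) < level) {
    stop("degenerate curve: never reaches the requested level", call. = FALSE)
  }
  idx <- which(v >= level)
  i1 <- idx[1]
  i2 <- idx[length(idx)]

  if (i1 == 1L) {
    warning("curve still at/above level at the short-wavelength window edge; ",
            "returning the edge", call. = FALSE)
    lo <- w[1]
  } else {
    lo <- interp_crossing(w[i1 - 1L], w[i1], v[i1 - 1L], v[i1], level)
  }
  if (i2 == length(w)) {
    warning("curve still at/above level at the long-wavelength window edge; ",
            "returning the edge", call. = FALSE)
    hi <- w[length(w)]
  } else {
    hi <- interp_crossing(w[i2], w[i2 + 1L], v[i2], v[i2 + 1L], level)
  }

  if (hi <= lo) {
    stop("degenerate curve: half-maximum interval has zero width", call. = FALSE)
  }
  gap <- !all(v[i1:i2] >= level)
  if (gap) {
    message("interior sub-threshold gap between the outermost crossings; ",
            "reporting the enveloping interval")
  }
  visual_range(lo, hi, gap = gap)
}

interp_crossing <- function(w0, w1, v0, v1, level) {
  if (v1 == v0) return(w1)
  w0 + (level - v0) / (v1 - v0) * (w1 - w0)
}

#' Construct a species/pigment visual range
#'
#' @param min,max Outermost half-maximum wavelengths in nm (`min < max`).
#' @param gap Whether the underlying curve dipped below the level between the
#'   outermost crossings.
#' @return A `visual_range` object.
#' @export
visual_range <- function(min, max, gap = FALSE) {
  if (!is.finite(min) || !is.finite(max) || min >= max) {
    stop("visual range requires min < max, both finite", call. = FALSE)
  }
  structure(list(min = min, max = max, gap = isTRUE(gap)), class = "visual_range")
}

#' @export
print.visual_range <- function(x, ...) {
  cat(sprintf("<visual_range> %.2f-%.2f nm (width %.2f nm)%s\n",
              x$min, x$max, x$max - x$min,
              if (x$gap) " [interior gap]" else ""))
  invisible(x)
}

#' Half-maximum range of a single photoreceptor
#'
#' Convenience wrapper: evaluates the pigment template, applies an optional
#' oil-droplet transmittance filter, renormalizes, and extracts the outermost
#' half-maximum crossings.
#'
#' @inheritParams pigment_template
#' @param oil Optional [oil_droplet()]; clear droplets act as the identity.
#' @param level Fractional sensitivity level, default 0.5.
#' @param slope Droplet edge slope passed to [droplet_transmittance()] when
#'   only `lambda_cut` is known.
#' @param renormalize Renormalize the filtered curve to peak 1 before crossing
#'   extraction (default `TRUE`).
#' @return A `visual_range`.
#' @export
pigment_visual_range <- function(lambda_max, oil = NULL, grid = wavelength_grid(),
                                 level = 0.5, slope = 0.04, renormalize = TRUE) {
  crv <- pigment_template(lambda_max, grid)
  if (!is.null(oil) && !oil$clear) {
    tr <- droplet_transmittance(oil, grid, slope = slope)
    crv <- apply_filter(crv, tr, renormalize = renormalize)
  }
  half_max_crossings(crv, level = level)
}

#' Species-level visual range as the envelope of per-pigment ranges
#'
#' The species' visual range (lambda_0.5 range) is the single enveloping
#' interval from the smallest per-pigment minimum to the largest per-pigment
#' maximum half-maximum wavelength.
#'
#' @param ranges List of `visual_range` objects, one per pigment (>= 1).
#' @return A `visual_range`.
#' @export
species_visual_range <- function(ranges) {
  if (length(ranges) < 1) {
    stop("a species must have at least one pigment", call. = FALSE)
  }
  stopifnot(all(vapply(ranges, inherits, logical(1), "visual_range")))
  visual_range(
    min(vapply(ranges, `[[`, numeric(1), "min")),
    max(vapply(ranges, `[[`, numeric(1), "max")),
    gap = any(vapply(ranges, `[[`, logical(1), "gap"))
  )
}

#' Half-maximum visual ranges for a species photoreceptor table
#'
#' Computes per-pigment half-maximum ranges (with oil-droplet filtering where
#' applicable) and the per-species enveloping interval for every species in a
#' photoreceptor table (one row per photoreceptor, see
#' [read_species_table()]). Oil droplets are applied only to non-UV receptors
#' of birds and of diurnal reptiles; all other rows bypass filtering even if
#' droplet columns are populated. Species with a missing `lambda_max_nm` on
#' any row are excluded with a warning naming them (they are flagged, not
#' silently dropped).
#'
#' @param species A tibble with columns `species_id`, `class`,
#'   `receptor_label`, `lambda_max_nm`, `oil_lambda_cut_nm`,
#'   `oil_lambda_mid_nm`, `diurnal`.
#' @inheritParams pigment_visual_range
#' @return A tibble with one row per species: `species_id`, `class`,
#'   `n_pigments`, `min_lambda_half_nm`, `max_lambda_half_nm`.
#' @export
species_visual_ranges <- function(species, grid = wavelength_grid(), level = 0.5,
                                  slope = 0.04, renormalize = TRUE) {
  species <- validate_species_table(species)

  missing_ids <- unique(species$species_id[!is.finite(species$lambda_max_nm)])
  if (length(missing_ids) > 0) {
    warning("excluding ", length(missing_ids),
            " species with missing lambda_max for known photoreceptors: ",
            paste(missing_ids, collapse = ", "), call. = FALSE)
    species <- species[!(species$species_id %in% missing_ids), , drop = FALSE]
  }
  if (nrow(species) == 0) {
    stop("no species left after excluding rows with missing lambda_max",
         call. = FALSE)
  }

  out <- lapply(split(species, factor(species$species_id,
                                      levels = unique(species$species_id))),
                function(rows) {
    ranges <- lapply(seq_len(nrow(rows)), function(i) {
      row <- rows[i, ]
      oil <- NULL
      if (droplet_applies(row$class, row$receptor_label, row$diurnal) &&
          (is.finite(row$oil_lambda_cut_nm) || is.finite(row$oil_lambda_mid_nm))) {
        oil <- oil_droplet(
          lambda_cut = if (is.finite(row$oil_lambda_cut_nm)) row$oil_lambda_cut_nm else NULL,
          lambda_mid = if (is.finite(row$oil_lambda_mid_nm)) row$oil_lambda_mid_nm else NULL
        )
      }
      pigment_visual_range(row$lambda_max_nm, oil = oil, grid = grid,
                           level = level, slope = slope,
                           renormalize = renormalize)
    })
    sp <- species_visual_range(ranges)
    tibble::tibble(
      species_id = rows$species_id[1],
      class = rows$class[1],
      n_pigments = nrow(rows),
      min_lambda_half_nm = sp$min,
      max_lambda_half_nm = sp$max
    )
  })
  dplyr::bind_rows(out)
}
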