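#' Cone oil droplet descriptor
#'
#' Bird and diurnal-reptile cone photoreceptors contain carotenoid-pigmented
#' oil droplets that act as long-pass spectral filters in front of the visual
#' pigment. A droplet is characterized either by its cut-off wavelength
#' `lambda_cut` (axis intercept of the tangent to the transmittance curve at
#' half-maximum) or by `lambda_mid`, the wavelength of half-maximum
#' transmittance. UV cones and all cones of nocturnal reptiles carry clear
#' (transparent) droplets that do not filter.
#'
#' @param lambda_cut,lambda_mid Droplet parameters in nm; at least one must be
#'   given unless `clear = TRUE`.
#' @param clear Transparent droplet (identity filter).
#' @return An `oil_droplet` object.
#' @export
oil_droplet <- function(lambda_cut = NULL, lambda_mid = NULL, clear = FALSE) {
  if (isTRUE(clear)) {
    if (!is.null(lambda_cut) || !is.null(lambda_mid)) {
      stop("a clear droplet takes no cut-off parameters", call. = FALSE)
    }
  } else if (is.null(lambda_cut) && is.null(lambda_mid)) {
    stop("a pigmented droplet needs `lambda_cut` or `lambda_mid`", call. = FALSE)
  }
  for (p in c(lambda_cut, lambda_mid)) {
    if (!is.finite(p) || p < 300 || p > 700) {
      stop("droplet wavelengths must lie between 300 and 700 nm", call. = FALSE)
    }
  }
  structure(list(lambda_cut = lambda_cut, lambda_mid = lambda_mid,
                 clear = isTRUE(clear)),
            class = "oil_droplet")
}

#' Convert a droplet cut-off wavelength to its half-maximum wavelength
#'
#' Uses the tangent geometry of the long-pass edge: the tangent at the
#' half-maximum point has slope `slope` (per nm) and intersects zero
#' transmittance at `lambda_cut`, so `lambda_mid = lambda_cut + 0.5 / slope`.
#'
#' @param lambda_cut Cut-off wavelength (nm).
#' @param slope Edge slope at half maximum, per nm; default 0.04 gives the
#'   ~12.5 nm cut-to-mid offset typical of published avian droplet data.
#' @return `lambda_mid` in nm.
#' @export
lambda_mid_from_cut <- function(lambda_cut, slope = 0.04) {
  if (!is.numeric(slope) || slope <= 0) {
    stop("`slope` must be positive", call. = FALSE)
  }
  lambda_cut + 0.5 / slope
}

#' Oil droplet transmittance curve
#'
#' Gompertz-type double-exponential long-pass transmittance
#' `T(lambda) = exp(-ln 2 * exp(-k (lambda - lambda_mid)))` with the rate `k`
#' scaled so that the slope of `T` at `lambda_mid` equals `slope`
#' (`k = slope / (0.5 ln 2)`). By construction `T(lambda_mid) = 0.5` exactly,
#' `T` is strictly increasing, tends to 1 at long wavelengths and to 0 well
#' below `lambda_cut`. If only `lambda_cut` is known, `lambda_mid` is obtained
#' with [lambda_mid_from_cut()].
#'
#' @param droplet An [oil_droplet()]; must not be clear (clear droplets are
#'   the identity and should bypass filtering).
#' @param grid Wavelength grid (nm).
#' @param slope Edge slope at half maximum (per nm), default 0.04.
#' @return A [spectral_curve] with values in (0, 1\].
#' @export
droplet_transmittance <- function(droplet, grid = wavelength_grid(), slope = 0.04) {
  stopifnot(inherits(droplet, "oil_droplet"))
  if (droplet$clear) {
    stop("clear droplet: use the unfiltered pigment curve directly", call. = FALSE)
  }
  if (!is.numeric(slope) || slope <= 0) {
    stop("`slope` must be positive", call. = FALSE)
  }
  mid <- droplet$lambda_mid
  if (is.null(mid)) mid <- lambda_mid_from_cut(droplet$lambda_cut, slope)
  k <- slope / (0.5 * log(2))
  tr <- exp(-log(2) * exp(-k * (grid - mid)))
  spectral_curve(grid, tr)
}

#' Apply a transmittance filter to a pigment absorbance curve
#'
#' Pointwise product of the pigment curve and the filter transmittance,
#' optionally renormalized to peak 1 so that subsequent half-maximum crossing
#' extraction reflects the filtered receptor's own maximum.
#'
#' @param pigment_curve,transmittance [spectral_curve]s on identical grids.
#' @param renormalize Rescale the product to `max == 1` (default `TRUE`).
#' @return A [spectral_curve].
#' @export
apply_filter <- function(pigment_curve, transmittance, renormalize = TRUE) {
  stopifnot(inherits(pigment_curve, "spectral_curve"),
            inherits(transmittance, "spectral_curve"))
  stopifnot_same_grid(pigment_curve, transmittance)
  v <- pigment_curve$value * transmittance$value
  if (renormalize) v <- v / max(v)
  spectral_curve(pigment_curve$wavelength, v)
}

#' Does oil-droplet filtering apply to this photoreceptor?
#'
#' Routing rule: droplets filter only the non-UV receptors of birds and of
#' diurnal reptiles. UV receptors, nocturnal reptiles and all other classes
#' bypass (their droplets, if any, are clear).
#'
#' @param class Taxonomic class label.
#' @param receptor_label Free-text receptor label; labels containing "UV"
#'   (case-insensitive) are treated as UV receptors.
#' @param diurnal Logical diurnal flag (reptiles only; `NA` elsewhere).
#' @return Logical.
#' @export
droplet_applies <- function(class, receptor_label, diurnal = NA) {
  if (grepl("uv", receptor_label, ignore.case = TRUE)) return(FALSE)
  if (identical(class, "Aves")) return(TRUE)
  if (identical(class, "Reptilia")) return(isTRUE(diurnal))
  FALSE
}
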