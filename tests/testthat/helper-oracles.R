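# Independent oracles used throughout the suite. These are deliberate second
# transcriptions of the published formulas and brute-force computations kept
# separate from the package implementation, so tests compare two routes to
# the same quantity.

# A1 pigment template (alpha sum-of-exponentials + beta Gaussian), written
# independently of lampvision:::a1_template_raw.
oracle_pigment_absorbance <- function(wl, peak) {
  x <- peak / wl
  a_const <- 0.8795 + 0.0459 * exp(-((peak - 300)^2) / 11940)
  inv_alpha <- exp(69.7 * (a_const - x)) +
    exp(28 * (0.922 - x)) +
    exp(-14.9 * (1.104 - x)) +
    0.674
  beta_band <- 0.26 * exp(-((wl - (189 + 0.315 * peak)) /
                              (0.195 * peak - 40.5))^2)
  1 / inv_alpha + beta_band
}

# Gompertz long-pass droplet transmittance written as a power of one half:
# T = 0.5 ^ exp(-rate (wl - mid)), rate chosen so the slope at `mid` is bmid.
oracle_droplet_transmittance <- function(wl, mid, bmid = 0.04) {
  0.5^(exp(-(bmid / (0.5 * log(2))) * (wl - mid)))
}

# Brute-force half-maximum crossings on a dense grid (default 0.01 nm):
# outermost grid points at/above the level, optionally after droplet
# filtering. Resolution-limited, so comparisons use a 0.05 nm tolerance.
oracle_dense_crossings <- function(peak, level = 0.5, step = 0.01,
                                   oil_mid = NULL, slope = 0.04) {
  wl <- seq(200, 750, by = step)
  v <- oracle_pigment_absorbance(wl, peak)
  if (!is.null(oil_mid)) {
    v <- v * oracle_droplet_transmittance(wl, oil_mid, slope)
  }
  v <- v / max(v)
  hit <- which(v >= level)
  c(min = wl[hit[1]], max = wl[hit[length(hit)]])
}

# Direct closed-interval arithmetic for the overlap index.
oracle_percent_overlap <- function(vlo, vhi, elo, ehi) {
  100 * max(0, min(vhi, ehi) - max(vlo, elo)) / (vhi - vlo)
}

# Minimal valid one-species photoreceptor table for targeted tests.
make_species_row <- function(species_id = "sp1", class = "Insecta",
                             receptor_label = "MWS", lambda_max_nm = 530,
                             oil_lambda_cut_nm = NA_real_,
                             oil_lambda_mid_nm = NA_real_, diurnal = NA) {
  tibble::tibble(species_id = species_id, class = class,
                 receptor_label = receptor_label,
                 lambda_max_nm = lambda_max_nm,
                 oil_lambda_cut_nm = oil_lambda_cut_nm,
                 oil_lambda_mid_nm = oil_lambda_mid_nm, diurnal = diurnal)
}
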