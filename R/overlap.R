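#' Percentage of a species' visual range stimulated by a lamp
#'
#' The core index of the analysis: the percentage of the species' lambda_0.5
#' range (the interval between the outermost half-maximum wavelengths)
#' overlapped by the lamp's emission range. Interval arithmetic is carried out
#' on closed intervals in continuous nm (no grid counting). In `"span"` mode
#' (default) the emission range is its single contiguous span; in `"union"`
#' mode intersection lengths are summed over the disjoint emission intervals.
#'
#' @param visual A `visual_range` (or list with `min`/`max` in nm).
#' @param emission An `emission_range`.
#' @param mode `"span"` or `"union"`.
#' @return Percentage in \[0, 100\].
#' @export
percent_range_stimulated <- function(visual, emission, mode = c("span", "union")) {
  mode <- match.arg(mode)
  width <- visual$max - visual$min
  if (!is.finite(width) || width <= 0) {
    stop("visual range has zero or negative width", call. = FALSE)
  }
  if (mode == "span") {
    ov <- interval_overlap(visual$min, visual$max,
                           emission$span[1], emission$span[2])
  } else {
    ov <- sum(mapply(interval_overlap, emission$intervals$lo,
                     emission$intervals$hi,
                     MoreArgs = list(lo = visual$min, hi = visual$max)))
  }
  min(max(100 * ov / width, 0), 100)
}

interval_overlap <- function(lo, hi, lo2, hi2) {
  max(0, min(hi, hi2) - max(lo, lo2))
}

#' Species x lamp overlap table
#'
#' Assembles one row per species x lamp combination with the species'
#' half-maximum range, the lamp's emission span and the percentage of the
#' visual range stimulated. Per-species failures are reported as warnings with
#' the species id and the species is skipped, not fatal.
#'
#' @param ranges Species range table from [species_visual_ranges()].
#' @param emissions Named list of `emission_range` objects (names are lamp
#'   types) or a single `emission_range`.
#' @param mode Passed to [percent_range_stimulated()].
#' @return A tibble with columns `species_id`, `class`, `lamp_type`,
#'   `min_lambda_half_nm`, `max_lambda_half_nm`, `lamp_span_lo_nm`,
#'   `lamp_span_hi_nm`, `percent_stimulated`.
#' @export
overlap_table <- function(ranges, emissions, mode = c("span", "union")) {
  mode <- match.arg(mode)
  if (inherits(emissions, "emission_range")) {
    emissions <- stats::setNames(list(emissions), emissions$lamp_type)
  }
  stopifnot(length(emissions) >= 1)
  rows <- list()
  for (lamp in names(emissions)) {
    em <- emissions[[lamp]]
    for (i in seq_len(nrow(ranges))) {
      vr <- list(min = ranges$min_lambda_half_nm[i],
                 max = ranges$max_lambda_half_nm[i])
      pct <- tryCatch(percent_range_stimulated(vr, em, mode = mode),
                      error = function(e) {
                        warning("species ", ranges$species_id[i], " skipped: ",
                                conditionMessage(e), call. = FALSE)
                        NA_real_
                      })
      if (is.na(pct)) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        species_id = ranges$species_id[i],
        class = ranges$class[i],
        lamp_type = lamp,
        min_lambda_half_nm = vr$min,
        max_lambda_half_nm = vr$max,
        lamp_span_lo_nm = em$span[1],
        lamp_span_hi_nm = em$span[2],
        percent_stimulated = pct
      )
    }
  }
  dplyr::bind_rows(rows)
}
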