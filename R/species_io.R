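TAXON_CLASSES <- c("Arachnida", "Insecta", "Aves", "Reptilia", "Mammalia")

species_table_columns <- c("species_id", "class", "receptor_label",
                           "lambda_max_nm", "oil_lambda_cut_nm",
                           "oil_lambda_mid_nm", "diurnal")

#' Validate a species photoreceptor table
#'
#' Checks the one-row-per-photoreceptor contract: required columns present,
#' class labels from the closed set (Arachnida, Insecta, Aves, Reptilia,
#' Mammalia), every non-missing lambda_max within 300--700 nm, and at least
#' one pigment per species. Missing lambda_max values are allowed here (they
#' are flagged and excluded downstream by [species_visual_ranges()]).
#'
#' @param species A data frame / tibble.
#' @return The validated table as a tibble (invisibly usable in pipes).
#' @export
validate_species_table <- function(species) {
  species <- tibble::as_tibble(species)
  missing_cols <- setdiff(species_table_columns, names(species))
  if (length(missing_cols) > 0) {
    stop("species table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(species) == 0) stop("species table is empty", call. = FALSE)
  bad_class <- setdiff(unique(species$class), TAXON_CLASSES)
  if (length(bad_class) > 0) {
    stop("unknown taxonomic class label(s): ",
         paste(bad_class, collapse = ", "), call. = FALSE)
  }
  lm <- species$lambda_max_nm
  out_of_range <- is.finite(lm) & (lm < 300 | lm > 700)
  if (any(out_of_range)) {
    stop("lambda_max outside 300-700 nm in row(s): ",
         paste(which(out_of_range), collapse = ", "), call. = FALSE)
  }
  species
}

#' Read a species photoreceptor table from CSV
#'
#' One row per photoreceptor with header
#' `species_id, class, receptor_label, lambda_max_nm, oil_lambda_cut_nm,
#' oil_lambda_mid_nm, diurnal`. Empty oil fields mean no (or clear) droplet.
#' Species with missing lambda_max for known photoreceptors are kept in the
#' returned table but reported with a warning so the exclusion applied later
#' is visible at ingest.
#'
#' @param path CSV file path (UTF-8, header required).
#' @param dedupe_sex If `TRUE` and an optional `sex` column is present, keep
#'   for each species only the sex with the larger number of quantified
#'   pigments (the female on ties), mirroring the convention used when male
#'   and female spectral sensitivities are reported separately.
#' @return A tibble passing [validate_species_table()].
#' @export
read_species_table <- function(path, dedupe_sex = FALSE) {
  species <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (isTRUE(dedupe_sex) && "sex" %in% names(species)) {
    species <- dedupe_by_sex(species)
  }
  species$diurnal <- as.logical(species$diurnal)
  species <- validate_species_table(species[, species_table_columns])
  n_missing <- sum(!is.finite(species$lambda_max_nm))
  if (n_missing > 0) {
    warning(n_missing, " photoreceptor row(s) with missing lambda_max; ",
            "the affected species will be excluded from range estimation",
            call. = FALSE)
  }
  species
}

# keep, per species, the sex with more quantified pigments; female on ties
dedupe_by_sex <- function(species) {
  keep <- unlist(lapply(split(seq_len(nrow(species)), species$species_id),
                        function(ix) {
    sx <- species$sex[ix]
    if (length(unique(sx)) < 2) return(ix)
    counts <- table(sx[is.finite(species$lambda_max_nm[ix])])
    best <- names(counts)[counts == max(counts)]
    pick <- if (length(best) > 1 && "F" %in% best) "F" else best[1]
    ix[sx == pick]
  }), use.names = FALSE)
  species[sort(keep), , drop = FALSE]
}

#' Write a species photoreceptor table to CSV
#'
#' @param species Table passing [validate_species_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_species_table <- function(species, path) {
  readr::write_csv(validate_species_table(species), path, progress = FALSE)
  invisible(path)
}
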