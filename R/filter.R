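#' Somatic filter parameters
#'
#' Parameters of the three-stage somatic filtering cascade: matched-normal
#' subtraction, consequence filtering, and population-frequency filtering.
#'
#' @param max_population_freq variants with a known population frequency
#'   strictly above this fraction are removed ("higher frequency" rule);
#'   default 0.005 (0.5%). A frequency exactly at the threshold is kept,
#'   and an unknown frequency is treated as rare (kept), mirroring novel
#'   variants absent from dbSNP/1000 Genomes/HapMap.
#' @param drop_consequences consequence classes removed outright; default
#'   synonymous and noncoding.
#' @param match_keys columns defining tumor-vs-normal variant identity for
#'   subtraction; default chromosome, position and both alleles (exact
#'   allele identity; inputs are assumed left-normalized upstream).
#' @return an object of class `spex_filter_params`.
#' @seealso [run_filter_pipeline()]
#' @export
filter_params <- function(max_population_freq = 0.005,
                          drop_consequences = c("synonymous", "noncoding"),
                          match_keys = c("chromosome", "position",
                                         "ref_allele", "alt_allele")) {
  stopifnot(is.numeric(max_population_freq), length(max_population_freq) == 1,
            max_population_freq >= 0, max_population_freq <= 1)
  stopifnot(all(drop_consequences %in% CONSEQUENCES))
  stopifnot(length(match_keys) >= 1, all(match_keys %in% VARIANT_COLUMNS))
  structure(list(max_population_freq = max_population_freq,
                 drop_consequences = drop_consequences,
                 match_keys = match_keys),
            class = "spex_filter_params")
}

match_key_string <- function(variants, keys) {
  if (nrow(variants) == 0) return(character(0))
  do.call(paste, c(lapply(keys, function(k) variants[[k]]), sep = "\r"))
}

check_single_patient <- function(tumor, normal) {
  ids <- unique(c(tumor$patient_id, normal$patient_id))
  if (length(ids) > 1) {
    stop("mixed patient_ids: tumor/normal pair must belong to one patient (",
         paste(ids, collapse = ", "), ")", call. = FALSE)
  }
  invisible(ids)
}

#' Subtract matched-normal calls from a tumor call set
#'
#' Returns the tumor records whose identity tuple (see
#' [filter_params()] `match_keys`) is absent from the matched normal —
#' the paired-comparison step that makes a call set tumor-specific
#' (somatic). Input order is preserved.
#'
#' @param tumor,normal variant tables for one patient.
#' @param params [filter_params()].
#' @return the tumor-only subset of `tumor`.
#' @export
subtract_matched_normal <- function(tumor, normal, params = filter_params()) {
  tumor <- as_variant_table(tumor, "tumor")
  normal <- as_variant_table(normal, "normal")
  check_single_patient(tumor, normal)
  keep <- !(match_key_string(tumor, params$match_keys) %in%
              match_key_string(normal, params$match_keys))
  tumor[keep, , drop = FALSE]
}

#' Remove variants by annotated consequence
#'
#' Drops records whose `consequence` is in `params$drop_consequences`
#' (default: synonymous and noncoding variants are removed).
#'
#' @param variants variant table.
#' @param params [filter_params()].
#' @return the retained subset, order preserved.
#' @export
apply_consequence_filter <- function(variants, params = filter_params()) {
  variants <- as_variant_table(variants)
  variants[!(variants$consequence %in% params$drop_consequences), ,
           drop = FALSE]
}

#' Remove common variants by population frequency
#'
#' Drops records whose known `population_freq` is strictly greater than
#' `params$max_population_freq`; unknown frequencies are kept.
#'
#' @param variants variant table.
#' @param params [filter_params()].
#' @return the retained subset, order preserved.
#' @export
apply_frequency_filter <- function(variants, params = filter_params()) {
  variants <- as_variant_table(variants)
  common <- !is.na(variants$population_freq) &
    variants$population_freq > params$max_population_freq
  variants[!common, , drop = FALSE]
}

#' Run the full somatic filtering cascade for one patient
#'
#' Applies, in order, matched-normal subtraction, the consequence filter
#' and the population-frequency filter, and reports how many records each
#' stage removed. A record failing several filters is attributed to the
#' first stage that removes it, so the counts partition the input:
#' `input_count = removed_by_normal + removed_by_consequence +
#' removed_by_frequency + nrow(retained)`.
#'
#' @param tumor,normal variant tables for one patient.
#' @param params [filter_params()].
#' @return an object of class `spex_filter_report`: a list with
#'   `input_count`, `removed_by_normal`, `removed_by_consequence`,
#'   `removed_by_frequency` and the `retained` variant table.
#' @examples
#' sim <- generate_paired_cohort(sim_config(seed = 1, n_patients = 1))
#' rep <- run_filter_pipeline(sim$tumor, sim$normal)
#' rep$input_count - nrow(rep$retained)
#' @export
run_filter_pipeline <- function(tumor, normal, params = filter_params()) {
  tumor <- as_variant_table(tumor, "tumor")
  normal <- as_variant_table(normal, "normal")
  check_single_patient(tumor, normal)
  n0 <- nrow(tumor)
  s1 <- subtract_matched_normal(tumor, normal, params)
  s2 <- apply_consequence_filter(s1, params)
  s3 <- apply_frequency_filter(s2, params)
  report <- structure(list(input_count = n0,
                           removed_by_normal = n0 - nrow(s1),
                           removed_by_consequence = nrow(s1) - nrow(s2),
                           removed_by_frequency = nrow(s2) - nrow(s3),
                           retained = s3),
                      class = "spex_filter_report")
  stopifnot(report$input_count == report$removed_by_normal +
              report$removed_by_consequence + report$removed_by_frequency +
              nrow(report$retained))
  report
}

#' @export
print.spex_filter_report <- function(x, ...) {
  cat("Somatic filter report\n")
  cat("  input variants:        ", x$input_count, "\n")
  cat("  removed (in normal):   ", x$removed_by_normal, "\n")
  cat("  removed (consequence): ", x$removed_by_consequence, "\n")
  cat("  removed (common):      ", x$removed_by_frequency, "\n")
  cat("  retained somatic:      ", nrow(x$retained), "\n")
  invisible(x)
}
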