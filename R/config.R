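#' Declare the internal standard
#'
#' The internal standard (IS) is an exogenous microorganism (or its DNA)
#' added to every sample at a known concentration before the measurement
#' pipeline. Its known actual abundance anchors the Scaled Abundance metric.
#'
#' @param taxon_id identifier of the IS taxon as it appears in the count
#'   table.
#' @param actual_abundance known concentration of the IS (e.g. copies/mcL);
#'   must be positive.
#' @param units free-text units; propagated to every Scaled Abundance and
#'   quantification result.
#' @param uncertainty optional nonnegative standard uncertainty on
#'   `actual_abundance`, kept for reporting only.
#' @return an `internal_standard_spec` object.
#' @examples
#' internal_standard_spec("L_pneumophila", 2.16e5, "copies/mcL", 3.7e3)
#' @export
internal_standard_spec <- function(taxon_id, actual_abundance,
                                   units = "copies/mcL",
                                   uncertainty = NULL) {
  if (!is.character(taxon_id) || length(taxon_id) != 1L || !nzchar(taxon_id))
    sa_config_error("internal standard 'taxon_id' must be a nonempty string")
  actual_abundance <- stopifnot_scalar_number(actual_abundance,
                                              "actual_abundance",
                                              positive = TRUE)
  if (!is.null(uncertainty)) {
    uncertainty <- stopifnot_scalar_number(uncertainty, "uncertainty")
    if (uncertainty < 0)
      sa_config_error("'uncertainty' must be nonnegative")
  }
  structure(list(taxon_id = taxon_id,
                 actual_abundance = actual_abundance,
                 units = units,
                 uncertainty = uncertainty),
            class = "internal_standard_spec")
}

#' @export
print.internal_standard_spec <- function(x, ...) {
  cat(sprintf("<internal_standard_spec> %s at %g %s%s\n", x$taxon_id,
              x$actual_abundance, x$units,
              if (is.null(x$uncertainty)) ""
              else sprintf(" (+/- %g)", x$uncertainty)))
  invisible(x)
}

#' Known actual abundances of spiked-in taxa
#'
#' Ground truth for taxa added to samples at known concentrations, used for
#' bias-ratio estimation and accuracy assessment. `sample_id = "ALL"` means
#' the spike was uniform across samples.
#'
#' @param taxon_id character vector of spiked taxa.
#' @param actual_abundance positive abundances, recycled against
#'   `taxon_id`.
#' @param sample_id sample the truth applies to, or `"ALL"` (default).
#' @param units abundance units; must match the internal standard's.
#' @return a `spike_truth` data frame.
#' @export
spike_truth <- function(taxon_id, actual_abundance, sample_id = "ALL",
                        units = "copies/mcL") {
  df <- data.frame(taxon_id = as.character(taxon_id),
                   sample_id = as.character(sample_id),
                   actual_abundance = as.numeric(actual_abundance),
                   units = units,
                   stringsAsFactors = FALSE)
  if (any(!is.finite(df$actual_abundance) | df$actual_abundance <= 0))
    sa_config_error("spike truth abundances must be positive")
  if (anyDuplicated(df[c("taxon_id", "sample_id")]))
    sa_config_error("duplicate (taxon_id, sample_id) in spike truth")
  class(df) <- c("spike_truth", "data.frame")
  df
}

#' Per-sample experimental metadata
#'
#' Encodes replicate structure (technical replicates of one sample),
#' background identity (which underlying community a sample came from), and
#' dilution fraction for dilution-series designs.
#'
#' @param sample_id sample identifiers.
#' @param replicate_group label shared by technical replicates.
#' @param background_id label of the underlying community.
#' @param dilution_fraction fraction of undiluted material in `(0, 1]`, or
#'   `NA` when not applicable.
#' @return a `sample_metadata` data frame.
#' @export
sample_metadata <- function(sample_id, replicate_group = NA_character_,
                            background_id = NA_character_,
                            dilution_fraction = NA_real_) {
  df <- data.frame(sample_id = as.character(sample_id),
                   replicate_group = as.character(replicate_group),
                   background_id = as.character(background_id),
                   dilution_fraction = as.numeric(dilution_fraction),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample_id))
    sa_config_error("duplicate sample_id in metadata")
  frac <- df$dilution_fraction
  if (any(!is.na(frac) & (frac <= 0 | frac > 1)))
    sa_config_error("dilution_fraction must lie in (0, 1]")
  class(df) <- c("sample_metadata", "data.frame")
  df
}

check_metadata_covers <- function(metadata, tab) {
  missing <- setdiff(rownames(tab), metadata$sample_id)
  if (length(missing) > 0L)
    sa_validation_error(sprintf(
      "metadata missing samples: %s", paste(missing, collapse = ", ")))
  invisible(metadata)
}

#' Read an analysis configuration (YAML or JSON)
#'
#' The configuration must contain an `internal_standard` block
#' (`taxon_id`, `actual_abundance`, optional `units`, `uncertainty`) and may
#' contain `spike_truth` (list of records with `taxon_id`,
#' `actual_abundance`, optional `sample_id`, `units`) and `metadata` (list
#' of per-sample records).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a list with elements `internal_standard`
#'   ([internal_standard_spec()]), `spike_truth` ([spike_truth()] or
#'   `NULL`), and `metadata` ([sample_metadata()] or `NULL`).
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) sa_io_error(sprintf("file not found: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw$internal_standard))
    sa_config_error(sprintf("'%s' lacks an internal_standard block", path))
  is_block <- raw$internal_standard
  if (is.null(is_block$taxon_id))
    sa_config_error("internal_standard block lacks taxon_id")
  if (is.null(is_block$actual_abundance))
    sa_config_error("internal_standard block lacks actual_abundance")
  is_spec <- internal_standard_spec(
    taxon_id = as.character(is_block$taxon_id),
    actual_abundance = is_block$actual_abundance,
    units = as.character(is_block$units %||% "copies/mcL"),
    uncertainty = is_block$uncertainty)

  truth <- NULL
  if (!is.null(raw$spike_truth)) {
    recs <- raw$spike_truth
    truth <- spike_truth(
      taxon_id = vapply(recs, function(r) as.character(r$taxon_id),
                        character(1L)),
      actual_abundance = vapply(recs, function(r)
        stopifnot_scalar_number(r$actual_abundance, "actual_abundance",
                                positive = TRUE), numeric(1L)),
      sample_id = vapply(recs, function(r)
        as.character(r$sample_id %||% "ALL"), character(1L)),
      units = vapply(recs, function(r)
        as.character(r$units %||% is_spec$units), character(1L)))
    if (!all(truth$units == is_spec$units))
      sa_config_error("spike truth units differ from internal standard units")
  }

  meta <- NULL
  if (!is.null(raw$metadata)) {
    recs <- raw$metadata
    meta <- sample_metadata(
      sample_id = vapply(recs, function(r) as.character(r$sample_id),
                         character(1L)),
      replicate_group = vapply(recs, function(r)
        as.character(r$replicate_group %||% NA_character_), character(1L)),
      background_id = vapply(recs, function(r)
        as.character(r$background_id %||% NA_character_), character(1L)),
      dilution_fraction = vapply(recs, function(r)
        as.numeric(r$dilution_fraction %||% NA_real_), numeric(1L)))
  }

  list(internal_standard = is_spec, spike_truth = truth, metadata = meta)
}
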