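# YAML serialization of scenario specifications so a simulated design can
# be archived next to its outputs and re-run exactly.

#' Write a scenario specification to YAML
#'
#' @param spec a `scenario_spec`.
#' @param path destination `.yaml` file.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(spec, path) {
  if (!inherits(spec, "scenario_spec"))
    sa_validation_error("'spec' must be a scenario_spec")
  payload <- list(
    kind = spec$kind,
    seed = spec$seed,
    params = spec$params,
    taxon_ids = colnames(spec$design),
    sample_ids = rownames(spec$design),
    units = attr(spec$design, "units", exact = TRUE),
    design = apply(unclass(spec$design), 1L, as.numeric, simplify = FALSE),
    bias = if (is.null(spec$bias)) NULL else {
      stats::setNames(as.list(as.numeric(spec$bias)), names(spec$bias))
    },
    internal_standard = if (is.null(spec$is_spec)) NULL else {
      list(taxon_id = spec$is_spec$taxon_id,
           actual_abundance = spec$is_spec$actual_abundance,
           units = spec$is_spec$units)
    },
    spike_truth = if (is.null(spec$spike_truth)) NULL else {
      lapply(seq_len(nrow(spec$spike_truth)), function(i)
        as.list(spec$spike_truth[i, ]))
    },
    metadata = if (is.null(spec$metadata)) NULL else {
      lapply(seq_len(nrow(spec$metadata)), function(i)
        as.list(spec$metadata[i, ]))
    })
  ok <- tryCatch({
    yaml::write_yaml(payload, path, precision = 15L)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    sa_io_error(sprintf("cannot write '%s': %s", path,
                        conditionMessage(ok)))
  invisible(path)
}

#' Read a scenario specification from YAML
#'
#' @param path a file written by [write_scenario()].
#' @return a `scenario_spec`.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) sa_io_error(sprintf("file not found: %s", path))
  raw <- yaml::read_yaml(path)
  for (field in c("kind", "taxon_ids", "sample_ids", "design"))
    if (is.null(raw[[field]]))
      sa_config_error(sprintf("scenario file lacks '%s'", field))
  design <- do.call(rbind, lapply(raw$design, as.numeric))
  dimnames(design) <- list(unlist(raw$sample_ids), unlist(raw$taxon_ids))
  design <- community_design(design,
                             units = raw$units %||% "copies/mcL")
  bias <- if (is.null(raw$bias)) NULL else {
    bias_model(bias = unlist(raw$bias))
  }
  is_spec <- if (is.null(raw$internal_standard)) NULL else {
    internal_standard_spec(raw$internal_standard$taxon_id,
                           raw$internal_standard$actual_abundance,
                           raw$internal_standard$units %||% "copies/mcL")
  }
  truth <- if (is.null(raw$spike_truth)) NULL else {
    spike_truth(
      taxon_id = vapply(raw$spike_truth, function(r)
        as.character(r$taxon_id), character(1L)),
      actual_abundance = vapply(raw$spike_truth, function(r)
        as.numeric(r$actual_abundance), numeric(1L)),
      sample_id = vapply(raw$spike_truth, function(r)
        as.character(r$sample_id %||% "ALL"), character(1L)),
      units = vapply(raw$spike_truth, function(r)
        as.character(r$units %||% "copies/mcL"), character(1L)))
  }
  meta <- if (is.null(raw$metadata)) NULL else {
    sample_metadata(
      sample_id = vapply(raw$metadata, function(r)
        as.character(r$sample_id), character(1L)),
      replicate_group = vapply(raw$metadata, function(r)
        as.character(r$replicate_group %||% NA_character_), character(1L)),
      background_id = vapply(raw$metadata, function(r)
        as.character(r$background_id %||% NA_character_), character(1L)),
      dilution_fraction = vapply(raw$metadata, function(r)
        as.numeric(r$dilution_fraction %||% NA_real_), numeric(1L)))
  }
  new_scenario(raw$kind, design, bias, is_spec = is_spec,
               spike_truth = truth, metadata = meta, seed = raw$seed,
               params = raw$params %||% list())
}
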