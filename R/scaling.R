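#' Relative abundance of each taxon in each sample
#'
#' Closes a count table to proportions: each value becomes its sample's
#' share of total reads. Because sequencing caps the total number of reads,
#' these proportions are the only directly observable quantity in MGS data,
#' and each one depends on the abundances of all taxa in the sample (the
#' compositionality the rest of the package corrects for).
#'
#' @param counts a [count_table()]. Proportions-mode tables pass through
#'   after validation.
#' @param pseudocount nonnegative constant added to every count before
#'   normalization (counts mode only). The default of 0 matches the plain
#'   closure; the flag exists for log-scale workflows.
#' @return a `relabund_table`: samples x taxa matrix with rows summing to 1.
#' @export
relative_abundance <- function(counts, pseudocount = 0) {
  validate_count_table(counts)
  m <- bare_matrix(counts)
  if (identical(abund_mode(counts), "proportions")) {
    if (pseudocount != 0)
      sa_validation_error("pseudocount applies to counts, not proportions")
  } else {
    if (pseudocount < 0)
      sa_validation_error("pseudocount must be nonnegative")
    m <- m + pseudocount
    tot <- rowSums(m)
    zero <- which(tot == 0)
    if (length(zero) > 0L)
      sa_validation_error(sprintf(
        "sample '%s' has zero total count; cannot normalize",
        rownames(m)[zero[1L]]))
    m <- m / tot
  }
  structure(m, abund_mode = "proportions",
            class = c("relabund_table", "count_table", "matrix", "array"))
}

as_relabund <- function(x, pseudocount = 0) {
  if (inherits(x, "relabund_table")) x else relative_abundance(x, pseudocount)
}

#' Scaled Abundance of each taxon
#'
#' The core metric: for each taxon z in each sample,
#' `SA_z = (RA_z / RA_IS) * ActualAbundance_IS`, where IS is the internal
#' standard. Dividing by the internal standard's relative abundance cancels
#' the compositional denominator shared by all taxa in a sample, so SA is
#' proportional to the taxon's actual abundance with a slope equal to the
#' (protocol-specific) ratio of the taxon's bias to the internal standard's
#' bias, independent of what else is in the sample.
#'
#' @param x a [count_table()] or `relabund_table`.
#' @param is_spec an [internal_standard_spec()]; its taxon must be present
#'   in the table.
#' @param is_zero policy for samples where the internal standard has
#'   relative abundance 0: `"error"` (default; such a sample cannot be
#'   interpreted) or `"drop"` (remove the sample with a warning).
#' @param pseudocount forwarded to [relative_abundance()] when `x` holds
#'   counts.
#' @return a `scaled_abundance` matrix (samples x taxa) in the units of
#'   `is_spec`. The internal standard column is kept and equals
#'   `is_spec$actual_abundance` exactly; its identity is stored in the
#'   `is_taxon` attribute.
#' @examples
#' m <- matrix(c(40, 10, 950), nrow = 1,
#'             dimnames = list("s1", c("taxA", "IS", "other")))
#' sa <- scaled_abundance(count_table(m), internal_standard_spec("IS", 1000))
#' sa[, "taxA"]  # 4000: (0.04 / 0.01) * 1000
#' @export
scaled_abundance <- function(x, is_spec, is_zero = c("error", "drop"),
                             pseudocount = 0) {
  is_zero <- match.arg(is_zero)
  if (!inherits(is_spec, "internal_standard_spec"))
    sa_config_error("'is_spec' must be an internal_standard_spec")
  ra <- as_relabund(x, pseudocount)
  m <- bare_matrix(ra)
  if (!is_spec$taxon_id %in% colnames(m))
    sa_config_error(sprintf(
      "internal standard taxon '%s' not found in table", is_spec$taxon_id))
  ra_is <- m[, is_spec$taxon_id]
  zero <- which(ra_is == 0)
  if (length(zero) > 0L) {
    if (is_zero == "error")
      sa_validation_error(sprintf(
        "internal standard '%s' has relative abundance 0 in sample(s): %s",
        is_spec$taxon_id,
        paste(rownames(m)[zero], collapse = ", ")))
    warning(sprintf("dropping %d sample(s) with zero internal standard: %s",
                    length(zero), paste(rownames(m)[zero], collapse = ", ")))
    m <- m[-zero, , drop = FALSE]
    ra_is <- ra_is[-zero]
    if (nrow(m) == 0L)
      sa_validation_error("all samples dropped: internal standard absent everywhere")
  }
  sa <- m / ra_is * is_spec$actual_abundance
  sa[, is_spec$taxon_id] <- is_spec$actual_abundance
  structure(sa,
            is_taxon = is_spec$taxon_id,
            is_abundance = is_spec$actual_abundance,
            units = is_spec$units,
            class = c("scaled_abundance", "matrix", "array"))
}

#' @export
print.scaled_abundance <- function(x, ...) {
  cat(sprintf(
    "<scaled_abundance> %d samples x %d taxa [%s], internal standard '%s'\n",
    nrow(x), ncol(x), attr(x, "units"), attr(x, "is_taxon")))
  print(utils::head(unclass(x)[, seq_len(min(ncol(x), 6L)), drop = FALSE]),
        ...)
  invisible(x)
}

native_taxa <- function(sa) {
  setdiff(colnames(sa), attr(sa, "is_taxon", exact = TRUE))
}

truth_for <- function(truth, taxon, samples) {
  rows <- truth[truth$taxon_id == taxon, , drop = FALSE]
  if (nrow(rows) == 0L) return(rep(NA_real_, length(samples)))
  out <- rep(NA_real_, length(samples))
  all_row <- rows$sample_id == "ALL"
  if (any(all_row)) out[] <- rows$actual_abundance[which(all_row)[1L]]
  per <- rows[!all_row, , drop = FALSE]
  if (nrow(per) > 0L) {
    idx <- match(samples, per$sample_id)
    out[!is.na(idx)] <- per$actual_abundance[idx[!is.na(idx)]]
  }
  out
}

#' Estimate taxon bias ratios from replicates with known truth
#'
#' For replicate samples in which a taxon's actual abundance is known (a
#' spike-in), each replicate yields a ratio
#' `r_i = SA_i / ActualAbundance`, an observation of the taxon's bias ratio
#' `Bias_taxon / Bias_IS`. Under a locked-down protocol this ratio is a
#' constant; the estimate is its mean over replicates with a two-sided
#' t-interval.
#'
#' @param sa a [scaled_abundance()] matrix.
#' @param truth a [spike_truth()] table with positive abundances for the
#'   taxa to estimate.
#' @param metadata optional [sample_metadata()] used with
#'   `replicate_group` to select the replicate samples.
#' @param replicate_group label selecting replicates from `metadata`; when
#'   `NULL` all samples of `sa` are used.
#' @param ci_level confidence level for the t-interval (default 0.95).
#' @param aggregate `"arithmetic"` (default): mean of the per-replicate
#'   ratios with a t-interval on the ratios. `"geometric"`: t-interval on
#'   log ratios, back-transformed.
#' @return a `bias_ratio_estimate` data frame with columns `taxon_id`,
#'   `point`, `ci_low`, `ci_high`, `n_replicates`.
#' @export
estimate_bias_ratio <- function(sa, truth, metadata = NULL,
                                replicate_group = NULL, ci_level = 0.95,
                                aggregate = c("arithmetic", "geometric")) {
  aggregate <- match.arg(aggregate)
  if (!inherits(sa, "scaled_abundance"))
    sa_validation_error("'sa' must be a scaled_abundance matrix")
  samples <- rownames(sa)
  if (!is.null(replicate_group)) {
    if (is.null(metadata))
      sa_validation_error("replicate_group given without metadata")
    keep <- metadata$sample_id[!is.na(metadata$replicate_group) &
                                 metadata$replicate_group == replicate_group]
    samples <- intersect(samples, keep)
  }
  if (length(samples) < 2L)
    sa_validation_error("bias-ratio estimation needs at least 2 replicate samples")
  taxa <- unique(truth$taxon_id)
  absent <- setdiff(taxa, colnames(sa))
  if (length(absent) > 0L)
    sa_validation_error(sprintf("taxa absent from scaled abundances: %s",
                                paste(absent, collapse = ", ")))
  est <- lapply(taxa, function(tx) {
    tr <- truth_for(truth, tx, samples)
    if (anyNA(tr))
      sa_validation_error(sprintf(
        "no truth abundance for taxon '%s' in sample(s): %s", tx,
        paste(samples[is.na(tr)], collapse = ", ")))
    r <- unclass(sa)[samples, tx] / tr
    n <- length(r)
    if (aggregate == "arithmetic") {
      point <- mean(r)
      half <- stats::qt(1 - (1 - ci_level) / 2, df = n - 1L) *
        stats::sd(r) / sqrt(n)
      lo <- point - half
      hi <- point + half
    } else {
      if (any(r <= 0))
        sa_validation_error(sprintf(
          "geometric aggregation needs positive ratios (taxon '%s')", tx))
      lr <- log(r)
      half <- stats::qt(1 - (1 - ci_level) / 2, df = n - 1L) *
        stats::sd(lr) / sqrt(n)
      point <- exp(mean(lr))
      lo <- exp(mean(lr) - half)
      hi <- exp(mean(lr) + half)
    }
    data.frame(taxon_id = tx, point = point, ci_low = lo, ci_high = hi,
               n_replicates = n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, est)
  attr(out, "ci_level") <- ci_level
  attr(out, "aggregate") <- aggregate
  class(out) <- c("bias_ratio_estimate", "data.frame")
  out
}

#' @export
print.bias_ratio_estimate <- function(x, ...) {
  cat(sprintf("<bias_ratio_estimate> %s mean, %.0f%% t-interval, n = %d\n",
              attr(x, "aggregate"), 100 * attr(x, "ci_level"),
              x$n_replicates[1L]))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Back-calculate actual abundances from Scaled Abundances
#'
#' Inverts the proportionality `SA = ActualAbundance * bias_ratio`:
#' with a bias ratio measured from spike-in replicates, each Scaled
#' Abundance converts to an absolute abundance estimate
#' `SA / bias_ratio`, in the units of the internal standard.
#'
#' @param sa a [scaled_abundance()] matrix.
#' @param bias a `bias_ratio_estimate` from [estimate_bias_ratio()].
#' @param taxa taxa to quantify; defaults to all taxa with a bias ratio.
#' @return an `abundance_estimate` data frame with columns `sample_id`,
#'   `taxon_id`, `estimate`, `ci_low`, `ci_high`, `units`. CI bounds invert
#'   the bias interval (`SA / ci_high`, `SA / ci_low`); they are `NA` when
#'   the bias interval touches or crosses zero.
#' @export
quantify_actual <- function(sa, bias, taxa = NULL) {
  if (!inherits(sa, "scaled_abundance"))
    sa_validation_error("'sa' must be a scaled_abundance matrix")
  if (is.null(taxa)) taxa <- bias$taxon_id
  missing_bias <- setdiff(taxa, bias$taxon_id)
  if (length(missing_bias) > 0L)
    sa_validation_error(sprintf("no bias ratio for taxa: %s",
                                paste(missing_bias, collapse = ", ")))
  absent <- setdiff(taxa, colnames(sa))
  if (length(absent) > 0L)
    sa_validation_error(sprintf("taxa absent from scaled abundances: %s",
                                paste(absent, collapse = ", ")))
  if (any(bias$point[bias$taxon_id %in% taxa] <= 0))
    sa_validation_error("bias ratio point estimates must be positive")
  rows <- lapply(taxa, function(tx) {
    b <- bias[bias$taxon_id == tx, , drop = FALSE][1L, ]
    v <- unclass(sa)[, tx]
    lo <- if (b$ci_high > 0) v / b$ci_high else NA_real_
    hi <- if (b$ci_low > 0) v / b$ci_low else NA_real_
    data.frame(sample_id = rownames(sa), taxon_id = tx, estimate = v / b$point,
               ci_low = lo, ci_high = hi,
               units = attr(sa, "units") %||% NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("abundance_estimate", "data.frame")
  out
}

#' Fold change in Scaled Abundance between sample pairs
#'
#' Under a common protocol the bias ratio of a taxon is the same in every
#' sample, so the ratio of its Scaled Abundances between two samples equals
#' the ratio of its actual abundances — no bias estimate needed.
#'
#' @param sa a [scaled_abundance()] matrix.
#' @param pairs a two-column matrix or data frame of
#'   (numerator_sample, denominator_sample) ids, or a list of length-2
#'   character vectors.
#' @param taxa taxa to report; defaults to all taxa in `sa` (including the
#'   internal standard, whose fold change is 1 by construction).
#' @return a `fold_change_table` data frame with columns
#'   `numerator_sample`, `denominator_sample`, `taxon_id`, `fold_change`.
#'   The fold change is `NA` (undefined) whenever either sample's Scaled
#'   Abundance is 0 — never an infinity.
#' @export
fold_change <- function(sa, pairs, taxa = NULL) {
  if (!inherits(sa, "scaled_abundance"))
    sa_validation_error("'sa' must be a scaled_abundance matrix")
  if (is.list(pairs) && !is.data.frame(pairs))
    pairs <- do.call(rbind, pairs)
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L)
    sa_validation_error("'pairs' must have two columns: numerator, denominator")
  unknown <- setdiff(unique(c(pairs)), rownames(sa))
  if (length(unknown) > 0L)
    sa_validation_error(sprintf("unknown sample id(s): %s",
                                paste(unknown, collapse = ", ")))
  if (is.null(taxa)) taxa <- colnames(sa)
  m <- unclass(sa)[, taxa, drop = FALSE]
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    num <- m[pairs[i, 1L], ]
    den <- m[pairs[i, 2L], ]
    fc <- ifelse(num > 0 & den > 0, num / den, NA_real_)
    data.frame(numerator_sample = pairs[i, 1L],
               denominator_sample = pairs[i, 2L],
               taxon_id = taxa, fold_change = fc,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("fold_change_table", "data.frame")
  out
}
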