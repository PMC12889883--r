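#' Coefficient of variation of a group of measurements
#'
#' `100 * sd / mean`, with the sample (n-1) standard deviation. Used to
#' summarize replicate precision of relative or Scaled Abundances.
#'
#' @param values numeric vector of at least two measurements.
#' @return CV in percent; `NA` when the mean is 0 (undefined).
#' @examples
#' group_cv(c(1, 2, 3))   # 50
#' group_cv(c(5, 5, 5))   # 0
#' @export
group_cv <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    sa_validation_error("group_cv needs at least 2 values")
  if (anyNA(values))
    sa_validation_error("group_cv values must not contain NA")
  m <- mean(values)
  if (m == 0) return(NA_real_)
  100 * stats::sd(values) / m
}

#' Proportionality regression with CV goodness-of-fit
#'
#' Least-squares fit of a response (Scaled or relative abundance) against a
#' known quantity (actual abundance or dilution fraction). The default fit
#' is through the origin, matching the zero-intercept proportionality the
#' Scaled Abundance metric predicts. Goodness-of-fit is summarized as a
#' coefficient of variation: `100 * residual RMSE / mean(y)`, where the
#' RMSE is the regression standard error `sqrt(RSS / (n - p))`.
#'
#' @param x predictor values (known abundances or dilution fractions).
#' @param y response values.
#' @param through_origin fit `y ~ x + 0` (default) or `y ~ x`.
#' @param ci_level confidence level for the slope interval.
#' @param taxon_id optional label carried into the result.
#' @return a `prop_fit` object: list with `slope`, `slope_ci`, `intercept`,
#'   `cv_percent`, `sigma`, `n_points`, `fitted`, `residuals`.
#' @export
fit_proportionality <- function(x, y, through_origin = TRUE,
                                ci_level = 0.95, taxon_id = NULL) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y))
    sa_validation_error("'x' and 'y' must have the same length")
  if (length(x) < 3L)
    sa_validation_error("proportionality fit needs at least 3 points")
  if (max(x) == min(x))
    sa_validation_error("degenerate predictor: all x values equal")
  fit <- if (through_origin) stats::lm(y ~ x + 0) else stats::lm(y ~ x)
  co <- stats::coef(fit)
  slope <- unname(co[["x"]])
  intercept <- if (through_origin) 0 else unname(co[[1L]])
  # suppress lm's "essentially perfect fit" warning: exact proportional
  # data is a legitimate (noise-free) input here
  ci <- suppressWarnings(stats::confint(fit, "x", level = ci_level))
  res <- stats::residuals(fit)
  sigma <- sqrt(sum(res^2) / fit$df.residual)
  my <- mean(y)
  cv <- if (my == 0) NA_real_ else 100 * sigma / my
  structure(list(taxon_id = taxon_id, slope = slope,
                 slope_ci = c(low = ci[1L], high = ci[2L]),
                 intercept = intercept, cv_percent = cv, sigma = sigma,
                 n_points = length(x), through_origin = through_origin,
                 ci_level = ci_level,
                 fitted = unname(stats::fitted(fit)),
                 residuals = unname(stats::residuals(fit))),
            class = "prop_fit")
}

#' @export
print.prop_fit <- function(x, ...) {
  cat(sprintf(
    "<prop_fit>%s slope %.6g [%.6g, %.6g]%s, CV %.4g%%, n = %d\n",
    if (is.null(x$taxon_id)) "" else paste0(" ", x$taxon_id),
    x$slope, x$slope_ci[["low"]], x$slope_ci[["high"]],
    if (x$through_origin) " (through origin)"
    else sprintf(", intercept %.6g", x$intercept),
    x$cv_percent, x$n_points))
  invisible(x)
}

fit_cv_by_taxon <- function(response, truth, min_samples = 3L,
                            through_origin = TRUE) {
  taxa <- colnames(response)
  cv <- rep(NA_real_, length(taxa))
  names(cv) <- taxa
  skipped <- character(0L)
  for (tx in taxa) {
    keep <- which(truth[, tx] > 0)
    if (length(keep) < min_samples ||
        length(unique(truth[keep, tx])) < 2L) {
      skipped <- c(skipped, tx)
      next
    }
    f <- fit_proportionality(truth[keep, tx], response[keep, tx],
                             through_origin = through_origin)
    cv[tx] <- f$cv_percent
  }
  list(cv = cv, skipped = skipped)
}

#' Internal-standard rotation analysis
#'
#' Treats each taxon of a mock-community design in turn as the internal
#' standard, computes Scaled Abundances for the remaining taxa from its
#' known actual abundance, regresses each remaining taxon's SA on its known
#' actual abundance across communities, and averages the regression CVs.
#' The analogous regressions on raw relative abundance are reported once as
#' the compositional baseline. Communities in which a candidate standard is
#' absent (truth 0 or measured relative abundance 0) are omitted for that
#' rotation.
#'
#' @param ra a `relabund_table` (or [count_table()], converted internally),
#'   samples x taxa.
#' @param truth numeric matrix of known actual abundances, same samples and
#'   taxa as `ra`; 0 marks a taxon absent from a community.
#' @param min_samples taxa observed (truth > 0) in fewer samples than this
#'   are skipped; skipped taxa are listed in the `skipped` attribute.
#' @param ci_level level of the t-interval across per-taxon CVs.
#' @param through_origin passed to [fit_proportionality()].
#' @return a `rotation_summary` data frame: one row per candidate internal
#'   standard (metric `"SA"`) plus one `"RA"` baseline row, with
#'   `mean_cv_percent`, `ci_low`, `ci_high`, `n_taxa`.
#' @export
rotate_internal_standard <- function(ra, truth, min_samples = 3L,
                                     ci_level = 0.95,
                                     through_origin = TRUE) {
  ra <- as_relabund(ra)
  m <- unclass(ra)
  if (ncol(m) < 3L)
    sa_validation_error("rotation needs at least 3 taxa")
  truth <- as.matrix(truth)
  if (!all(colnames(m) %in% colnames(truth)))
    sa_validation_error("truth must cover every taxon in the table")
  truth <- truth[rownames(m), colnames(m), drop = FALSE]

  t_ci <- function(v, level) {
    v <- v[!is.na(v)]
    n <- length(v)
    mu <- mean(v)
    if (n < 2L) return(c(mu, NA_real_, NA_real_, n))
    half <- stats::qt(1 - (1 - level) / 2, df = n - 1L) *
      stats::sd(v) / sqrt(n)
    c(mu, mu - half, mu + half, n)
  }

  skipped <- list()
  rows <- list()
  for (cand in colnames(m)) {
    keep <- which(truth[, cand] > 0 & m[, cand] > 0)
    if (length(keep) < min_samples) {
      skipped[[cand]] <- "candidate present in too few samples"
      next
    }
    others <- setdiff(colnames(m), cand)
    # per-sample IS abundance: the candidate's own known actual abundance
    sa <- m[keep, others, drop = FALSE] / m[keep, cand] * truth[keep, cand]
    res <- fit_cv_by_taxon(sa, truth[keep, others, drop = FALSE],
                           min_samples = min_samples,
                           through_origin = through_origin)
    stat <- t_ci(res$cv, ci_level)
    if (length(res$skipped) > 0L) skipped[[cand]] <- res$skipped
    rows[[cand]] <- data.frame(
      candidate_is = cand, metric = "SA", mean_cv_percent = stat[1L],
      ci_low = stat[2L], ci_high = stat[3L], n_taxa = as.integer(stat[4L]),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    sa_validation_error("no candidate internal standard had enough samples")

  base <- fit_cv_by_taxon(m, truth, min_samples = min_samples,
                          through_origin = through_origin)
  bstat <- t_ci(base$cv, ci_level)
  rows[["..ra"]] <- data.frame(
    candidate_is = NA_character_, metric = "RA",
    mean_cv_percent = bstat[1L], ci_low = bstat[2L], ci_high = bstat[3L],
    n_taxa = as.integer(bstat[4L]), stringsAsFactors = FALSE)

  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "skipped") <- skipped
  attr(out, "ci_level") <- ci_level
  class(out) <- c("rotation_summary", "data.frame")
  out
}

#' Limit-of-quantitation profile from a dilution series
#'
#' For every native taxon, regresses its Scaled Abundance through the
#' origin on the dilution fraction and pairs the regression CV with the
#' taxon's relative abundance in the undiluted sample. Plotting CV against
#' undiluted relative abundance shows how far down the abundance scale the
#' metric still tracks actual abundance within a precision bound — the
#' limit of quantitation.
#'
#' @param sa a [scaled_abundance()] matrix over the dilution-series
#'   samples.
#' @param metadata [sample_metadata()] with `dilution_fraction` set for
#'   every sample of `sa`; an undiluted sample (fraction 1) is required.
#' @param ra_reference optional `relabund_table` supplying the undiluted
#'   relative abundances; defaults to re-deriving them from `sa`.
#' @return a `loq_profile` data frame: `taxon_id`, `ra_undiluted`,
#'   `cv_percent`, `slope`, `n_points`. Taxa with zero Scaled Abundance in
#'   every sample are excluded (and reported via `message()`).
#' @export
loq_profile <- function(sa, metadata, ra_reference = NULL) {
  if (!inherits(sa, "scaled_abundance"))
    sa_validation_error("'sa' must be a scaled_abundance matrix")
  check_metadata_covers(metadata, sa)
  frac <- metadata$dilution_fraction[match(rownames(sa),
                                           metadata$sample_id)]
  if (anyNA(frac))
    sa_validation_error("dilution_fraction must be present for all samples")
  if (length(unique(frac)) < 3L)
    sa_validation_error("dilution series needs at least 3 dilution levels")
  undil <- which(frac == 1)
  if (length(undil) == 0L)
    sa_validation_error("no undiluted sample (dilution_fraction = 1) found")

  taxa <- native_taxa(sa)
  m <- unclass(sa)
  if (is.null(ra_reference)) {
    ra_ref <- m[, colnames(sa), drop = FALSE] /
      rowSums(m[, colnames(sa), drop = FALSE])
  } else {
    ra_ref <- unclass(ra_reference)[rownames(sa), colnames(sa),
                                    drop = FALSE]
  }

  dropped <- character(0L)
  rows <- list()
  for (tx in taxa) {
    v <- m[, tx]
    if (all(v == 0)) {
      dropped <- c(dropped, tx)
      next
    }
    f <- fit_proportionality(frac, v, through_origin = TRUE)
    rows[[tx]] <- data.frame(
      taxon_id = tx,
      ra_undiluted = mean(ra_ref[undil, tx]),
      cv_percent = f$cv_percent, slope = f$slope,
      n_points = f$n_points, stringsAsFactors = FALSE)
  }
  if (length(dropped) > 0L)
    message("excluded taxa absent from all samples: ",
            paste(dropped, collapse = ", "))
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "excluded") <- dropped
  class(out) <- c("loq_profile", "data.frame")
  out
}

#' @export
plot.loq_profile <- function(x, cv_bound = 25, ...) {
  graphics::plot(x$ra_undiluted, x$cv_percent, log = "x",
                 xlab = "relative abundance (undiluted sample)",
                 ylab = "regression CV (%)", ...)
  graphics::abline(h = cv_bound, col = "red", lty = 2)
  invisible(x)
}
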