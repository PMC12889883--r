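with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Community design: true taxon abundances per sample
#'
#' @param abundances numeric matrix, samples x taxa, of actual abundances
#'   (nonnegative; each sample needs at least one positive taxon).
#' @param units abundance units (copies/mcL by convention; the simulator
#'   never converts units).
#' @return a `community_design` object.
#' @export
community_design <- function(abundances, units = "copies/mcL") {
  m <- as.matrix(abundances)
  storage.mode(m) <- "double"
  if (is.null(rownames(m)))
    rownames(m) <- sprintf("sample_%02d", seq_len(nrow(m)))
  if (is.null(colnames(m)))
    sa_validation_error("community design needs taxon names")
  if (any(!is.finite(m) | m < 0))
    sa_validation_error("actual abundances must be finite and nonnegative")
  zero <- which(rowSums(m) == 0)
  if (length(zero) > 0L)
    sa_validation_error(sprintf(
      "sample '%s' has no taxon with positive abundance",
      rownames(m)[zero[1L]]))
  structure(m, units = units,
            class = c("community_design", "matrix", "array"))
}

#' Per-taxon measurement bias factors
#'
#' Each taxon carries a single aggregate multiplicative bias summarizing
#' every step of a locked-down measurement pipeline (extraction, library
#' prep, sequencing, bioinformatics). Biases are assumed constant across
#' samples analyzed with the same protocol.
#'
#' @param taxon_ids taxa to generate biases for (ignored when `bias` is
#'   supplied).
#' @param sigma sdlog of the lognormal generation law (meanlog 0). The
#'   default 1 spans roughly an order of magnitude either way, the regime
#'   in which biases vary substantially and unpredictably between taxa.
#' @param bias optional named vector of fixed positive bias factors,
#'   bypassing generation.
#' @param seed RNG seed for the lognormal draw.
#' @return a named numeric vector of class `bias_model`.
#' @export
bias_model <- function(taxon_ids = NULL, sigma = 1, bias = NULL,
                       seed = NULL) {
  if (is.null(bias)) {
    if (is.null(taxon_ids))
      sa_validation_error("either 'taxon_ids' or 'bias' must be given")
    bias <- with_seed(seed,
                      stats::rlnorm(length(taxon_ids), meanlog = 0,
                                    sdlog = sigma))
    names(bias) <- taxon_ids
  }
  bias <- unlist(bias)
  if (is.null(names(bias)) || any(!nzchar(names(bias))))
    sa_validation_error("bias factors must be named by taxon")
  if (any(!is.finite(bias) | bias <= 0))
    sa_validation_error("bias factors must be positive and finite")
  structure(as.numeric(stats::setNames(bias, names(bias))),
            class = "bias_model", names = names(bias))
}

#' Simulate MGS counts from the biased-multinomial measurement model
#'
#' The measurement model: each taxon's analytical response is its actual
#' abundance times its bias factor; sequencing closes these responses to
#' proportions (expected relative abundances) and draws a fixed total
#' number of reads, so the expected relative abundance of taxon z is
#' `A_z B_z / sum(A B)`.
#'
#' @param design a [community_design()].
#' @param bias a [bias_model()] covering every taxon of `design`, in any
#'   order.
#' @param depth reads per sample (positive integer).
#' @param noise `"multinomial"`: counts drawn from
#'   `Multinomial(depth, expected RA)` per sample; `"expectation"`:
#'   noise-free counts `depth * expected RA` (generally non-integer),
#'   useful for algebraic checks.
#' @param depth_poisson draw each sample's depth from `Poisson(depth)`
#'   instead of fixing it.
#' @param seed RNG seed (required in multinomial mode for
#'   reproducibility).
#' @return a `sim_result` list: `counts` (a [count_table()]) and `truth`
#'   (list with `actual`, `bias`, `expected_ra`, `depth`, `units`).
#' @examples
#' d <- community_design(matrix(c(1, 3), 1, dimnames = list("s", c("a", "b"))))
#' b <- bias_model(bias = c(a = 2, b = 1))
#' simulate_counts(d, b, depth = 10, noise = "expectation")$truth$expected_ra
#' @export
simulate_counts <- function(design, bias, depth = 1e5,
                            noise = c("multinomial", "expectation"),
                            depth_poisson = FALSE, seed = NULL) {
  noise <- match.arg(noise)
  if (!inherits(design, "community_design"))
    design <- community_design(design)
  taxa <- colnames(design)
  if (!all(taxa %in% names(bias)))
    sa_validation_error(sprintf(
      "bias model missing taxa: %s",
      paste(setdiff(taxa, names(bias)), collapse = ", ")))
  b <- as.numeric(bias)[match(taxa, names(bias))]
  depth <- stopifnot_scalar_number(depth, "depth", positive = TRUE)

  resp <- sweep(bare_matrix(design), 2L, b, `*`)
  tot <- rowSums(resp)
  if (any(tot == 0))
    sa_validation_error("zero total analytical response in a sample")
  expected_ra <- resp / tot

  with_seed(seed, {
    if (noise == "expectation") {
      depths <- rep(depth, nrow(design))
      counts <- depth * expected_ra
    } else {
      depths <- if (depth_poisson) {
        pmax(1L, stats::rpois(nrow(design), depth))
      } else rep(as.integer(round(depth)), nrow(design))
      counts <- t(vapply(seq_len(nrow(design)), function(i) {
        as.numeric(stats::rmultinom(1L, size = depths[i],
                                    prob = expected_ra[i, ]))
      }, numeric(ncol(design))))
      dimnames(counts) <- dimnames(design)
    }
    structure(list(
      counts = count_table(counts, mode = "counts"),
      truth = list(actual = bare_matrix(design),
                   bias = stats::setNames(b, taxa),
                   expected_ra = expected_ra, depth = depths,
                   units = attr(design, "units", exact = TRUE))),
      class = "sim_result")
  })
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %d samples x %d taxa, depth ~ %g\n",
              nrow(x$counts), ncol(x$counts), mean(x$truth$depth)))
  invisible(x)
}

new_scenario <- function(kind, design, bias, is_spec = NULL,
                         spike_truth = NULL, metadata = NULL, seed = NULL,
                         params = list()) {
  structure(list(kind = kind, design = design, bias = bias,
                 is_spec = is_spec, spike_truth = spike_truth,
                 metadata = metadata, seed = seed, params = params),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario_spec> kind = %s, %d samples x %d taxa, seed = %s\n",
              x$kind, nrow(x$design), ncol(x$design),
              if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

#' Mock-community scenario
#'
#' Emulates a bench design in which many distinct mock communities are
#' assembled from a panel of strains, each member strain added as a
#' specified dilution of its overnight stock; those specified dilutions are
#' the known actual abundances.
#'
#' @param n_communities number of communities (default 80).
#' @param taxon_ids strain panel (default 7 strains).
#' @param dilution_levels stock dilutions to draw member abundances from
#'   (default 1/2, 1/3, 1/7).
#' @param subset_rule `"random"`: each community holds a uniformly drawn
#'   subset of at least `min_subset` strains; `"all"`: every community
#'   holds the full panel.
#' @param min_subset minimum community size (must be at least 2).
#' @param seed RNG seed for the design draw.
#' @return a `scenario_spec` whose design holds stock-dilution abundances
#'   (dimensionless) with 0 for non-members.
#' @export
scenario_mock_community <- function(n_communities = 80,
                                    taxon_ids = sprintf("strain_%d", 1:7),
                                    dilution_levels = c(1/2, 1/3, 1/7),
                                    subset_rule = c("random", "all"),
                                    min_subset = 2L, seed = NULL) {
  subset_rule <- match.arg(subset_rule)
  if (min_subset < 2L)
    sa_validation_error("community subsets need at least 2 taxa")
  if (min_subset > length(taxon_ids))
    sa_validation_error("min_subset exceeds the taxon panel size")
  if (any(dilution_levels <= 0))
    sa_validation_error("dilution levels must be positive")
  k <- length(taxon_ids)
  design <- with_seed(seed, {
    m <- matrix(0, n_communities, k,
                dimnames = list(sprintf("community_%02d",
                                        seq_len(n_communities)),
                                taxon_ids))
    for (i in seq_len(n_communities)) {
      members <- if (subset_rule == "all") seq_len(k) else {
        size <- sample(min_subset:k, 1L)
        sample.int(k, size)
      }
      m[i, members] <- sample(dilution_levels, length(members),
                              replace = TRUE)
    }
    m
  })
  new_scenario("mock_community",
               community_design(design, units = "stock dilution"),
               bias = NULL, seed = seed,
               params = list(dilution_levels = dilution_levels,
                             subset_rule = subset_rule))
}

default_spikes <- c(A_baumanii = 4.8e4, V_furnissii = 9.6e3,
                    N_meningitidis = 5.4e3, A_hydrophila = 6.2e2)

#' Spike-in across diverse backgrounds scenario
#'
#' Emulates the composition-independence experiment: several distinct
#' native communities ("backgrounds", e.g. stool from different donors),
#' each measured in technical replicates, all receiving the same four
#' spike-in taxa at fixed concentrations spanning two orders of magnitude
#' plus the internal standard.
#'
#' @param n_backgrounds number of distinct background communities.
#' @param n_replicates technical replicates per background (identical
#'   actual-abundance vectors).
#' @param spike_abundances named positive vector of spike concentrations
#'   (defaults: 4.8e4, 9.6e3, 5.4e3, 6.2e2 copies/mcL).
#' @param is_abundance internal-standard concentration (default 2.16e5
#'   copies/mcL).
#' @param is_taxon internal-standard taxon id.
#' @param n_native native taxa per background.
#' @param native_total total native abundance per background (copies/mcL).
#'   The default 1e6 puts the smallest default spike near relative
#'   abundance 5e-4.
#' @param alpha symmetric Dirichlet concentration for background
#'   compositions; values below 1 give the uneven compositions typical of
#'   stool.
#' @param bias_sigma sdlog of the lognormal bias draw over all taxa.
#' @param seed RNG seed (backgrounds and biases).
#' @return a `scenario_spec` with design, biases, internal-standard spec,
#'   spike truth, and replicate/background metadata.
#' @export
scenario_spikein_backgrounds <- function(n_backgrounds = 5L,
                                         n_replicates = 3L,
                                         spike_abundances = default_spikes,
                                         is_abundance = 2.16e5,
                                         is_taxon = "L_pneumophila",
                                         n_native = 50L,
                                         native_total = 1e6,
                                         alpha = 0.5, bias_sigma = 1,
                                         seed = NULL) {
  if (any(!is.finite(spike_abundances) | spike_abundances <= 0))
    sa_validation_error("spike abundances must be positive")
  is_abundance <- stopifnot_scalar_number(is_abundance, "is_abundance",
                                          positive = TRUE)
  if (is.null(names(spike_abundances)))
    names(spike_abundances) <- sprintf("spike_%d",
                                       seq_along(spike_abundances))
  native_ids <- sprintf("native_%02d", seq_len(n_native))
  taxa <- c(native_ids, names(spike_abundances), is_taxon)

  out <- with_seed(seed, {
    comp <- matrix(stats::rgamma(n_backgrounds * n_native, shape = alpha),
                   n_backgrounds, n_native)
    comp <- comp / rowSums(comp) * native_total
    bias <- bias_model(taxa, sigma = bias_sigma)
    list(comp = comp, bias = bias)
  })

  design <- matrix(0, n_backgrounds * n_replicates, length(taxa),
                   dimnames = list(NULL, taxa))
  sample_ids <- character(nrow(design))
  bg_ids <- character(nrow(design))
  row <- 0L
  for (bgi in seq_len(n_backgrounds)) {
    for (rep in seq_len(n_replicates)) {
      row <- row + 1L
      design[row, native_ids] <- out$comp[bgi, ]
      design[row, names(spike_abundances)] <- spike_abundances
      design[row, is_taxon] <- is_abundance
      sample_ids[row] <- sprintf("bg%d_rep%d", bgi, rep)
      bg_ids[row] <- sprintf("bg%d", bgi)
    }
  }
  rownames(design) <- sample_ids
  meta <- sample_metadata(sample_id = sample_ids, replicate_group = bg_ids,
                          background_id = bg_ids)
  new_scenario("spikein_backgrounds", community_design(design),
               bias = out$bias,
               is_spec = internal_standard_spec(is_taxon, is_abundance),
               spike_truth = spike_truth(names(spike_abundances),
                                         spike_abundances),
               metadata = meta, seed = seed,
               params = list(n_backgrounds = n_backgrounds,
                             n_replicates = n_replicates,
                             native_total = native_total, alpha = alpha,
                             bias_sigma = bias_sigma))
}

#' Dilution-series scenario
#'
#' Emulates the proportionality experiment: a single community is diluted
#' into buffer at several fractions of full strength; the dilution series
#' is then treated as independent samples into which the internal standard
#' is added at a constant concentration after dilution. The dilution
#' fraction serves as the known surrogate for every native taxon's actual
#' abundance.
#'
#' @param fractions dilution fractions in `(0, 1]` (default 0.2–1.0 in
#'   steps of 0.2).
#' @param base_community optional named vector of undiluted native
#'   abundances; by default `n_native` lognormal abundances
#'   (sdlog `abundance_sigma`) scaled to `native_total`.
#' @param n_native,native_total,bias_sigma as in
#'   [scenario_spikein_backgrounds()].
#' @param abundance_sigma sdlog of the lognormal abundance draw for the
#'   default base community (default 2, spanning several orders of
#'   magnitude as native gut taxa do).
#' @param is_abundance,is_taxon internal standard, added post-dilution at
#'   constant concentration.
#' @param loq_target_ra if set, append a sentinel taxon
#'   (`"loq_sentinel"`, bias 1) whose expected relative abundance in the
#'   undiluted sample equals this value — used to probe the limit of
#'   quantitation.
#' @param seed RNG seed (community and biases).
#' @return a `scenario_spec` with dilution metadata.
#' @export
scenario_dilution_series <- function(fractions = seq(0.2, 1, by = 0.2),
                                     base_community = NULL,
                                     n_native = 50L, native_total = 1e6,
                                     abundance_sigma = 2,
                                     is_abundance = 2.16e5,
                                     is_taxon = "L_pneumophila",
                                     bias_sigma = 1,
                                     loq_target_ra = NULL, seed = NULL) {
  if (any(!is.finite(fractions) | fractions <= 0 | fractions > 1))
    sa_validation_error("dilution fractions must lie in (0, 1]")
  is_abundance <- stopifnot_scalar_number(is_abundance, "is_abundance",
                                          positive = TRUE)
  out <- with_seed(seed, {
    base <- base_community
    if (is.null(base)) {
      base <- stats::rlnorm(n_native, meanlog = 0, sdlog = abundance_sigma)
      base <- base / sum(base) * native_total
      names(base) <- sprintf("native_%02d", seq_len(n_native))
    }
    bias <- bias_model(c(names(base), is_taxon), sigma = bias_sigma)
    list(base = base, bias = bias)
  })
  base <- out$base
  bias <- out$bias
  if (any(base <= 0))
    sa_validation_error("base community abundances must be positive")

  if (!is.null(loq_target_ra)) {
    r <- stopifnot_scalar_number(loq_target_ra, "loq_target_ra",
                                 positive = TRUE)
    if (r >= 1)
      sa_validation_error("loq_target_ra must be below 1")
    # undiluted-sample analytical response of everything else
    s_other <- sum(base * as.numeric(bias)[match(names(base), names(bias))]) +
      is_abundance * as.numeric(bias)[match(is_taxon, names(bias))]
    sentinel <- r / (1 - r) * s_other   # bias 1 => response == abundance
    base <- c(base, loq_sentinel = sentinel)
    bv <- as.numeric(bias)
    names(bv) <- names(bias)
    bias <- bias_model(bias = c(bv, loq_sentinel = 1))
  }

  sample_ids <- sprintf("dil_%03d", round(100 * fractions))
  design <- t(vapply(fractions, function(f) c(base * f, is_abundance),
                     numeric(length(base) + 1L)))
  colnames(design) <- c(names(base), is_taxon)
  rownames(design) <- sample_ids
  meta <- sample_metadata(sample_id = sample_ids,
                          replicate_group = sample_ids,
                          background_id = "base",
                          dilution_fraction = fractions)
  new_scenario("dilution_series", community_design(design), bias = bias,
               is_spec = internal_standard_spec(is_taxon, is_abundance),
               metadata = meta, seed = seed,
               params = list(fractions = fractions,
                             native_total = native_total,
                             abundance_sigma = abundance_sigma,
                             bias_sigma = bias_sigma,
                             loq_target_ra = loq_target_ra))
}

#' Run the sequencing model over a scenario
#'
#' @param spec a `scenario_spec` from one of the scenario builders. Mock
#'   community scenarios carry no bias model by default; supply one via
#'   `bias` (or it is drawn lognormally with `bias_sigma`, seeded by
#'   `seed`).
#' @param depth,noise,depth_poisson,seed passed to [simulate_counts()].
#' @param bias optional [bias_model()] overriding the scenario's.
#' @param bias_sigma sdlog used when a bias model must be drawn.
#' @return a `sim_result` with the scenario's `is_spec`, `spike_truth` and
#'   `metadata` attached to its `truth` bundle.
#' @export
simulate_scenario <- function(spec, depth = 1e5,
                              noise = c("multinomial", "expectation"),
                              depth_poisson = FALSE, seed = NULL,
                              bias = NULL, bias_sigma = 1) {
  if (!inherits(spec, "scenario_spec"))
    sa_validation_error("'spec' must be a scenario_spec")
  noise <- match.arg(noise)
  b <- bias %||% spec$bias %||%
    bias_model(colnames(spec$design), sigma = bias_sigma, seed = seed)
  res <- simulate_counts(spec$design, b, depth = depth, noise = noise,
                         depth_poisson = depth_poisson, seed = seed)
  res$truth$is_spec <- spec$is_spec
  res$truth$spike_truth <- spec$spike_truth
  res$truth$metadata <- spec$metadata
  res$truth$kind <- spec$kind
  res
}
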