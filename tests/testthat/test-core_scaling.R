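mk_table <- function(values, samples = NULL, taxa = NULL,
                     mode = "counts") {
  m <- as.matrix(values)
  rownames(m) <- samples %||% sprintf("s%d", seq_len(nrow(m)))
  colnames(m) <- taxa %||% sprintf("t%d", seq_len(ncol(m)))
  count_table(m, mode = mode)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("relative abundance closes counts to proportions", {
  tab <- mk_table(rbind(c(30, 70), c(25, 25)))
  ra <- relative_abundance(tab)
  expect_equal(unname(unclass(ra)[1, ]), c(0.3, 0.7))
  expect_equal(unname(unclass(ra)[2, ]), c(0.5, 0.5))

  eq <- mk_table(matrix(13, 1, 4))
  expect_equal(unname(unclass(relative_abundance(eq))[1, ]), rep(0.25, 4))

  solo <- mk_table(rbind(c(42, 0)))
  expect_equal(unname(unclass(relative_abundance(solo))[1, ]), c(1, 0))

  zero <- mk_table(rbind(c(1, 1), c(0, 0)))
  expect_error(relative_abundance(zero), "s2",
               class = "sa_validation_error")

  prop <- mk_table(rbind(c(0.2, 0.8)), mode = "proportions")
  expect_identical(unclass(relative_abundance(prop)), unclass(prop))
})

test_that("scaled abundance implements the internal-standard ratio", {
  is_spec <- internal_standard_spec("IS", 2.16e5, "copies/mcL")
  tab <- mk_table(rbind(c(100, 100, 800)), taxa = c("taxA", "IS", "bg"))
  sa <- scaled_abundance(tab, is_spec)
  # equal relative abundances: SA equals the IS actual abundance
  expect_equal(unclass(sa)[1, "taxA"], 2.16e5)
  expect_equal(unclass(sa)[1, "IS"], 2.16e5)
  expect_equal(attr(sa, "units"), "copies/mcL")

  tab2 <- mk_table(rbind(c(0.04, 0.01, 0.95)),
                   taxa = c("taxA", "IS", "bg"), mode = "proportions")
  sa2 <- scaled_abundance(tab2, internal_standard_spec("IS", 1000))
  expect_equal(unclass(sa2)[1, "taxA"], 4000)

  zero <- mk_table(rbind(c(0, 10, 90)), taxa = c("taxA", "IS", "bg"))
  expect_equal(unclass(scaled_abundance(
    zero, internal_standard_spec("IS", 1000)))[1, "taxA"], 0)
})

test_that("missing or vanished internal standard follows policy", {
  is_spec <- internal_standard_spec("IS", 1000)
  tab <- mk_table(rbind(c(1, 2)), taxa = c("a", "b"))
  expect_error(scaled_abundance(tab, is_spec), "IS",
               class = "sa_config_error")

  gone <- mk_table(rbind(c(5, 0, 5), c(5, 5, 0)),
                   taxa = c("a", "IS", "b"))
  expect_error(scaled_abundance(gone, is_spec), "s1",
               class = "sa_validation_error")
  expect_warning(sa <- scaled_abundance(gone, is_spec, is_zero = "drop"),
                 "dropping")
  expect_equal(rownames(sa), "s2")
})

test_that("bias ratios use the mean of per-replicate ratios with a t-CI", {
  is_spec <- internal_standard_spec("IS", 1000)
  # three replicates whose taxA scaled abundances are 200, 220, 180
  counts <- rbind(c(200, 100, 700), c(220, 100, 680), c(180, 100, 720))
  tab <- mk_table(counts * 10, taxa = c("taxA", "IS", "bg"))
  sa <- scaled_abundance(tab, internal_standard_spec("IS", 1000))
  expect_equal(unname(unclass(sa)[, "taxA"]), c(2000, 2200, 1800))

  truth <- spike_truth("taxA", 1000)
  br <- estimate_bias_ratio(sa, truth)
  expect_equal(br$point, 2.0)
  # frozen t-interval: mean 2, sd 0.2, half-width 4.302653 * 0.2 / sqrt(3)
  expect_equal(br$ci_low, 1.5031725, tolerance = 1e-6)
  expect_equal(br$ci_high, 2.4968275, tolerance = 1e-6)
  expect_equal(br$n_replicates, 3L)

  # exact replicates of the truth: point 1, zero-width interval
  exact <- mk_table(rbind(c(10, 10, 80), c(20, 20, 160)),
                    taxa = c("taxA", "IS", "bg"))
  sae <- scaled_abundance(exact, is_spec)
  bre <- estimate_bias_ratio(sae, spike_truth("taxA", 1000))
  expect_equal(bre$point, 1.0)
  expect_equal(bre$ci_low, 1.0)
  expect_equal(bre$ci_high, 1.0)

  # geometric aggregation returns the geometric mean
  brg <- estimate_bias_ratio(sa, truth, aggregate = "geometric")
  expect_equal(brg$point, prod(c(2, 2.2, 1.8))^(1 / 3))

  one <- scaled_abundance(mk_table(rbind(c(10, 10, 80)),
                                   taxa = c("taxA", "IS", "bg")), is_spec)
  expect_error(estimate_bias_ratio(one, truth), "2 replicate",
               class = "sa_validation_error")
  expect_error(estimate_bias_ratio(sa, spike_truth("nope", 5)), "nope",
               class = "sa_validation_error")
})

test_that("replicate groups select the estimation samples", {
  is_spec <- internal_standard_spec("IS", 1000)
  tab <- mk_table(rbind(c(100, 100, 800), c(120, 100, 780),
                        c(500, 100, 400)),
                  taxa = c("taxA", "IS", "bg"))
  sa <- scaled_abundance(tab, is_spec)
  meta <- sample_metadata(c("s1", "s2", "s3"),
                          replicate_group = c("g1", "g1", "g2"))
  br <- estimate_bias_ratio(sa, spike_truth("taxA", 1000),
                            metadata = meta, replicate_group = "g1")
  expect_equal(br$n_replicates, 2L)
  expect_equal(br$point, mean(c(1.0, 1.2)))
})

test_that("quantification inverts the bias proportionality", {
  is_spec <- internal_standard_spec("IS", 1000)
  tab <- mk_table(rbind(c(40, 10, 950)), taxa = c("taxA", "IS", "bg"))
  sa <- scaled_abundance(tab, is_spec)
  bias <- data.frame(taxon_id = "taxA", point = 2, ci_low = 1.6,
                     ci_high = 2.5, n_replicates = 3L)
  est <- quantify_actual(sa, bias)
  expect_equal(est$estimate, 2000)
  expect_equal(est$ci_low, 4000 / 2.5)
  expect_equal(est$ci_high, 4000 / 1.6)

  unit <- data.frame(taxon_id = "taxA", point = 1, ci_low = 1,
                     ci_high = 1, n_replicates = 3L)
  expect_equal(quantify_actual(sa, unit)$estimate,
               unname(unclass(sa)[1, "taxA"]))
  expect_error(quantify_actual(sa, bias, taxa = c("taxA", "bg")), "bg",
               class = "sa_validation_error")
})

test_that("noise-free simulation round-trips abundances through the bias", {
  set.seed(31)
  for (rep in 1:5) {
    k <- sample(4:8, 1)
    taxa <- c(sprintf("t%d", seq_len(k)), "IS")
    actual <- matrix(runif(3 * (k + 1), 10, 1e4), 3, k + 1,
                     dimnames = list(c("a", "b", "c"), taxa))
    bias <- bias_model(bias = setNames(rlnorm(k + 1), taxa))
    is_spec <- internal_standard_spec("IS", actual[1, "IS"])
    # constant IS abundance across samples for a valid spec
    actual[, "IS"] <- actual[1, "IS"]
    res <- simulate_counts(community_design(actual), bias, depth = 1e4,
                           noise = "expectation")
    sa <- scaled_abundance(res$counts, is_spec)
    ratio <- as.numeric(bias)[match(taxa, names(bias))] /
      as.numeric(bias)[match("IS", names(bias))]
    # Scaled Abundance = actual abundance x bias ratio, taxon by taxon
    expect_equal(unclass(sa)[, seq_len(k)],
                 sweep(actual[, seq_len(k)], 2, ratio[seq_len(k)], `*`),
                 tolerance = 1e-9)
    # quantification with the true bias ratios recovers the design exactly
    bias_df <- data.frame(taxon_id = sprintf("t%d", seq_len(k)),
                          point = ratio[seq_len(k)],
                          ci_low = ratio[seq_len(k)],
                          ci_high = ratio[seq_len(k)], n_replicates = 2L)
    est <- quantify_actual(sa, bias_df)
    for (j in seq_len(k))
      expect_equal(est$estimate[est$taxon_id == sprintf("t%d", j)],
                   unname(actual[, sprintf("t%d", j)]), tolerance = 1e-9)
  }
})

test_that("fold changes report actual-abundance ratios and mark zeros", {
  is_spec <- internal_standard_spec("IS", 1000)
  tab <- mk_table(rbind(c(10, 10, 80), c(20, 10, 70)),
                  taxa = c("taxA", "IS", "bg"))
  sa <- scaled_abundance(tab, is_spec)
  self <- fold_change(sa, list(c("s1", "s1")))
  expect_true(all(self$fold_change == 1))

  # expectation-mode doubling of one taxon: fold change exactly 2
  actual <- rbind(s1 = c(taxA = 100, IS = 50, bg = 900),
                  s2 = c(taxA = 200, IS = 50, bg = 900))
  bias <- bias_model(bias = c(taxA = 3.3, IS = 0.7, bg = 1.9))
  res <- simulate_counts(community_design(actual), bias, depth = 1e5,
                         noise = "expectation")
  saf <- scaled_abundance(res$counts, internal_standard_spec("IS", 50))
  fc <- fold_change(saf, list(c("s2", "s1")), taxa = "taxA")
  expect_equal(fc$fold_change, 2, tolerance = 1e-12)

  zero <- mk_table(rbind(c(0, 10, 90), c(5, 10, 85)),
                   taxa = c("taxA", "IS", "bg"))
  saz <- scaled_abundance(zero, is_spec)
  fcz <- fold_change(saz, list(c("s2", "s1")))
  expect_true(is.na(fcz$fold_change[fcz$taxon_id == "taxA"]))
  expect_error(fold_change(sa, list(c("s1", "nope"))), "nope",
               class = "sa_validation_error")
})

test_that("scaled abundance is invariant to background composition", {
  set.seed(32)
  is_spec <- internal_standard_spec("IS", 5e4)
  a_z <- 1234        # fixed taxon of interest
  bias <- bias_model(bias = c(taxA = 2.5, IS = 0.8, bg1 = 1.1, bg2 = 4,
                              bg3 = 0.3))
  sas <- replicate(40, {
    bg <- runif(3, 1, 1e6)   # arbitrary background abundances
    actual <- matrix(c(a_z, 5e4, bg), 1,
                     dimnames = list("s", c("taxA", "IS", "bg1", "bg2",
                                            "bg3")))
    res <- simulate_counts(community_design(actual), bias, depth = 1e4,
                           noise = "expectation")
    unclass(scaled_abundance(res$counts, is_spec))[1, "taxA"]
  })
  expect_equal(max(abs(sas / sas[1] - 1)), 0, tolerance = 1e-9)
  expect_equal(sas[1], a_z * 2.5 / 0.8, tolerance = 1e-9)
})

test_that("scaled abundance is scale-free in counts", {
  is_spec <- internal_standard_spec("IS", 1000)
  tab <- mk_table(rbind(c(13, 7, 80), c(5, 11, 33)),
                  taxa = c("taxA", "IS", "bg"))
  sa1 <- unclass(scaled_abundance(tab, is_spec))
  for (c_mult in c(3, 0.5, 1e6)) {
    tab2 <- mk_table(unclass(tab) * c_mult, taxa = colnames(tab))
    expect_equal(unclass(scaled_abundance(tab2, is_spec)), sa1,
                 tolerance = 1e-12)
  }
})

test_that("pseudocount is off by default and only shifts zeros when on", {
  is_spec <- internal_standard_spec("IS", 1000)
  tab <- mk_table(rbind(c(0, 10, 90)), taxa = c("taxA", "IS", "bg"))
  sa0 <- scaled_abundance(tab, is_spec)
  expect_equal(unclass(sa0)[1, "taxA"], 0)
  sa1 <- scaled_abundance(tab, is_spec, pseudocount = 0.5)
  expect_gt(unclass(sa1)[1, "taxA"], 0)
  expect_error(relative_abundance(tab, pseudocount = -1),
               class = "sa_validation_error")
})
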