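# Brute-force reference implementations, kept independent of the package's
# code paths (no lm, no package helpers): explicit sums and closed forms.

oracle_cv <- function(v) {
  n <- length(v)
  m <- sum(v) / n
  if (m == 0) return(NA_real_)
  100 * sqrt(sum((v - m)^2) / (n - 1)) / m
}

oracle_origin_fit <- function(x, y, level = 0.95) {
  n <- length(x)
  slope <- sum(x * y) / sum(x * x)
  r <- y - slope * x
  sigma <- sqrt(sum(r^2) / (n - 1))
  se <- sigma / sqrt(sum(x * x))
  tq <- qt(1 - (1 - level) / 2, df = n - 1)
  list(slope = slope, ci = c(slope - tq * se, slope + tq * se),
       sigma = sigma,
       cv = if (mean(y) == 0) NA_real_ else 100 * sigma / mean(y))
}

# expected relative abundance of the biased-multinomial model, by loops
oracle_expected_ra <- function(actual, bias) {
  out <- actual
  for (i in seq_len(nrow(actual))) {
    resp <- numeric(ncol(actual))
    for (j in seq_len(ncol(actual))) resp[j] <- actual[i, j] * bias[j]
    out[i, ] <- resp / sum(resp)
  }
  out
}

# full rotation analysis by brute force: mean per-taxon through-origin
# regression CV for each candidate internal standard
oracle_rotation_means <- function(ra, truth, min_samples = 3L) {
  taxa <- colnames(ra)
  means <- numeric(0)
  for (cand in taxa) {
    keep <- which(truth[, cand] > 0 & ra[, cand] > 0)
    if (length(keep) < min_samples) next
    cvs <- numeric(0)
    for (tx in setdiff(taxa, cand)) {
      pts <- keep[truth[keep, tx] > 0]
      if (length(pts) < min_samples ||
          length(unique(truth[pts, tx])) < 2L) next
      sa <- ra[pts, tx] / ra[pts, cand] * truth[pts, cand]
      cvs <- c(cvs, oracle_origin_fit(truth[pts, tx], sa)$cv)
    }
    means[cand] <- mean(cvs)
  }
  means
}

rand_count_table <- function(n_samples = 3L, n_taxa = 4L,
                             mode = "counts") {
  m <- matrix(rpois(n_samples * n_taxa, lambda = 50) + 1, n_samples,
              n_taxa,
              dimnames = list(sprintf("s%d", seq_len(n_samples)),
                              sprintf("t%d", seq_len(n_taxa))))
  if (mode == "proportions") m <- m / rowSums(m)
  count_table(m, mode = mode)
}
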