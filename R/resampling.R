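#' Pooled haplotype frequency with proportion bootstrap
#'
#' Uncorrected estimate: the SB (and complementary Sb) share of confirmed
#' haploid males of one life stage, pooling all colonies. The 95% CI is the
#' 2.5/97.5 percentile interval of the bootstrap distribution of the
#' proportion, resampling individuals with replacement (default 5000
#' replicates).
#'
#' @param calls A `ploidy_calls` data.frame (see [classify_table()]).
#' @param stage `"adult"` or `"pupa"`.
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed.
#' @param conf Confidence level.
#' @return A `freq_estimate` data.frame with one row per haplotype
#'   (SB, Sb); points sum to 1.
#' @export
pooled_frequency <- function(calls, stage = "adult", n_boot = 5000L, seed = 1L,
                             conf = 0.95) {
  hap <- calls[calls$ploidy == "haploid" & calls$stage == stage, , drop = FALSE]
  n <- nrow(hap)
  if (n == 0L) sb_input_error(sprintf("no haploid calls for stage '%s'", stage))
  if (n_boot < 1L) sb_parameter_error("n_boot must be >= 1")
  is_sb_hap <- hap$supergene_genotype == "SB"
  p_SB <- mean(is_sb_hap)
  set.seed(as.integer(seed))
  boot <- rbinom(n_boot, n, p_SB) / n
  a <- (1 - conf) / 2
  ci <- quantile(boot, c(a, 1 - a), names = FALSE, type = 7)
  out <- data.frame(
    stage = stage, haplotype = c("SB", "Sb"),
    point = c(p_SB, 1 - p_SB),
    ci_low = c(ci[1L], 1 - ci[2L]), ci_high = c(ci[2L], 1 - ci[1L]),
    method = "pooled_bootstrap", n_replicates = n_boot,
    n_colonies_used = length(unique(hap$colony_id)), n_males = n,
    seed = as.integer(seed), stringsAsFactors = FALSE
  )
  class(out) <- unique(c("freq_estimate", class(out)))
  out
}

# One-male-per-colony replicate draws. Returns an n_reps-length vector of
# replicate values of FUN applied to the drawn males (one per eligible
# colony, uniformly at random, independently across replicates).
colony_replicates <- function(value, colony, n_reps, statistic = mean) {
  groups <- split(seq_along(value), colony)
  draws <- vapply(groups, function(idx) {
    idx[sample.int(length(idx), n_reps, replace = TRUE)]
  }, integer(n_reps))
  # draws: n_reps x n_colonies matrix of row indices
  if (n_reps == 1L) draws <- matrix(draws, nrow = 1L)
  apply(matrix(value[draws], nrow = n_reps), 1L, statistic)
}

#' Colony-weighted resampled haplotype frequency
#'
#' Corrects for genetic nonindependence and uneven sampling of colonies by
#' weighting colonies equally: each replicate draws one confirmed haploid
#' male at random from every eligible colony (those with at least one
#' haploid male of the stage) and computes the SB proportion among the
#' drawn males; the default 500 independent replicate values are averaged
#' for the point estimate. Two 95% interval constructions are reported:
#' `ci_low`/`ci_high` for the default method (see `ci`), with both always
#' available in the `ci_*_percentile` / `ci_*_mean` columns — the
#' percentile interval of the replicate values, and the interval for their
#' mean (mean +/- 1.96 SD/sqrt(n_reps)).
#'
#' @param calls A `ploidy_calls` data.frame.
#' @param stage Life stage.
#' @param n_reps Number of one-male-per-colony replicates (default 500).
#' @param seed Integer seed.
#' @param ci Which construction fills `ci_low`/`ci_high`: `"mean"`
#'   (default) or `"percentile"`.
#' @param conf Confidence level.
#' @return A `freq_estimate` data.frame (rows SB and Sb). The attribute
#'   `replicates` holds the SB replicate values.
#' @export
colony_resampled_frequency <- function(calls, stage = "adult", n_reps = 500L,
                                       seed = 1L, ci = c("mean", "percentile"),
                                       conf = 0.95) {
  ci <- match.arg(ci)
  if (n_reps < 1L) sb_parameter_error("n_reps must be >= 1")
  hap <- calls[calls$ploidy == "haploid" & calls$stage == stage, , drop = FALSE]
  n_col_all <- length(unique(calls$colony_id))
  eligible <- unique(hap$colony_id)
  if (length(eligible) < 2L) {
    sb_input_error(sprintf(
      "need >= 2 colonies with a haploid male of stage '%s' (found %d)",
      stage, length(eligible)))
  }
  n_excluded <- n_col_all - length(eligible)
  set.seed(as.integer(seed))
  reps <- colony_replicates(as.numeric(hap$supergene_genotype == "SB"),
                            hap$colony_id, n_reps)
  est <- build_resampled_estimate(reps, n_reps, conf, ci, seed)
  out <- data.frame(
    stage = stage, haplotype = c("SB", "Sb"),
    point = c(est$point, 1 - est$point),
    ci_low = c(est$ci[1L], 1 - est$ci[2L]),
    ci_high = c(est$ci[2L], 1 - est$ci[1L]),
    ci_low_percentile = c(est$pct[1L], 1 - est$pct[2L]),
    ci_high_percentile = c(est$pct[2L], 1 - est$pct[1L]),
    ci_low_mean = c(est$mean_ci[1L], 1 - est$mean_ci[2L]),
    ci_high_mean = c(est$mean_ci[2L], 1 - est$mean_ci[1L]),
    method = "colony_resampled", n_replicates = n_reps,
    n_colonies_used = length(eligible), n_colonies_excluded = n_excluded,
    n_males = nrow(hap), seed = as.integer(seed), stringsAsFactors = FALSE
  )
  class(out) <- unique(c("freq_estimate", class(out)))
  attr(out, "replicates") <- reps
  out
}

build_resampled_estimate <- function(reps, n_reps, conf, ci, seed) {
  a <- (1 - conf) / 2
  pct <- quantile(reps, c(a, 1 - a), names = FALSE, type = 7)
  z <- qnorm(1 - a)
  se <- stats::sd(reps) / sqrt(n_reps)
  m <- mean(reps)
  mean_ci <- c(m - z * se, m + z * se)
  list(point = m, pct = pct, mean_ci = mean_ci,
       ci = if (ci == "mean") mean_ci else pct)
}

#' Colony-weighted resampled mean weight for one haplotype
#'
#' The weight analogue of [colony_resampled_frequency()]: per replicate one
#' confirmed haploid male of the given haplotype is drawn from each colony
#' containing at least one, and the replicate value is the mean weight of
#' the drawn males. The point estimate is the mean of the replicate values;
#' one-tailed 95% confidence limits (the 5th and 95th percentiles of the
#' replicate values) are reported separately as `lower_limit` /
#' `upper_limit`.
#'
#' @param calls A `ploidy_calls` data.frame (weights carried on the calls).
#' @param haplotype `"SB"` or `"Sb"`.
#' @param stage Life stage.
#' @param n_reps Replicates (default 500).
#' @param seed Integer seed.
#' @param conf Confidence level for the one-tailed limits.
#' @return A one-row `freq_estimate` data.frame in mg, with attribute
#'   `replicates`.
#' @export
colony_resampled_weight <- function(calls, haplotype = c("SB", "Sb"),
                                    stage = "adult", n_reps = 500L, seed = 1L,
                                    conf = 0.95) {
  haplotype <- match.arg(haplotype)
  if (n_reps < 1L) sb_parameter_error("n_reps must be >= 1")
  sel <- calls[calls$ploidy == "haploid" & calls$stage == stage &
                 calls$supergene_genotype == haplotype, , drop = FALSE]
  eligible <- unique(sel$colony_id)
  if (length(eligible) < 2L) {
    sb_input_error(sprintf(
      "need >= 2 colonies with a haploid %s male of stage '%s' (found %d)",
      haplotype, stage, length(eligible)))
  }
  set.seed(as.integer(seed))
  reps <- colony_replicates(sel$weight_mg, sel$colony_id, n_reps)
  out <- data.frame(
    stage = stage, haplotype = haplotype, point = mean(reps),
    lower_limit = quantile(reps, 1 - conf, names = FALSE),
    upper_limit = quantile(reps, conf, names = FALSE),
    method = "colony_resampled", n_replicates = n_reps,
    n_colonies_used = length(eligible), n_males = nrow(sel),
    seed = as.integer(seed), stringsAsFactors = FALSE
  )
  class(out) <- unique(c("freq_estimate", class(out)))
  attr(out, "replicates") <- reps
  out
}

#' Resampling-based comparison of two weight streams
#'
#' Compares paired replicate streams (e.g. SB vs Sb resampled mean
#' weights): reports the fraction of replicates in which the difference
#' A - B is <= 0 and the confidence-limit overlap statement. When the
#' streams never cross, the result is reported as P < 1/n_reps.
#'
#' @param reps_a,reps_b Equal-length replicate value vectors (e.g. the
#'   `replicates` attribute of [colony_resampled_weight()]).
#' @return A list with `frac_nonpositive`, `p_label`, `limits_overlap`,
#'   `n_reps`.
#' @export
resampled_weight_difference <- function(reps_a, reps_b) {
  if (length(reps_a) != length(reps_b)) {
    sb_input_error("replicate streams must have equal length")
  }
  n <- length(reps_a)
  if (n == 0L) sb_input_error("empty replicate streams")
  frac <- mean(reps_a - reps_b <= 0)
  lo_a <- quantile(reps_a, 0.05, names = FALSE)
  hi_b <- quantile(reps_b, 0.95, names = FALSE)
  list(
    frac_nonpositive = frac,
    p_label = if (frac == 0) sprintf("P < %g", 1 / n) else sprintf("P = %g", frac),
    limits_overlap = lo_a <= hi_b,
    n_reps = n
  )
}
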