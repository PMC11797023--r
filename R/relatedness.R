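#' Pairwise relatedness between two haploid multilocus genotypes
#'
#' Identity-in-state moment estimator (the haploid reduction of the
#' Queller-Goodnight family): with `s_l = 1` if the two males carry the
#' same allele at locus `l` and `h_l = sum_a p_a^2` the expected identity
#' of two random haplotypes under the reference allele frequencies,
#'
#'   r = sum_l (s_l - h_l) / sum_l (1 - h_l).
#'
#' Unrelated pairs drawn from the reference population have expectation 0,
#' brothers (sons of one singly-mated diploid mother) expectation 0.5, and
#' identical genotypes give exactly 1. The estimator is symmetric and can
#' be negative.
#'
#' @param g1,g2 Named character vectors (locus -> allele label) or
#'   single-male genotype rows with `a/a` strings; one allele per locus.
#' @param ref Reference [allele_freqs()].
#' @return Relatedness estimate in (-Inf, 1].
#' @export
pairwise_relatedness <- function(g1, g2, ref) {
  stopifnot(inherits(ref, "allele_freqs"))
  loci <- intersect(names(g1), names(g2))
  if (length(loci) == 0L) sb_input_error("genotypes share no loci")
  absent <- setdiff(loci, names(ref))
  if (length(absent) > 0L) {
    sb_input_error(sprintf("locus/loci absent from reference: %s",
                           paste(absent, collapse = ", ")))
  }
  h <- vapply(ref[loci], function(p) sum(p^2), numeric(1L))
  denom <- sum(1 - h)
  if (denom <= 0) sb_input_error("reference is monomorphic at all shared loci; r undefined")
  s <- as.numeric(unlist(g1[loci]) == unlist(g2[loci]))
  sum(s - h) / denom
}

# Haploid allele matrix (males x loci) from a male table restricted to
# confirmed haploids: takes the first label of each a/a pair.
haploid_allele_matrix <- function(males, loci) {
  m <- vapply(loci, function(loc) parse_genotypes(males[[loc]])[, 1L],
              character(nrow(males)))
  matrix(m, nrow = nrow(males), dimnames = list(males$male_id, loci))
}

# Mean pairwise r among rows of an allele matrix (n >= 2).
mean_pairwise_r <- function(alleles, h) {
  n <- nrow(alleles)
  denom <- sum(1 - h)
  tot <- 0
  npair <- n * (n - 1) / 2
  for (l in seq_along(h)) {
    a <- alleles[, l]
    counts <- table(a)
    same <- sum(counts * (counts - 1) / 2)  # identical pairs at this locus
    tot <- tot + (same - npair * h[l])
  }
  tot / (npair * denom)
}

#' Colony and population nestmate relatedness for haploid males
#'
#' Computes, for confirmed haploid males of one life stage, the mean
#' pairwise relatedness within each colony holding at least two, then the
#' population value as the unweighted mean of colony values (each colony
#' counts once, consistent with the colony-equalising resampling
#' philosophy; a pair-weighted mean is available via `weighting`). The 95%
#' CI is a percentile bootstrap over colonies (resampled with replacement).
#'
#' @param males A [male_table()] carrying the microsatellite genotypes.
#' @param calls Matching `ploidy_calls` from [classify_table()].
#' @param ref Reference [allele_freqs()].
#' @param stage Life stage.
#' @param n_boot Bootstrap replicates over colonies (default 5000).
#' @param seed Integer seed.
#' @param weighting `"colony"` (default, each colony one value) or
#'   `"pair"` (pairs pooled across colonies).
#' @return A list with `population` (one-row data.frame: `r`, `ci_low`,
#'   `ci_high`, `n_colonies`, `n_pairs`) and `colonies` (per-colony r).
#' @export
colony_and_population_relatedness <- function(males, calls, ref,
                                              stage = "adult", n_boot = 5000L,
                                              seed = 1L,
                                              weighting = c("colony", "pair")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(ref, "allele_freqs"))
  loci <- intersect(attr(males, "loci") %||% default_locus_panel(), names(ref))
  keep <- calls$ploidy == "haploid" & calls$stage == stage
  hap <- males[males$male_id %in% calls$male_id[keep], , drop = FALSE]
  groups <- split(seq_len(nrow(hap)), hap$colony_id)
  groups <- groups[vapply(groups, length, integer(1L)) >= 2L]
  if (length(groups) == 0L) {
    sb_input_error(sprintf("no colony with >= 2 haploid males of stage '%s'", stage))
  }
  h <- vapply(ref[loci], function(p) sum(p^2), numeric(1L))
  alleles <- haploid_allele_matrix(hap, loci)
  col_r <- vapply(groups, function(idx) {
    mean_pairwise_r(alleles[idx, , drop = FALSE], h)
  }, numeric(1L))
  n_pairs <- vapply(groups, function(idx) length(idx) * (length(idx) - 1) / 2,
                    numeric(1L))
  pop_r <- if (weighting == "colony") mean(col_r) else
    sum(col_r * n_pairs) / sum(n_pairs)
  set.seed(as.integer(seed))
  k <- length(col_r)
  boot <- vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(k, k, replace = TRUE)
    if (weighting == "colony") mean(col_r[idx]) else
      sum(col_r[idx] * n_pairs[idx]) / sum(n_pairs[idx])
  }, numeric(1L))
  ci <- quantile(boot, c(0.025, 0.975), names = FALSE)
  list(
    population = data.frame(
      scope = "population", stage = stage, r = pop_r,
      ci_low = ci[1L], ci_high = ci[2L], n_colonies = k,
      n_pairs = sum(n_pairs), n_boot = n_boot, seed = as.integer(seed),
      weighting = weighting, estimator = "identity-in-state moment (haploid QG)",
      stringsAsFactors = FALSE
    ),
    colonies = data.frame(
      scope = "colony", stage = stage, colony_id = names(groups),
      r = unname(col_r), n_males = vapply(groups, length, integer(1L)),
      n_pairs = unname(n_pairs), stringsAsFactors = FALSE
    )
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bootstrap difference test between two sets of colony values
#'
#' Resamples each group's single-colony values with replacement `n_iter`
#' times, forms the difference of group means per iteration, and returns
#' the two-sided p-value `2 * min(frac(diff <= 0), frac(diff >= 0))`,
#' clipped to `[2/n_iter, 1]`.
#'
#' @param values_a,values_b Numeric vectors of per-colony values.
#' @param n_iter Bootstrap iterations (default 5000).
#' @param seed Integer seed.
#' @return A list with `p_value`, `mean_diff`, `n_iter`.
#' @export
bootstrap_difference_test <- function(values_a, values_b, n_iter = 5000L,
                                      seed = 1L) {
  if (length(values_a) == 0L || length(values_b) == 0L) {
    sb_input_error("both groups must be non-empty")
  }
  set.seed(as.integer(seed))
  na <- length(values_a); nb <- length(values_b)
  diffs <- vapply(seq_len(n_iter), function(i) {
    mean(values_a[sample.int(na, na, replace = TRUE)]) -
      mean(values_b[sample.int(nb, nb, replace = TRUE)])
  }, numeric(1L))
  p <- 2 * min(mean(diffs <= 0), mean(diffs >= 0))
  p <- min(1, max(2 / n_iter, p))
  list(p_value = p, mean_diff = mean(values_a) - mean(values_b), n_iter = n_iter)
}

#' Effective queen number from nestmate relatedness
#'
#' The number of equally contributing, mutually unrelated queens (mated to
#' unrelated males) that would produce the observed nestmate relatedness
#' among haploid males. Haploid brothers have pedigree relatedness 0.5, so
#' with q such queens the expected nestmate relatedness is 0.5/q and
#'
#'   n_e = sibling_r / r.
#'
#' @param r Observed nestmate relatedness, in (0, 1].
#' @param sibling_r Pedigree relatedness of brothers (default 0.5 for the
#'   male-haploid system).
#' @return A list with `n_e`, `r_input`, `sibling_r` and the stated
#'   assumptions.
#' @export
effective_queen_number <- function(r, sibling_r = 0.5) {
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r <= 0 || r > 1) {
    sb_input_error("r must be a single value in (0, 1]")
  }
  list(
    n_e = sibling_r / r,
    r_input = r,
    sibling_r = sibling_r,
    assumptions = "queens mutually unrelated; their male mates mutually unrelated"
  )
}
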