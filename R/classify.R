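#' False-haploid misclassification probability
#'
#' Probability that a random outbred diploid male is homozygous at every
#' locus of the microsatellite panel — i.e. the chance of falsely calling a
#' diploid homozygote at Gp-9 a haploid hemizygote. Under Hardy-Weinberg
#' with independent loci this is the product over panel loci of the expected
#' homozygosity `sum_a p_a^2`; an optional inbreeding coefficient `f_is`
#' inflates each locus to `f_is + (1 - f_is) * sum_a p_a^2`.
#'
#' @param freqs An [allele_freqs()] table.
#' @param panel Locus names to use (default: all loci in `freqs`).
#' @param f_is Inbreeding coefficient (default 0).
#' @return A probability.
#' @export
false_haploid_probability <- function(freqs, panel = names(freqs), f_is = 0) {
  stopifnot(inherits(freqs, "allele_freqs"))
  if (length(panel) == 0L) sb_input_error("empty locus panel: probability undefined")
  absent <- setdiff(panel, names(freqs))
  if (length(absent) > 0L) {
    sb_input_error(sprintf("panel locus/loci absent from frequency table: %s",
                           paste(absent, collapse = ", ")))
  }
  if (f_is < 0 || f_is > 1) sb_parameter_error("f_is must lie in [0, 1]")
  hom <- vapply(freqs[panel], function(p) sum(p^2), numeric(1L))
  prod(f_is + (1 - f_is) * hom)
}

#' Classify male ploidy and supergene genotype
#'
#' Combines the two-band Gp-9 assay with multilocus microsatellite
#' hemizygosity. Two Gp-9 bands (517 + 423 bp) prove a heterozygous diploid
#' (SB/Sb) outright. A single band leaves ploidy ambiguous: any
#' heterozygous microsatellite locus proves diploidy (SB/SB for the 517 bp
#' band, Sb/Sb for 423 bp); a male homozygous-appearing at every panel
#' locus is called haploid (SB or Sb by band) and carries the residual
#' false-haploid probability from the allele-frequency table. A record with
#' a missing microsatellite call and a single band is `unresolved` and is
#' excluded downstream.
#'
#' @param record One row of a [male_table()] (or a list with the same
#'   fields).
#' @param freqs Optional [allele_freqs()] used to attach the false-haploid
#'   probability to haploid calls.
#' @param loci Locus panel.
#' @return A one-row data.frame `ploidy_call` with columns `male_id`,
#'   `colony_id`, `stage`, `weight_mg`, `ploidy`, `supergene_genotype`,
#'   `n_heterozygous_loci`, `confirmed_by_microsats`, `false_haploid_prob`.
#' @export
classify_male <- function(record, freqs = NULL, loci = default_locus_panel()) {
  df <- as.data.frame(record, stringsAsFactors = FALSE)
  classify_table(male_table(df, loci = loci), freqs = freqs, loci = loci)$calls
}

#' Classify a whole male table
#'
#' Vectorised classification of every record plus the per-stage accounting
#' the study design calls for: males genotyped at Gp-9, single-band males
#' (ploidy uncertain, sent to microsatellite genotyping), males confirmed
#' haploid by multilocus hemizygosity, single-band diploids, and unresolved
#' records (missing calls).
#'
#' @param males A [male_table()].
#' @param freqs Optional [allele_freqs()] for the false-haploid probability.
#' @param loci Locus panel.
#' @return A list with `calls` (data.frame, one row per male) and `summary`
#'   (per-stage counts). Totals reconcile: confirmed haploids +
#'   single-band diploids = single-band total - unresolved.
#' @export
classify_table <- function(males, freqs = NULL, loci = default_locus_panel()) {
  stopifnot(inherits(males, "male_tbl"))
  n <- nrow(males)
  bands <- lapply(males$gp9_bands, parse_bands)
  if (any(vapply(bands, is.null, logical(1L)))) {
    sb_input_error("empty or invalid Gp-9 band set")
  }
  two_band <- vapply(bands, length, integer(1L)) == 2L
  band_one <- vapply(bands, `[`, integer(1L), 1L)  # 517 or 423 for singles

  n_het <- integer(n)
  any_missing <- logical(n)
  for (loc in loci) {
    g <- parse_genotypes(males[[loc]])
    miss <- g[, 1L] == missing_allele | g[, 2L] == missing_allele
    any_missing <- any_missing | miss
    n_het <- n_het + (!miss & g[, 1L] != g[, 2L])
  }

  ploidy <- character(n)
  genotype <- character(n)
  confirmed <- logical(n)

  ploidy[two_band] <- "diploid"
  genotype[two_band] <- "SB/Sb"

  single <- !two_band
  unresolved <- single & any_missing
  ploidy[unresolved] <- "unresolved"
  genotype[unresolved] <- NA_character_

  het_dip <- single & !any_missing & n_het >= 1L
  ploidy[het_dip] <- "diploid"
  genotype[het_dip] <- ifelse(band_one[het_dip] == gp9_product_bp[["SB"]],
                              "SB/SB", "Sb/Sb")

  hap <- single & !any_missing & n_het == 0L
  ploidy[hap] <- "haploid"
  genotype[hap] <- ifelse(band_one[hap] == gp9_product_bp[["SB"]], "SB", "Sb")
  confirmed[hap] <- TRUE

  fh <- if (!is.null(freqs)) false_haploid_probability(freqs, panel = loci) else NA_real_
  calls <- data.frame(
    male_id = males$male_id, colony_id = males$colony_id,
    stage = males$stage, weight_mg = males$weight_mg,
    ploidy = ploidy, supergene_genotype = genotype,
    n_heterozygous_loci = n_het,
    confirmed_by_microsats = confirmed,
    false_haploid_prob = ifelse(ploidy == "haploid", fh, NA_real_),
    stringsAsFactors = FALSE
  )
  class(calls) <- unique(c("ploidy_calls", class(calls)))

  summ <- do.call(rbind, lapply(c("adult", "pupa"), function(st) {
    s <- calls$stage == st
    data.frame(
      stage = st,
      n_genotyped = sum(s),
      n_single_band = sum(s & !two_band),
      n_two_band = sum(s & two_band),
      n_confirmed_haploid = sum(s & confirmed),
      n_single_band_diploid = sum(s & het_dip),
      n_unresolved = sum(s & unresolved),
      stringsAsFactors = FALSE
    )
  }))
  list(calls = calls, summary = summ)
}

#' Confusion matrix of ploidy calls against simulator ground truth
#'
#' @param calls `calls` data.frame from [classify_table()].
#' @param males The simulated [male_table()] the calls came from (must carry
#'   truth columns).
#' @return A contingency table of truth_ploidy x called ploidy.
#' @export
ploidy_confusion <- function(calls, males) {
  if (!"truth_ploidy" %in% names(males)) {
    sb_input_error("male table has no truth columns; not simulator output")
  }
  table(truth = males$truth_ploidy,
        called = calls$ploidy[match(males$male_id, calls$male_id)])
}
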