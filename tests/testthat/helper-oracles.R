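# Independent brute-force oracles and fixture builders used across tests.
# These deliberately avoid the package's code paths (and stats::fisher.test /
# stats::binom.test) so they can serve as cross-checks.

# Exact two-sided binomial p-value at null p by direct enumeration of the
# pmf, summing point probabilities no larger than that of the observed k.
oracle_binom_two_sided <- function(k, n, p = 0.5) {
  pmf <- stats::dbinom(0:n, n, p)
  sum(pmf[pmf <= pmf[k + 1L] * (1 + 1e-7)])
}

# Exact two-sided Fisher p-value by full enumeration of all 2x2 tables with
# the observed margins, via the hypergeometric pmf.
oracle_fisher_two_sided <- function(tab) {
  r1 <- sum(tab[1L, ]); c1 <- sum(tab[, 1L]); n <- sum(tab)
  lo <- max(0L, r1 + c1 - n); hi <- min(r1, c1)
  support <- lo:hi
  pmf <- stats::dhyper(support, c1, n - c1, r1)
  obs <- stats::dhyper(tab[1L, 1L], c1, n - c1, r1)
  sum(pmf[pmf <= obs * (1 + 1e-7)])
}

# Minimal well-formed male table rows (defaults are a haploid-looking Sb).
make_males <- function(n = 1L, male_id = sprintf("m%02d", seq_len(n)),
                       colony_id = "c1", stage = "adult", weight_mg = 6.0,
                       gp9_bands = "423",
                       Sol42_f = "118/118", Sol49 = "201/201",
                       C536 = "152/152", cassidy = "240/240") {
  male_table(data.frame(male_id = male_id, colony_id = colony_id,
                        stage = stage, weight_mg = weight_mg,
                        gp9_bands = gp9_bands, Sol42_f = Sol42_f,
                        Sol49 = Sol49, C536 = C536, cassidy = cassidy,
                        stringsAsFactors = FALSE))
}

# Hand-built ploidy_calls rows for resampling tests (bypasses the
# classifier on purpose; the resampling stage only contracts on columns).
make_calls <- function(colony_id, genotype, stage = "adult",
                       weight_mg = 6.0, ploidy = "haploid") {
  n <- max(length(colony_id), length(genotype))
  d <- data.frame(
    male_id = sprintf("m%03d", seq_len(n)), colony_id = colony_id,
    stage = stage, weight_mg = weight_mg, ploidy = ploidy,
    supergene_genotype = genotype, n_heterozygous_loci = 0L,
    confirmed_by_microsats = ploidy == "haploid",
    false_haploid_prob = NA_real_, stringsAsFactors = FALSE
  )
  class(d) <- unique(c("ploidy_calls", class(d)))
  d
}

# Pedigree generator with a FIXED queen number per colony: q unrelated
# SB/Sb queens, each male an impaternate son of a uniformly chosen queen.
# Serves as the independent pedigree oracle for relatedness recovery
# (expected nestmate r = 0.5/q).
make_pedigree_males <- function(n_colonies, q, males_per_colony, freqs,
                                p_sb = 0.5, seed = 1L) {
  set.seed(seed)
  loci <- names(freqs)
  rows <- lapply(seq_len(n_colonies), function(cc) {
    queens <- lapply(loci, function(loc) {
      matrix(sample(names(freqs[[loc]]), 2L * q, replace = TRUE,
                    prob = freqs[[loc]]), ncol = 2L)
    })
    mother <- sample.int(q, males_per_colony, replace = TRUE)
    geno <- lapply(seq_along(loci), function(l) {
      a <- queens[[l]][cbind(mother, 1L + (runif(males_per_colony) < 0.5))]
      paste(a, a, sep = "/")
    })
    d <- data.frame(
      male_id = sprintf("c%02d_m%03d", cc, seq_len(males_per_colony)),
      colony_id = sprintf("c%02d", cc), stage = "adult",
      weight_mg = 6.0,
      gp9_bands = ifelse(runif(males_per_colony) < p_sb, "423", "517"),
      stringsAsFactors = FALSE
    )
    for (l in seq_along(loci)) d[[loci[l]]] <- geno[[l]]
    d
  })
  male_table(do.call(rbind, rows), loci = loci)
}

# Equifrequent k-allele panel over the default loci.
equifreq_panel <- function(k = 10L) {
  allele_freqs(setNames(lapply(default_locus_panel(), function(loc) {
    setNames(rep(1 / k, k), paste0("a", seq_len(k)))
  }), default_locus_panel()))
}
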