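#' Default microsatellite reference frequencies
#'
#' A four-locus panel (`Sol42_f`, `Sol49`, `C536`, `cassidy`) of amply
#' polymorphic loci with uneven allele frequencies. Per-locus expected
#' homozygosities are roughly 0.30, 0.27, 0.25 and 0.24, so the probability
#' that an outbred diploid is homozygous at all four loci — the false-haploid
#' misclassification probability — is about 0.005 (0.5%). Allele labels are
#' fragment lengths in bp.
#'
#' @return An [allele_freqs()] object.
#' @export
default_allele_freqs <- function() {
  allele_freqs(list(
    Sol42_f = c(`118` = 0.50, `122` = 0.15, `126` = 0.10, `130` = 0.08,
                `134` = 0.07, `138` = 0.05, `142` = 0.03, `146` = 0.02),
    Sol49   = c(`201` = 0.45, `205` = 0.20, `209` = 0.12, `213` = 0.08,
                `217` = 0.06, `221` = 0.04, `225` = 0.03, `229` = 0.02),
    C536    = c(`152` = 0.42, `156` = 0.20, `160` = 0.12, `164` = 0.10,
                `168` = 0.07, `172` = 0.05, `176` = 0.04),
    cassidy = c(`240` = 0.40, `244` = 0.22, `248` = 0.12, `252` = 0.10,
                `256` = 0.08, `260` = 0.05, `264` = 0.03)
  ))
}

#' Simulation parameters for the polygyne breeding system
#'
#' Parameterises the forward simulator of [simulate_population()]. Defaults
#' emulate a field collection of 40 polygyne colonies: every reproductive
#' queen is an SB/Sb heterozygote; haploid (fertile) males arise from
#' unfertilised eggs and carry Sb with probability `distortion_delta`
#' (0.5 = Mendelian); diploid males arise from matched matings at the
#' complementary sex-determination locus and make up
#' `diploid_male_target_fraction` of males; haploid male production per
#' colony is strongly overdispersed and zero-inflated (many colonies yield
#' none, a couple dominate the sample); weights follow a group mean
#' (haploid Sb < haploid SB < diploid) plus a shared colony effect and a
#' residual, all in mg.
#'
#' @param n_colonies Number of polygyne colonies (default 40).
#' @param queen_mean Mean queens per colony; counts are `max(1, Poisson)`
#'   (default 2.75, giving roughly 2.5-3 effective queens).
#' @param distortion_delta P(an unfertilised egg of an SB/Sb queen carries
#'   Sb). Default 0.78, a strong Sb transmission bias; 0.5 is Mendelian.
#' @param matched_mating_rate P(a queen's single mating is matched at the
#'   sex locus). Matched queens produce diploid males (half of their
#'   fertilised eggs under single-locus CSD); default 0.2.
#' @param diploid_male_target_fraction Target fraction of all produced males
#'   that are diploid (default 0.85; field surveys report 80-95%).
#' @param haploid_males_mean Mean haploid males per colony, across all
#'   colonies including non-producers (default 10.8).
#' @param haploid_zero_prob Probability a colony produces no haploid males
#'   (default 15/40).
#' @param haploid_size Negative-binomial size (dispersion) for haploid male
#'   counts in producing colonies; small values let a couple of colonies
#'   dominate (default 0.9).
#' @param pupa_fraction Fraction of produced males collected as pupae
#'   (default 0.06, so that after the adult weight-threshold sub-sampling
#'   the genotyped sample runs roughly 4:1 adults to pupae, mirroring
#'   opportunistic pupal collection).
#' @param weight_model Named list with means `mean_hap_Sb` (6.12),
#'   `mean_hap_SB` (7.07), `mean_dip` (9.5), and SDs `colony_sd` (0.5) and
#'   `residual_sd` (0.5), all mg.
#' @param allele_freqs Reference [allele_freqs()] for the microsatellite
#'   panel (default [default_allele_freqs()]).
#' @param sampling_design Named list `threshold` (8.0 mg), `bin_width`
#'   (0.25 mg), `bin_cap` (20), `upper_limit` (10.0 mg); see
#'   [apply_sampling_design()].
#' @param father_Sb_freq P(a mate of a polygyne queen carries Sb); `NULL`
#'   (default) self-consistently uses `distortion_delta`.
#' @param execution_probs Per-group execution probabilities for
#'   [simulate_execution_assay()].
#' @param seed Integer RNG seed.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_colonies = 40L,
                       queen_mean = 2.75,
                       distortion_delta = 0.78,
                       matched_mating_rate = 0.2,
                       diploid_male_target_fraction = 0.85,
                       haploid_males_mean = 10.8,
                       haploid_zero_prob = 15 / 40,
                       haploid_size = 0.9,
                       pupa_fraction = 0.06,
                       weight_model = list(mean_hap_Sb = 6.12, mean_hap_SB = 7.07,
                                           mean_dip = 9.5, colony_sd = 0.5,
                                           residual_sd = 0.5),
                       allele_freqs = default_allele_freqs(),
                       sampling_design = list(threshold = 8.0, bin_width = 0.25,
                                              bin_cap = 20L, upper_limit = 10.0),
                       father_Sb_freq = NULL,
                       execution_probs = list(
                         polygyne = c(SB = 0.538, Sb = 0.538, `SB/SB` = 0.198,
                                      `SB/Sb` = 0.144, `Sb/Sb` = 0.469),
                         monogyne = c(SB = 0.01, Sb = 0.01, `SB/SB` = 0.01,
                                      `SB/Sb` = 0.01, `Sb/Sb` = 0.01)),
                       seed = 1L) {
  p <- list(n_colonies = as.integer(n_colonies), queen_mean = queen_mean,
            distortion_delta = distortion_delta,
            matched_mating_rate = matched_mating_rate,
            diploid_male_target_fraction = diploid_male_target_fraction,
            haploid_males_mean = haploid_males_mean,
            haploid_zero_prob = haploid_zero_prob, haploid_size = haploid_size,
            pupa_fraction = pupa_fraction, weight_model = weight_model,
            allele_freqs = allele_freqs, sampling_design = sampling_design,
            father_Sb_freq = father_Sb_freq, execution_probs = execution_probs,
            seed = as.integer(seed))
  probs <- c(p$distortion_delta, p$matched_mating_rate,
             p$diploid_male_target_fraction, p$haploid_zero_prob, p$pupa_fraction)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    sb_parameter_error("all probability parameters must lie in [0, 1]")
  }
  if (p$n_colonies < 1L) sb_parameter_error("n_colonies must be >= 1")
  if (p$queen_mean <= 0 || p$haploid_males_mean < 0 || p$haploid_size <= 0) {
    sb_parameter_error("distribution parameters must be positive")
  }
  wm <- p$weight_model
  need <- c("mean_hap_Sb", "mean_hap_SB", "mean_dip", "colony_sd", "residual_sd")
  if (!all(need %in% names(wm))) {
    sb_parameter_error(sprintf("weight_model must name: %s", paste(need, collapse = ", ")))
  }
  if (any(unlist(wm[1:3]) <= 0) || any(unlist(wm[4:5]) < 0)) {
    sb_parameter_error("weight means must be > 0 and SDs >= 0")
  }
  if (!inherits(p$allele_freqs, "allele_freqs")) {
    p$allele_freqs <- allele_freqs(p$allele_freqs)
  }
  structure(p, class = "sim_params")
}

#' Gp-9 PCR band pattern for a supergene genotype
#'
#' The assay is deterministic: the B (SB) allele yields a 517 bp product and
#' the b (Sb) allele a 423 bp product, so heterozygous diploids show both
#' bands while haploids and homozygous diploids show a single band — the
#' single-band ambiguity that motivates multilocus microsatellite screening.
#'
#' @param genotype One of `SB`, `Sb`, `SB/SB`, `SB/Sb`, `Sb/Sb` (vectorised).
#' @return For a single genotype, an integer vector of product lengths; for
#'   several, a list of such vectors.
#' @export
simulate_gp9_assay <- function(genotype) {
  one <- function(g) {
    switch(g,
      "SB"    = gp9_product_bp[["SB"]],
      "Sb"    = gp9_product_bp[["Sb"]],
      "SB/SB" = gp9_product_bp[["SB"]],
      "Sb/Sb" = gp9_product_bp[["Sb"]],
      "SB/Sb" = unname(gp9_product_bp),
      sb_input_error(sprintf("unknown supergene genotype: %s", g))
    )
  }
  if (length(genotype) == 1L) one(genotype) else lapply(genotype, one)
}

# Draw n alleles at one locus from reference frequencies.
draw_alleles <- function(freqs, n) {
  sample(names(freqs), n, replace = TRUE, prob = freqs)
}

#' Simulate a polygyne male population with known ground truth
#'
#' Forward-simulates the breeding system: each colony holds `max(1, Poisson)`
#' SB/Sb queens with microsatellite genotypes drawn from the reference
#' frequencies, each singly mated (matched at the sex locus with probability
#' `matched_mating_rate`). Haploid males are impaternate sons of a uniformly
#' chosen queen, carry Sb with probability `distortion_delta`, and inherit
#' one maternal allele per locus. Diploid males come from matched queens
#' only; their supergene genotype combines a Mendelian maternal allele with
#' a paternal haplotype, and their microsatellite genotypes add the father's
#' allele. Per-matched-queen diploid production is calibrated so diploids
#' make up `diploid_male_target_fraction` of all males in expectation.
#' Weights are group mean + colony effect + residual. Nestmate haploid males
#' therefore have expected pairwise relatedness 0.5 / (queens per colony).
#'
#' @param params A [sim_params()] object.
#' @param seed Optional seed overriding `params$seed`.
#' @return A [male_table()] with `truth_ploidy`, `truth_genotype` and
#'   `truth_mother_id` columns.
#' @export
simulate_population <- function(params = sim_params(), seed = NULL) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(if (is.null(seed)) params$seed else as.integer(seed))
  loci <- names(params$allele_freqs)
  nc <- params$n_colonies

  n_queens <- pmax(1L, rpois(nc, params$queen_mean))
  # Haploid male counts: zero-inflated negative binomial. The nonzero-class
  # mean is scaled so the overall mean matches haploid_males_mean.
  produce <- runif(nc) >= params$haploid_zero_prob
  mu_nz <- params$haploid_males_mean / max(1e-12, 1 - params$haploid_zero_prob)
  n_hap <- integer(nc)
  n_hap[produce] <- rnbinom(sum(produce), size = params$haploid_size, mu = mu_nz)

  # Diploid males only from matched queens; expected total calibrated to the
  # target diploid fraction f: D = H * f / (1 - f).
  f <- params$diploid_male_target_fraction
  matched <- lapply(n_queens, function(q) runif(q) < params$matched_mating_rate)
  exp_hap_total <- nc * params$haploid_males_mean
  exp_matched <- nc * mean(pmax(1, params$queen_mean)) * params$matched_mating_rate
  per_matched_mu <- if (f >= 1 || exp_matched <= 0) 0 else
    exp_hap_total * f / (1 - f) / exp_matched
  father_pSb <- if (is.null(params$father_Sb_freq)) params$distortion_delta else
    params$father_Sb_freq

  # Queen and mate genotypes per colony.
  queen_geno <- lapply(seq_len(nc), function(c) {
    lapply(loci, function(loc) {
      matrix(draw_alleles(params$allele_freqs[[loc]], 2L * n_queens[c]),
             ncol = 2L)
    })
  })
  father_geno <- lapply(seq_len(nc), function(c) {
    lapply(loci, function(loc) draw_alleles(params$allele_freqs[[loc]], n_queens[c]))
  })

  rows <- vector("list", nc)
  for (c in seq_len(nc)) {
    q <- n_queens[c]
    nh <- n_hap[c]
    nd <- if (any(matched[[c]])) sum(rpois(sum(matched[[c]]), per_matched_mu)) else 0L
    n <- nh + nd
    if (n == 0L) next
    matched_ids <- which(matched[[c]])
    mother <- c(sample.int(q, nh, replace = TRUE),
                if (nd > 0L) matched_ids[sample.int(length(matched_ids), nd, replace = TRUE)])
    ploidy <- rep(c("haploid", "diploid"), c(nh, nd))
    hap_allele <- ifelse(runif(nh) < params$distortion_delta, "Sb", "SB")
    dip_mat <- ifelse(runif(nd) < 0.5, "Sb", "SB")
    dip_pat <- ifelse(runif(nd) < father_pSb, "Sb", "SB")
    genotype <- c(hap_allele,
                  if (nd > 0L) ifelse(dip_mat == dip_pat,
                                      paste(dip_mat, dip_pat, sep = "/"),
                                      "SB/Sb"))
    # Homozygous diploid genotypes render as "SB/SB"/"Sb/Sb"; heterozygous
    # always in SB/Sb order.
    geno_cols <- lapply(seq_along(loci), function(l) {
      qg <- queen_geno[[c]][[l]]
      pick <- 1L + (runif(n) < 0.5)
      mat_allele <- qg[cbind(mother, pick)]
      pat_allele <- father_geno[[c]][[l]][mother]
      ifelse(ploidy == "haploid",
             paste(mat_allele, mat_allele, sep = "/"),
             paste(pmin(mat_allele, pat_allele), pmax(mat_allele, pat_allele), sep = "/"))
    })
    group_mean <- ifelse(ploidy == "diploid", params$weight_model$mean_dip,
                         ifelse(genotype == "Sb", params$weight_model$mean_hap_Sb,
                                params$weight_model$mean_hap_SB))
    colony_eff <- rnorm(1L, 0, params$weight_model$colony_sd)
    weight <- pmax(0.5, group_mean + colony_eff +
                     rnorm(n, 0, params$weight_model$residual_sd))
    stage <- ifelse(runif(n) < params$pupa_fraction, "pupa", "adult")
    df <- data.frame(
      male_id = sprintf("C%02d_M%03d", c, seq_len(n)),
      colony_id = sprintf("C%02d", c),
      stage = stage,
      weight_mg = round(weight, 2L),
      gp9_bands = vapply(genotype, function(g) format_bands(simulate_gp9_assay(g)), ""),
      stringsAsFactors = FALSE
    )
    for (l in seq_along(loci)) df[[loci[l]]] <- geno_cols[[l]]
    df$truth_ploidy <- ploidy
    df$truth_genotype <- genotype
    df$truth_mother_id <- sprintf("C%02d_Q%02d", c, mother)
    rows[[c]] <- df
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (is.null(out)) {
    sb_parameter_error("simulation produced no males; increase production parameters")
  }
  rownames(out) <- NULL
  male_table(out, loci = loci)
}

#' Apply the weight-threshold sampling design
#'
#' Emulates the study's sub-sampling of adult males by fresh weight: every
#' male lighter than `threshold` is retained; above it, males fall into
#' half-open bins `[threshold + k*bin_width, threshold + (k+1)*bin_width)`
#' and at most `bin_cap` per bin are kept (uniformly at random); males at or
#' above `upper_limit` are dropped. Pupae are exempt (all retained), since
#' every collected pupa was weighed and genotyped.
#'
#' @param males A [male_table()].
#' @param design List with `threshold`, `bin_width`, `bin_cap`,
#'   `upper_limit` (mg).
#' @param seed Optional integer seed for the within-bin draws.
#' @param stages Stages the design applies to (default `"adult"`).
#' @return The retained subset, a `male_tbl`.
#' @export
apply_sampling_design <- function(males,
                                  design = list(threshold = 8.0, bin_width = 0.25,
                                                bin_cap = 20L, upper_limit = 10.0),
                                  seed = NULL, stages = "adult") {
  stopifnot(inherits(males, "male_tbl"))
  if (!is.numeric(design$bin_width) || design$bin_width <= 0) {
    sb_parameter_error("bin_width must be positive")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  w <- males$weight_mg
  subject <- males$stage %in% stages
  keep <- !subject | w < design$threshold
  drop <- subject & w >= design$upper_limit
  keep[drop] <- FALSE
  binned <- which(subject & !keep & !drop)
  if (length(binned) > 0L) {
    bin <- floor((w[binned] - design$threshold) / design$bin_width)
    for (b in unique(bin)) {
      idx <- binned[bin == b]
      if (length(idx) > design$bin_cap) {
        idx <- sample(idx, design$bin_cap)
      }
      keep[idx] <- TRUE
    }
  }
  out <- males[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate a worker execution assay
#'
#' Each male is presented to workers of its colony and executed as an
#' independent Bernoulli draw with the probability configured for its
#' (social form, supergene class) group; executed males get a uniformly
#' distributed observation hour on the 1-12 h watch.
#'
#' @param males A data.frame with `male_id`, `colony_id` and either a
#'   `ploidy_genotype` column or `truth_genotype` (simulator output).
#' @param execution_probs Nested list: social form -> named vector of
#'   per-genotype execution probabilities.
#' @param seed Integer seed.
#' @param social_form Social form of the assay colonies.
#' @return An [execution_table()].
#' @export
simulate_execution_assay <- function(males, execution_probs, seed = NULL,
                                     social_form = "polygyne") {
  geno <- if ("ploidy_genotype" %in% names(males)) males$ploidy_genotype else
    males$truth_genotype
  if (is.null(geno)) sb_schema_error("males need a ploidy_genotype or truth_genotype column")
  probs <- execution_probs[[social_form]]
  if (is.null(probs)) sb_parameter_error(sprintf("no execution probabilities for %s", social_form))
  missing_grp <- setdiff(unique(geno), names(probs))
  if (length(missing_grp) > 0L) {
    sb_parameter_error(sprintf("no execution probability configured for group(s): %s",
                               paste(missing_grp, collapse = ", ")))
  }
  p <- unname(probs[geno])
  if (any(p < 0 | p > 1)) sb_parameter_error("execution probabilities must lie in [0, 1]")
  if (!is.null(seed)) set.seed(as.integer(seed))
  executed <- runif(length(p)) < p
  hour <- rep(NA_integer_, length(p))
  hour[executed] <- sample.int(12L, sum(executed), replace = TRUE)
  execution_table(data.frame(
    male_id = males$male_id, colony_id = males$colony_id,
    social_form = social_form, ploidy_genotype = geno,
    executed = executed, hour_observed = hour, stringsAsFactors = FALSE
  ))
}
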