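#' Exact binomial test against the Mendelian 50:50 expectation
#'
#' Two-sided exact binomial test of `k` successes in `n` trials against
#' null probability 0.5 ("as extreme" defined by point-probability
#' ordering, the conventional exact two-sided rule).
#'
#' @param k,n Successes and trials.
#' @return A `sb_test` list: `test_name`, `statistic` (k/n), `p_value`,
#'   `alternative`, `inputs`.
#' @export
binomial_test_vs_half <- function(k, n) {
  if (!is.numeric(k) || !is.numeric(n) || n < 1 || k < 0 || k > n ||
      k != round(k) || n != round(n)) {
    sb_input_error("need integers 0 <= k <= n, n >= 1")
  }
  ht <- binom.test(k, n, p = 0.5, alternative = "two.sided")
  sb_test("binomial_vs_0.5", statistic = k / n, df = NULL,
          p_value = ht$p.value, alternative = "two_sided",
          inputs = sprintf("k=%d, n=%d", k, n))
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact test with fixed margins; the p-value sums hypergeometric
#' probabilities of all tables no more probable than the observed one.
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @return A `sb_test` list.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) sb_input_error("table must be 2x2")
  if (any(tab < 0) || any(tab != round(tab))) {
    sb_input_error("cells must be non-negative integers")
  }
  if (sum(tab) == 0) sb_input_error("at least one margin must be positive")
  ht <- fisher.test(tab, alternative = "two.sided")
  sb_test("fisher_exact", statistic = unname(ht$estimate), df = NULL,
          p_value = ht$p.value, alternative = "two_sided",
          inputs = paste(as.vector(t(tab)), collapse = ","))
}

#' Two-sample t test of mean weights
#'
#' @param group_a,group_b Numeric vectors (each >= 2 values with positive
#'   variance).
#' @param variant `"welch"` (default, Satterthwaite df) or `"student"`
#'   (pooled variance).
#' @return A `sb_test` list with `statistic` (t), `df`, `p_value`.
#' @export
t_test <- function(group_a, group_b, variant = c("welch", "student")) {
  variant <- match.arg(variant)
  for (g in list(group_a, group_b)) {
    if (length(g) < 2L || stats::var(g) == 0) {
      sb_input_error("each group needs >= 2 values with positive variance")
    }
  }
  ht <- t.test(group_a, group_b, var.equal = variant == "student")
  sb_test(paste0("t_test_", variant), statistic = unname(ht$statistic),
          df = unname(ht$parameter), p_value = ht$p.value,
          alternative = "two_sided",
          inputs = sprintf("nA=%d, nB=%d", length(group_a), length(group_b)))
}

#' Two-way ANOVA of weight on colony and supergene haplotype
#'
#' Sequential (type-I) decomposition of adult haploid male weight with
#' colony of origin entered first, then haplotype, then their interaction.
#' By default only colonies holding at least two adult haploid males
#' including both haplotypes enter the fit; the realised colony df is part
#' of the result so the filtering can be audited.
#'
#' @param calls A `ploidy_calls` data.frame carrying `weight_mg`.
#' @param stage Life stage (default `"adult"`).
#' @param colony_filter Function mapping the per-colony subset of calls to
#'   TRUE/FALSE inclusion; the default requires >= 2 males and both
#'   haplotypes.
#' @return A list of `sb_test` results (`colony`, `haplotype`,
#'   `interaction`) plus `n_colonies` and `n_males`.
#' @export
anova_weight <- function(calls, stage = "adult", colony_filter = NULL) {
  hap <- calls[calls$ploidy == "haploid" & calls$stage == stage, , drop = FALSE]
  if (is.null(colony_filter)) {
    colony_filter <- function(d) nrow(d) >= 2L &&
      length(unique(d$supergene_genotype)) == 2L
  }
  keep_col <- names(Filter(isTRUE, lapply(split(hap, hap$colony_id), colony_filter)))
  hap <- hap[hap$colony_id %in% keep_col, , drop = FALSE]
  if (length(keep_col) < 2L) {
    sb_input_error("fewer than 2 colonies remain after filtering")
  }
  hap$colony_id <- factor(hap$colony_id)
  hap$haplotype <- factor(hap$supergene_genotype)
  if (stats::var(hap$weight_mg) == 0) {
    # Degenerate: no variance to decompose.
    zero <- function(term) sb_test(paste0("anova_", term), statistic = 0,
                                   df = NA_real_, p_value = 1,
                                   alternative = "two_sided", inputs = "constant weights")
    return(list(colony = zero("colony"), haplotype = zero("haplotype"),
                interaction = zero("interaction"),
                n_colonies = length(keep_col), n_males = nrow(hap)))
  }
  fit <- aov(weight_mg ~ colony_id + haplotype + colony_id:haplotype, data = hap)
  tab <- summary(fit)[[1L]]
  term_row <- function(rowname, label) {
    i <- match(rowname, trimws(rownames(tab)))
    if (is.na(i) || is.na(tab[i, "F value"])) return(NULL)
    sb_test(paste0("anova_", label),
            statistic = tab[i, "F value"],
            df = c(tab[i, "Df"], tab[nrow(tab), "Df"]),
            p_value = tab[i, "Pr(>F)"], alternative = "two_sided",
            inputs = sprintf("%d colonies, %d males", length(keep_col), nrow(hap)))
  }
  list(colony = term_row("colony_id", "colony"),
       haplotype = term_row("haplotype", "haplotype"),
       interaction = term_row("colony_id:haplotype", "interaction"),
       n_colonies = length(keep_col), n_males = nrow(hap))
}

#' Binomial proportion with confidence interval
#'
#' @param successes,n Counts.
#' @param method `"wilson"` (score interval, default), `"clopper_pearson"`,
#'   or `"bootstrap"` (percentile, 5000 draws).
#' @param conf Confidence level.
#' @param seed Seed (bootstrap method only).
#' @return A data.frame with `successes`, `n`, `p_hat`, `ci_low`,
#'   `ci_high`, `method`.
#' @export
proportion_ci <- function(successes, n,
                          method = c("wilson", "clopper_pearson", "bootstrap"),
                          conf = 0.95, seed = 1L) {
  method <- match.arg(method)
  if (n < 1 || successes < 0 || successes > n) {
    sb_input_error("need 0 <= successes <= n, n >= 1")
  }
  p <- successes / n
  a <- 1 - conf
  ci <- switch(method,
    wilson = {
      z <- qnorm(1 - a / 2)
      denom <- 1 + z^2 / n
      centre <- (p + z^2 / (2 * n)) / denom
      half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
      c(max(0, centre - half), min(1, centre + half))
    },
    clopper_pearson = as.numeric(binom.test(successes, n, conf.level = conf)$conf.int),
    bootstrap = {
      set.seed(as.integer(seed))
      quantile(rbinom(5000L, n, p) / n, c(a / 2, 1 - a / 2), names = FALSE)
    })
  data.frame(successes = successes, n = n, p_hat = p,
             ci_low = ci[1L], ci_high = ci[2L], method = method,
             stringsAsFactors = FALSE)
}

#' Execution-assay analysis
#'
#' Per-group execution proportions with CIs plus the four planned Fisher
#' contrasts: social form x execution (all males); ploidy x execution
#' within polygyne colonies; haplotype x execution among polygyne haploid
#' males; and genotype (SB/Sb vs Sb/Sb) x execution among polygyne diploid
#' males. A contrast whose groups are empty is skipped with a warning.
#'
#' @param records An [execution_table()].
#' @param ci_method CI method for per-group proportions (default Wilson).
#' @return A list with `groups` (proportion table) and `contrasts` (named
#'   list of `sb_test` results; absent entries were skipped).
#' @export
execution_assay_analysis <- function(records, ci_method = "wilson") {
  stopifnot(inherits(records, "execution_tbl"))
  haploid <- records$ploidy_genotype %in% c("SB", "Sb")
  poly <- records$social_form == "polygyne"
  grp_def <- list(
    monogyne_all       = !poly,
    polygyne_all       = poly,
    polygyne_haploid   = poly & haploid,
    polygyne_diploid   = poly & !haploid,
    polygyne_SB        = poly & records$ploidy_genotype == "SB",
    polygyne_Sb        = poly & records$ploidy_genotype == "Sb",
    `polygyne_SB/Sb`   = poly & records$ploidy_genotype == "SB/Sb",
    `polygyne_Sb/Sb`   = poly & records$ploidy_genotype == "Sb/Sb"
  )
  groups <- do.call(rbind, lapply(names(grp_def), function(g) {
    sel <- grp_def[[g]]
    if (sum(sel) == 0L) return(NULL)
    ci <- proportion_ci(sum(records$executed[sel]), sum(sel), method = ci_method)
    cbind(data.frame(group = g, stringsAsFactors = FALSE), ci)
  }))
  contrast <- function(sel_a, sel_b, name) {
    if (sum(sel_a) == 0L || sum(sel_b) == 0L) {
      warning(sprintf("contrast '%s' skipped: empty group", name), call. = FALSE)
      return(NULL)
    }
    tab <- rbind(c(sum(records$executed[sel_a]), sum(!records$executed[sel_a])),
                 c(sum(records$executed[sel_b]), sum(!records$executed[sel_b])))
    fisher_exact_2x2(tab)
  }
  contrasts <- Filter(Negate(is.null), list(
    form_vs_execution      = contrast(poly, !poly, "form_vs_execution"),
    ploidy_within_polygyne = contrast(poly & haploid, poly & !haploid,
                                      "ploidy_within_polygyne"),
    haplotype_among_haploids = contrast(poly & records$ploidy_genotype == "SB",
                                        poly & records$ploidy_genotype == "Sb",
                                        "haplotype_among_haploids"),
    genotype_among_diploids = contrast(poly & records$ploidy_genotype == "SB/Sb",
                                       poly & records$ploidy_genotype == "Sb/Sb",
                                       "genotype_among_diploids")
  ))
  list(groups = groups, contrasts = contrasts)
}

sb_test <- function(test_name, statistic, df, p_value, alternative, inputs) {
  structure(list(test_name = test_name, statistic = statistic, df = df,
                 p_value = p_value, alternative = alternative,
                 inputs_digest = inputs),
            class = "sb_test")
}

#' @export
print.sb_test <- function(x, ...) {
  dfs <- if (is.null(x$df) || all(is.na(x$df))) "" else
    sprintf(", df = %s", paste(signif(x$df, 4), collapse = ", "))
  cat(sprintf("%s: statistic = %.4g%s, p = %.4g (%s)\n",
              x$test_name, x$statistic, dfs, x$p_value, x$alternative))
  invisible(x)
}
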