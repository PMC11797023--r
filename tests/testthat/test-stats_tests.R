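test_that("exact binomial test against 0.5 matches its closed forms", {
  expect_equal(binomial_test_vs_half(5L, 10L)$p_value, 1)
  expect_equal(binomial_test_vs_half(0L, 10L)$p_value, 2 * 0.5^10)
  expect_equal(binomial_test_vs_half(2L, 12L)$p_value, 0.038574, tolerance = 1e-5)
  expect_error(binomial_test_vs_half(11L, 10L), class = "sbdrive_input_error")
  expect_error(binomial_test_vs_half(-1L, 10L), class = "sbdrive_input_error")
})

test_that("binomial p-values agree with the enumeration oracle", {
  for (n in c(1L, 5L, 12L, 20L)) {
    for (k in 0:n) {
      expect_equal(binomial_test_vs_half(k, n)$p_value,
                   oracle_binom_two_sided(k, n),
                   tolerance = 1e-10, info = sprintf("k=%d n=%d", k, n))
    }
  }
})

test_that("Fisher's exact test matches enumeration and is transpose-invariant", {
  expect_equal(fisher_exact_2x2(matrix(c(1, 1, 1, 1), 2))$p_value, 1)
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2))$p_value, 2 / 252,
               tolerance = 1e-10)
  expect_equal(fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2))$p_value, 0.485714,
               tolerance = 1e-5)
  set.seed(19)
  for (i in 1:50) {
    tab <- matrix(rpois(4L, 4), 2L)
    p <- fisher_exact_2x2(tab)$p_value
    expect_equal(p, oracle_fisher_two_sided(tab), tolerance = 1e-9)
    expect_equal(p, fisher_exact_2x2(t(tab))$p_value, tolerance = 1e-12)
    expect_equal(p, fisher_exact_2x2(tab[2:1, ])$p_value, tolerance = 1e-12)
  }
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)),
               class = "sbdrive_input_error")
  expect_error(fisher_exact_2x2(matrix(0, 2, 2)), class = "sbdrive_input_error")
})

test_that("t tests recover the pooled-variance closed form", {
  same <- t_test(c(1, 2, 3), c(1, 2, 3), variant = "student")
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  st <- t_test(c(1, 2, 3), c(4, 5, 6), variant = "student")
  expect_equal(st$statistic, -3.674235, tolerance = 1e-6)
  expect_equal(st$df, 4)
  expect_equal(st$p_value, 0.021312, tolerance = 1e-4)

  w <- t_test(c(1, 2, 3), c(4, 5, 6), variant = "welch")
  expect_equal(w$statistic, st$statistic)  # equal variances: same t
  expect_error(t_test(c(1, 1), c(2, 3)), class = "sbdrive_input_error")
  expect_error(t_test(1, c(2, 3)), class = "sbdrive_input_error")
})

test_that("two-way ANOVA matches an independent least-squares decomposition", {
  set.seed(23)
  calls <- make_calls(
    colony_id = rep(c("A", "B"), each = 8L),
    genotype = rep(rep(c("SB", "Sb"), each = 4L), 2L),
    weight_mg = round(7 + rep(c(0.4, -0.4), each = 8L) +
                        rep(rep(c(0.5, -0.5), each = 4L), 2L) + rnorm(16, 0, 0.3), 3L)
  )
  res <- anova_weight(calls)

  # oracle: sequential SS via nested least squares fits
  d <- data.frame(w = calls$weight_mg, colony = factor(calls$colony_id),
                  hap = factor(calls$supergene_genotype))
  rss <- function(form) sum(residuals(lm(form, data = d))^2)
  ss_colony <- rss(w ~ 1) - rss(w ~ colony)
  ss_hap <- rss(w ~ colony) - rss(w ~ colony + hap)
  ss_int <- rss(w ~ colony + hap) - rss(w ~ colony * hap)
  ss_res <- rss(w ~ colony * hap)
  df_res <- 16 - 4
  expect_equal(res$colony$statistic, (ss_colony / 1) / (ss_res / df_res),
               tolerance = 1e-8)
  expect_equal(res$haplotype$statistic, (ss_hap / 1) / (ss_res / df_res),
               tolerance = 1e-8)
  expect_equal(res$interaction$statistic, (ss_int / 1) / (ss_res / df_res),
               tolerance = 1e-8)
  expect_equal(res$n_colonies, 2L)
})

test_that("ANOVA filtering keeps colonies with both haplotypes and reports df", {
  calls <- make_calls(
    colony_id = c("A", "A", "A", "B", "B", "C", "C", "C"),
    genotype = c("SB", "Sb", "Sb", "Sb", "Sb", "SB", "Sb", "SB"),
    weight_mg = c(7.1, 6.2, 6.0, 6.3, 6.1, 7.0, 6.4, 7.2)
  )
  res <- anova_weight(calls)  # colony B lacks SB and is excluded
  expect_equal(res$n_colonies, 2L)
  expect_equal(res$colony$df[1L], 1)
  expect_error(anova_weight(make_calls("A", c("SB", "Sb"), weight_mg = c(7, 6))),
               class = "sbdrive_input_error")
})

test_that("ANOVA degenerates gracefully when weights are constant", {
  calls <- make_calls(colony_id = rep(c("A", "B"), each = 4L),
                      genotype = rep(c("SB", "Sb"), 4L), weight_mg = 7)
  res <- anova_weight(calls)
  expect_equal(res$colony$statistic, 0)
  expect_equal(res$colony$p_value, 1)
})

test_that("Wilson intervals match the score formula and its symmetries", {
  ci <- proportion_ci(0L, 10L)
  expect_equal(ci$ci_low, 0)
  expect_true(ci$ci_high > 0)

  ci <- proportion_ci(14L, 26L)
  expect_equal(ci$ci_low, 0.3546, tolerance = 1e-3)
  expect_equal(ci$ci_high, 0.7125, tolerance = 1e-3)

  ci <- proportion_ci(5L, 10L)
  expect_equal(ci$ci_low, 1 - ci$ci_high, tolerance = 1e-12)
  expect_true(ci$ci_low <= ci$p_hat && ci$p_hat <= ci$ci_high)

  cp <- proportion_ci(14L, 26L, method = "clopper_pearson")
  expect_true(cp$ci_low <= 14 / 26 && cp$ci_high >= 14 / 26)
  expect_error(proportion_ci(3L, 0L), class = "sbdrive_input_error")
})

test_that("Wilson 95% coverage is near nominal", {
  n <- 50L
  # exact coverage: P(k) summed over the k whose Wilson interval covers p
  cis <- lapply(0:n, function(k) proportion_ci(k, n))
  for (p in c(0.1, 0.5)) {
    covers <- vapply(cis, function(ci) ci$ci_low <= p && p <= ci$ci_high,
                     logical(1L))
    cover <- sum(dbinom((0:n)[covers], n, p))
    expect_gte(cover, 0.93)
    expect_lte(cover, 0.98)
  }
})

test_that("the execution-assay analysis reports groups and planned contrasts", {
  set.seed(71)
  n <- 120L
  recs <- execution_table(data.frame(
    male_id = sprintf("e%03d", 1:(2 * n)),
    colony_id = "x",
    social_form = rep(c("monogyne", "polygyne"), each = n),
    ploidy_genotype = c(rep("Sb", n),
                        sample(c("SB", "Sb", "SB/Sb", "Sb/Sb"), n, replace = TRUE)),
    executed = c(runif(n) < 0.01,
                 runif(n) < 0.45),
    stringsAsFactors = FALSE
  ))
  out <- execution_assay_analysis(recs)
  expect_true(all(c("monogyne_all", "polygyne_all", "polygyne_haploid") %in%
                    out$groups$group))
  expect_true(out$contrasts$form_vs_execution$p_value < 0.001)
  expect_true(all(vapply(out$contrasts, function(t) t$p_value, 1) >= 0))

  # all-zero executions: every contrast is flat
  recs0 <- recs
  recs0$executed <- FALSE
  out0 <- execution_assay_analysis(recs0)
  expect_true(all(vapply(out0$contrasts, function(t) t$p_value, 1) == 1))

  # an empty group skips its contrast with a warning, others survive
  solo <- recs[recs$social_form == "polygyne", ]
  class(solo) <- class(recs)
  expect_warning(out1 <- execution_assay_analysis(solo), "skipped")
  expect_null(out1$contrasts$form_vs_execution)
  expect_false(is.null(out1$contrasts$ploidy_within_polygyne))
})
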