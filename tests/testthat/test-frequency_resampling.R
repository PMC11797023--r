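test_that("pooled frequency is the simple proportion with complementary rows", {
  calls <- make_calls(colony_id = "c1", genotype = c("SB", "SB", "SB", "Sb"))
  est <- pooled_frequency(calls, "adult", n_boot = 1000L, seed = 1L)
  expect_equal(est$point[est$haplotype == "SB"], 0.75)
  expect_equal(sum(est$point), 1)
  expect_true(all(est$ci_low <= est$point & est$point <= est$ci_high))
})

test_that("pooled frequency handles the degenerate all-Sb case", {
  calls <- make_calls(colony_id = "c1", genotype = rep("Sb", 8L))
  est <- pooled_frequency(calls, "adult", n_boot = 500L, seed = 1L)
  sb <- est[est$haplotype == "SB", ]
  expect_equal(sb$point, 0)
  expect_equal(c(sb$ci_low, sb$ci_high), c(0, 0))
  expect_error(pooled_frequency(calls, "pupa"), class = "sbdrive_input_error")
})

test_that("each replicate weighs colonies equally, not males", {
  # colony A: 100 SB males; colony B: a single Sb male. Every replicate
  # must hit exactly 0.5 although the pooled estimate is ~0.99.
  calls <- make_calls(colony_id = c(rep("A", 100L), "B"),
                      genotype = c(rep("SB", 100L), "Sb"))
  res <- colony_resampled_frequency(calls, "adult", n_reps = 200L, seed = 1L)
  reps <- attr(res, "replicates")
  expect_true(all(reps == 0.5))
  expect_equal(res$point[res$haplotype == "SB"], 0.5)
  pooled <- pooled_frequency(calls, "adult", n_boot = 100L, seed = 1L)
  expect_equal(pooled$point[pooled$haplotype == "SB"], 100 / 101)
})

test_that("an all-SB population gives a degenerate replicate stream of 1", {
  calls <- make_calls(colony_id = rep(c("A", "B", "C"), each = 4L),
                      genotype = "SB")
  res <- colony_resampled_frequency(calls, "adult", n_reps = 100L, seed = 2L)
  expect_true(all(attr(res, "replicates") == 1))
  expect_equal(res$point[res$haplotype == "SB"], 1)
})

test_that("resampled point matches the unweighted mean of colony frequencies", {
  # deterministic per-colony compositions with known f_c
  comps <- list(c(SB = 9L, Sb = 1L), c(SB = 1L, Sb = 4L), c(SB = 3L, Sb = 3L),
                c(SB = 0L, Sb = 7L), c(SB = 5L, Sb = 5L))
  calls <- make_calls(
    colony_id = rep(sprintf("c%d", seq_along(comps)),
                    vapply(comps, sum, integer(1L))),
    genotype = unlist(lapply(comps, function(x) rep(names(x), x)))
  )
  f_c <- vapply(comps, function(x) x[["SB"]] / sum(x), numeric(1L))
  res <- colony_resampled_frequency(calls, "adult", n_reps = 2000L, seed = 3L)
  reps <- attr(res, "replicates")
  mc_se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(res$point[res$haplotype == "SB"] - mean(f_c)), 3 * mc_se)
})

test_that("duplicating a colony's males moves the pooled but not the resampled estimate", {
  set.seed(17)
  calls <- make_calls(
    colony_id = rep(sprintf("c%d", 1:8), times = c(2, 5, 9, 3, 14, 6, 2, 4)),
    genotype = sample(c("SB", "Sb"), 45L, replace = TRUE, prob = c(0.3, 0.7))
  )
  dup <- calls[calls$colony_id == "c5", ]
  dup$male_id <- paste0(dup$male_id, "_dup")
  doubled <- rbind(calls, dup)
  class(doubled) <- class(calls)

  p1 <- pooled_frequency(calls, "adult", 100L, 1L)$point[1L]
  p2 <- pooled_frequency(doubled, "adult", 100L, 1L)$point[1L]
  expect_false(isTRUE(all.equal(p1, p2)))

  r1 <- colony_resampled_frequency(calls, "adult", n_reps = 4000L, seed = 1L)
  r2 <- colony_resampled_frequency(doubled, "adult", n_reps = 4000L, seed = 2L)
  se <- sqrt(sd(attr(r1, "replicates"))^2 / 4000 +
               sd(attr(r2, "replicates"))^2 / 4000)
  expect_lt(abs(r1$point[1L] - r2$point[1L]), 4 * se)
})

test_that("SB and Sb estimates are complementary for both methods", {
  set.seed(5)
  calls <- make_calls(colony_id = rep(sprintf("c%d", 1:6), each = 5L),
                      genotype = sample(c("SB", "Sb"), 30L, replace = TRUE))
  for (est in list(pooled_frequency(calls, "adult", 200L, 1L),
                   colony_resampled_frequency(calls, "adult", 200L, 1L))) {
    expect_equal(sum(est$point), 1)
    expect_equal(est$ci_low[1L], 1 - est$ci_high[2L], tolerance = 1e-12)
  }
})

test_that("identical seeds reproduce identical replicate streams", {
  calls <- make_calls(colony_id = rep(c("A", "B", "C"), each = 6L),
                      genotype = rep(c("SB", "Sb"), 9L),
                      weight_mg = rep(c(6, 7), 9L))
  a <- colony_resampled_frequency(calls, "adult", 300L, seed = 7L)
  b <- colony_resampled_frequency(calls, "adult", 300L, seed = 7L)
  expect_identical(attr(a, "replicates"), attr(b, "replicates"))
  w1 <- colony_resampled_weight(calls, "SB", n_reps = 300L, seed = 7L)
  w2 <- colony_resampled_weight(calls, "SB", n_reps = 300L, seed = 7L)
  expect_identical(attr(w1, "replicates"), attr(w2, "replicates"))
})

test_that("weight resampling averages one male per colony with one-tailed limits", {
  # constant weights: zero-width limits
  calls <- make_calls(colony_id = rep(c("A", "B"), each = 3L), genotype = "Sb",
                      weight_mg = 6.5)
  w <- colony_resampled_weight(calls, "Sb", n_reps = 100L, seed = 1L)
  expect_equal(w$point, 6.5)
  expect_equal(w$lower_limit, 6.5)
  expect_equal(w$upper_limit, 6.5)

  # two colonies with constant 6 and 8 mg: every replicate is exactly 7
  calls <- make_calls(colony_id = rep(c("A", "B"), each = 4L), genotype = "Sb",
                      weight_mg = rep(c(6, 8), each = 4L))
  w <- colony_resampled_weight(calls, "Sb", n_reps = 150L, seed = 2L)
  expect_true(all(attr(w, "replicates") == 7))

  # eligibility is per haplotype
  calls <- make_calls(colony_id = c("A", "A", "B"), genotype = c("SB", "Sb", "Sb"))
  expect_error(colony_resampled_weight(calls, "SB", n_reps = 10L, seed = 1L),
               class = "sbdrive_input_error")
})

test_that("the replicate-stream weight comparison behaves at the extremes", {
  set.seed(9)
  a <- rnorm(500, 7, 0.1); b <- rnorm(500, 7, 0.1)
  same <- resampled_weight_difference(a, b)
  expect_gt(same$frac_nonpositive, 0.35)
  expect_lt(same$frac_nonpositive, 0.65)

  apart <- resampled_weight_difference(rnorm(500, 8, 0.05), rnorm(500, 6, 0.05))
  expect_equal(apart$frac_nonpositive, 0)
  expect_match(apart$p_label, "P < ")
  expect_false(apart$limits_overlap)

  expect_error(resampled_weight_difference(a, b[-1L]), class = "sbdrive_input_error")
})
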