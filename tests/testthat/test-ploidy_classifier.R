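test_that("band pattern and microsatellite hemizygosity drive the call", {
  # two Gp-9 bands prove a heterozygous diploid regardless of microsatellites
  two <- classify_male(make_males(1L, gp9_bands = "517+423",
                                  Sol42_f = "118/122"))
  expect_equal(two$ploidy, "diploid")
  expect_equal(two$supergene_genotype, "SB/Sb")

  # single 423 band, all loci single-allele: confirmed haploid Sb
  hap <- classify_male(make_males(1L, gp9_bands = "423"),
                       freqs = default_allele_freqs())
  expect_equal(hap$ploidy, "haploid")
  expect_equal(hap$supergene_genotype, "Sb")
  expect_true(hap$confirmed_by_microsats)
  expect_equal(hap$n_heterozygous_loci, 0L)
  expect_false(is.na(hap$false_haploid_prob))

  # single 517 band with one heterozygous locus: diploid SB homozygote
  dip <- classify_male(make_males(1L, gp9_bands = "517", cassidy = "240/244"))
  expect_equal(dip$ploidy, "diploid")
  expect_equal(dip$supergene_genotype, "SB/SB")
  expect_equal(dip$n_heterozygous_loci, 1L)
})

test_that("missing microsatellite calls leave single-band males unresolved", {
  un <- classify_male(make_males(1L, gp9_bands = "423", Sol49 = "./."))
  expect_equal(un$ploidy, "unresolved")
  expect_true(is.na(un$supergene_genotype))
  # ...but cannot overturn a two-band diploid
  two <- classify_male(make_males(1L, gp9_bands = "517+423", Sol49 = "./."))
  expect_equal(two$ploidy, "diploid")
})

test_that("false-haploid probability follows the homozygosity product", {
  one_locus <- allele_freqs(list(L1 = c(A = 0.5, B = 0.5)))
  expect_equal(false_haploid_probability(one_locus), 0.5)

  expect_equal(false_haploid_probability(equifreq_panel(10L)), 1e-4)

  # the default panel was built to give the aggregate ~0.5%
  expect_lt(abs(false_haploid_probability(default_allele_freqs()) - 0.005), 0.001)

  expect_error(false_haploid_probability(one_locus, panel = character()),
               class = "sbdrive_input_error")
  expect_error(false_haploid_probability(one_locus, panel = "L2"),
               class = "sbdrive_input_error")

  # full inbreeding forces homozygosity at every locus
  expect_equal(false_haploid_probability(one_locus, f_is = 1), 1)
})

test_that("adding a locus never increases the false-haploid probability", {
  af <- default_allele_freqs()
  panels <- Reduce(c, names(af), accumulate = TRUE)
  probs <- vapply(panels, function(p) false_haploid_probability(af, panel = p),
                  numeric(1L))
  expect_true(all(diff(probs) <= 1e-15))
})

test_that("no record with an observed heterozygous locus is ever called haploid", {
  set.seed(31)
  af <- default_allele_freqs()
  loci <- names(af)
  for (i in 1:200) {
    geno <- lapply(loci, function(loc) {
      a <- sample(names(af[[loc]]), 2L, replace = TRUE)
      paste(a[1L], a[2L], sep = "/")
    })
    rec <- make_males(1L, gp9_bands = sample(c("517", "423", "517+423"), 1L),
                      Sol42_f = geno[[1L]], Sol49 = geno[[2L]],
                      C536 = geno[[3L]], cassidy = geno[[4L]])
    call <- classify_male(rec)
    if (call$n_heterozygous_loci > 0L) expect_false(call$ploidy == "haploid")
  }
})

test_that("summary counts reconcile and confusion against truth is clean", {
  p <- sim_params(seed = 21L)
  m <- simulate_population(p)
  cls <- classify_table(m, freqs = p$allele_freqs)
  s <- cls$summary
  expect_equal(s$n_confirmed_haploid + s$n_single_band_diploid,
               s$n_single_band - s$n_unresolved)
  expect_equal(sum(s$n_genotyped), nrow(m))

  cm <- ploidy_confusion(cls$calls, m)
  # haploids can never be mistaken for diploids (they have one allele)
  expect_equal(cm["haploid", "diploid"], 0)
  # false haploids are bounded by the panel misclassification probability
  n_dip <- sum(m$truth_ploidy == "diploid")
  fh <- false_haploid_probability(p$allele_freqs)
  expect_lte(cm["diploid", "haploid"],
             stats::qbinom(0.999, n_dip, fh) + 1)
})

test_that("an all-heterozygote table yields zero haploid calls", {
  m <- make_males(5L, gp9_bands = "517", Sol42_f = "118/122")
  cls <- classify_table(m)
  expect_equal(sum(cls$calls$ploidy == "haploid"), 0L)
})

test_that("realised false-haploid rate matches the closed form", {
  # synthetic diploids, homozygous at Gp-9, genotypes drawn from the panel
  set.seed(77)
  af <- default_allele_freqs()
  n <- 20000L
  geno <- lapply(names(af), function(loc) {
    a1 <- sample(names(af[[loc]]), n, replace = TRUE, prob = af[[loc]])
    a2 <- sample(names(af[[loc]]), n, replace = TRUE, prob = af[[loc]])
    paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
  })
  m <- make_males(n, male_id = sprintf("d%05d", 1:n), gp9_bands = "517",
                  Sol42_f = geno[[1L]], Sol49 = geno[[2L]],
                  C536 = geno[[3L]], cassidy = geno[[4L]])
  calls <- classify_table(m)$calls
  rate <- mean(calls$ploidy == "haploid")
  expected <- false_haploid_probability(af)
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(rate - expected), 3 * se)
})
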