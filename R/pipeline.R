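#' Resolve and validate a run configuration
#'
#' Reads a YAML or JSON configuration file (or starts from nothing) and
#' fills in the documented defaults: 500 one-male-per-colony replicates,
#' 5000 bootstrap replicates, 95% CIs, the 8.0 mg threshold / 0.25 mg bin /
#' 20-per-bin / 10.0 mg sampling design, and the four-locus panel. Unknown
#' keys are rejected by name and all problems are reported together, not
#' first-error-only.
#'
#' @param path Optional path to a `.yaml`/`.yml`/`.json` file.
#' @param overrides Named list applied on top of the file values.
#' @return A `run_config` list.
#' @export
validate_config <- function(path = NULL, overrides = list()) {
  defaults <- list(
    loci = default_locus_panel(), sep = "\t",
    n_reps = 500L, n_boot = 5000L, ci_level = 0.95, resampled_ci = "mean",
    weight_threshold = 8.0, bin_width = 0.25, bin_cap = 20L, upper_limit = 10.0,
    seed = 1L, simulate = TRUE, sim = list(),
    male_table = NULL, allele_freqs = NULL, execution_table = NULL,
    out_dir = NULL
  )
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) sb_io_error(sprintf("config file not found: %s", path))
    user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    if (is.null(user)) user <- list()
  }
  user <- modifyList(user, overrides)
  errors <- character()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0L) {
    errors <- c(errors, sprintf("unknown config key(s): %s",
                                paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(defaults, user[setdiff(names(user), unknown)])
  chk <- function(cond, msg) if (!isTRUE(cond)) errors <<- c(errors, msg)
  chk(is.numeric(cfg$n_reps) && cfg$n_reps >= 1, "n_reps must be >= 1")
  chk(is.numeric(cfg$n_boot) && cfg$n_boot >= 1, "n_boot must be >= 1")
  chk(is.numeric(cfg$ci_level) && cfg$ci_level > 0 && cfg$ci_level < 1,
      "ci_level must lie in (0, 1)")
  chk(is.numeric(cfg$weight_threshold) && cfg$weight_threshold > 0,
      "weight_threshold must be positive")
  chk(is.numeric(cfg$bin_width) && cfg$bin_width > 0, "bin_width must be positive")
  chk(is.numeric(cfg$bin_cap) && cfg$bin_cap >= 1, "bin_cap must be >= 1")
  chk(is.numeric(cfg$upper_limit) && cfg$upper_limit > cfg$weight_threshold,
      "upper_limit must exceed weight_threshold")
  chk(cfg$resampled_ci %in% c("mean", "percentile"),
      "resampled_ci must be 'mean' or 'percentile'")
  chk(is.character(cfg$loci) && length(cfg$loci) >= 1, "loci must name >= 1 locus")
  if (length(errors) > 0L) {
    sb_validation_error(paste(c("invalid configuration:", errors), collapse = "\n  - "))
  }
  cfg$n_reps <- as.integer(cfg$n_reps); cfg$n_boot <- as.integer(cfg$n_boot)
  cfg$bin_cap <- as.integer(cfg$bin_cap); cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

# Deterministic per-stage sub-seed derived from the master seed and the
# stage name, so adding a stage never perturbs the streams of earlier ones.
stage_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(master) * 7919 + h * 104729) %% 2147483647)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> sampling design -> classify ->
#' frequencies (pooled and colony-resampled, per stage) -> resampled
#' weights -> relatedness and effective queen number -> test battery ->
#' report. All randomness derives from one master seed via per-stage
#' sub-seeds.
#'
#' @param config A `run_config` from [validate_config()] (or `NULL` for all
#'   defaults).
#' @param out_dir Output directory for the report files; `NULL` skips
#'   writing.
#' @return A `pipeline_run` list: `config`, `seeds`, `males`, `calls`,
#'   `summary`, `frequencies`, `weights`, `relatedness`, `tests`,
#'   `execution`, and `paths` of written outputs.
#' @export
run_pipeline <- function(config = NULL, out_dir = NULL) {
  cfg <- if (is.null(config)) validate_config() else config
  stopifnot(inherits(cfg, "run_config"))
  out_dir <- out_dir %||% cfg$out_dir
  seeds <- vapply(c("simulate", "sampling", "pooled", "resampled", "weights",
                    "relatedness", "execution", "tests"),
                  function(s) stage_seed(cfg$seed, s), integer(1L))

  freqs <- if (is.null(cfg$allele_freqs)) default_allele_freqs() else
    if (is.character(cfg$allele_freqs)) read_allele_freqs(cfg$allele_freqs) else
      cfg$allele_freqs

  design <- list(threshold = cfg$weight_threshold, bin_width = cfg$bin_width,
                 bin_cap = cfg$bin_cap, upper_limit = cfg$upper_limit)
  exec_tbl <- NULL
  if (isTRUE(cfg$simulate)) {
    params <- do.call(sim_params, modifyList(
      list(allele_freqs = freqs, sampling_design = design,
           seed = seeds[["simulate"]]), cfg$sim))
    males <- simulate_population(params)
    males <- apply_sampling_design(males, design, seed = seeds[["sampling"]])
    exec_tbl <- simulate_execution_assay(males, params$execution_probs,
                                         seed = seeds[["execution"]])
    # monogyne control group: SB haploid males in monogyne assay colonies
    mono <- data.frame(male_id = sprintf("mono_%03d", 1:60),
                       colony_id = sprintf("mono_c%d", rep(1:6, each = 10L)),
                       ploidy_genotype = "SB", stringsAsFactors = FALSE)
    mono_tbl <- simulate_execution_assay(mono, params$execution_probs,
                                         seed = seeds[["execution"]] + 1L,
                                         social_form = "monogyne")
    exec_tbl <- execution_table(rbind(as.data.frame(exec_tbl),
                                      as.data.frame(mono_tbl)))
  } else {
    if (is.null(cfg$male_table)) {
      sb_validation_error("config must set simulate: true or a male_table path")
    }
    males <- read_male_table(cfg$male_table, loci = cfg$loci, sep = cfg$sep)
    if (!is.null(cfg$execution_table)) {
      exec_tbl <- read_execution_table(cfg$execution_table, sep = cfg$sep)
    }
  }

  cls <- classify_table(males, freqs = freqs, loci = intersect(cfg$loci, names(males)))
  calls <- cls$calls

  stages_present <- function(min_hap) {
    st <- c("adult", "pupa")
    st[vapply(st, function(s) sum(calls$ploidy == "haploid" & calls$stage == s) >= min_hap,
              logical(1L))]
  }
  freq_rows <- list()
  for (st in stages_present(1L)) {
    freq_rows[[paste0("pooled_", st)]] <-
      pooled_frequency(calls, st, n_boot = cfg$n_boot, seed = seeds[["pooled"]],
                       conf = cfg$ci_level)
    n_col <- length(unique(calls$colony_id[calls$ploidy == "haploid" &
                                             calls$stage == st]))
    if (n_col >= 2L) {
      freq_rows[[paste0("resampled_", st)]] <-
        colony_resampled_frequency(calls, st, n_reps = cfg$n_reps,
                                   seed = seeds[["resampled"]],
                                   ci = cfg$resampled_ci, conf = cfg$ci_level)
    }
  }
  frequencies <- if (length(freq_rows) > 0L) {
    common <- Reduce(intersect, lapply(freq_rows, names))
    do.call(rbind, lapply(freq_rows, function(d) d[, common, drop = FALSE]))
  } else NULL
  if (!is.null(frequencies)) rownames(frequencies) <- NULL

  weights <- NULL
  weight_reps <- list()
  for (hpl in c("SB", "Sb")) {
    w <- tryCatch(
      colony_resampled_weight(calls, hpl, stage = "adult", n_reps = cfg$n_reps,
                              seed = seeds[["weights"]], conf = cfg$ci_level),
      sbdrive_error = function(e) NULL)
    if (!is.null(w)) {
      weights <- rbind(weights, w)
      weight_reps[[hpl]] <- attr(w, "replicates")
    }
  }

  tests <- list()
  for (st in stages_present(1L)) {
    k <- sum(calls$ploidy == "haploid" & calls$stage == st &
               calls$supergene_genotype == "SB")
    n <- sum(calls$ploidy == "haploid" & calls$stage == st)
    tests[[paste0("binomial_", st)]] <- binomial_test_vs_half(k, n)
  }
  if (all(c("adult", "pupa") %in% stages_present(1L))) {
    tab <- vapply(c("adult", "pupa"), function(st) {
      c(sum(calls$ploidy == "haploid" & calls$stage == st &
              calls$supergene_genotype == "SB"),
        sum(calls$ploidy == "haploid" & calls$stage == st &
              calls$supergene_genotype == "Sb"))
    }, integer(2L))
    tests$adult_vs_pupa_fisher <- fisher_exact_2x2(t(tab))
  }
  sb_w <- calls$weight_mg[calls$ploidy == "haploid" & calls$stage == "adult" &
                            calls$supergene_genotype == "Sb"]
  SB_w <- calls$weight_mg[calls$ploidy == "haploid" & calls$stage == "adult" &
                            calls$supergene_genotype == "SB"]
  dip_w <- calls$weight_mg[calls$ploidy == "diploid" & calls$stage == "adult"]
  hap_w <- calls$weight_mg[calls$ploidy == "haploid" & calls$stage == "adult"]
  safe <- function(expr) tryCatch(expr, sbdrive_error = function(e) NULL)
  tests$weight_SB_vs_Sb <- safe(t_test(SB_w, sb_w))
  tests$weight_diploid_vs_haploid <- safe(t_test(dip_w, hap_w))
  aw <- safe(anova_weight(calls))
  if (!is.null(aw)) {
    tests$anova_colony <- aw$colony
    tests$anova_haplotype <- aw$haplotype
    tests$anova_interaction <- aw$interaction
  }
  if (length(weight_reps) == 2L) {
    tests$resampled_weight_diff <- NULL  # reported separately below
    wd <- resampled_weight_difference(weight_reps$SB, weight_reps$Sb)
  } else wd <- NULL

  relatedness <- list()
  for (st in c("adult", "pupa")) {
    relatedness[[st]] <- safe(colony_and_population_relatedness(
      males, calls, freqs, stage = st, n_boot = cfg$n_boot,
      seed = seeds[["relatedness"]]))
  }
  relatedness <- Filter(Negate(is.null), relatedness)
  queen_est <- NULL
  if (!is.null(relatedness$adult) && relatedness$adult$population$r > 0) {
    queen_est <- effective_queen_number(relatedness$adult$population$r)
  }
  if (length(relatedness) == 2L) {
    tests$relatedness_adult_vs_pupa <- local({
      bt <- bootstrap_difference_test(relatedness$adult$colonies$r,
                                      relatedness$pupa$colonies$r,
                                      n_iter = cfg$n_boot,
                                      seed = seeds[["relatedness"]])
      sb_test("bootstrap_difference_relatedness", statistic = bt$mean_diff,
              df = NULL, p_value = bt$p_value, alternative = "two_sided",
              inputs = sprintf("%d vs %d colonies",
                               nrow(relatedness$adult$colonies),
                               nrow(relatedness$pupa$colonies)))
    })
  }

  execution <- if (!is.null(exec_tbl)) execution_assay_analysis(exec_tbl) else NULL

  run <- structure(list(
    config = cfg, seeds = seeds, males = males, calls = calls,
    summary = cls$summary, frequencies = frequencies, weights = weights,
    weight_difference = wd, relatedness = relatedness,
    effective_queens = queen_est, tests = Filter(Negate(is.null), tests),
    execution = execution, execution_table = exec_tbl, paths = character()
  ), class = "pipeline_run")
  if (!is.null(out_dir)) run$paths <- write_report(run, out_dir)
  run
}

tests_to_df <- function(tests) {
  if (length(tests) == 0L) {
    return(data.frame(label = character(), test_name = character(),
                      statistic = numeric(), df = character(),
                      p_value = numeric(), alternative = character(),
                      inputs = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(names(tests), function(nm) {
    t <- tests[[nm]]
    data.frame(label = nm, test_name = t$test_name, statistic = t$statistic,
               df = if (is.null(t$df)) "" else paste(t$df, collapse = ";"),
               p_value = t$p_value, alternative = t$alternative,
               inputs = t$inputs_digest, stringsAsFactors = FALSE)
  }))
}

#' Write pipeline results to disk
#'
#' Emits machine-readable TSVs (classification counts, Table-1-style
#' frequency block, resampled weights, relatedness, test battery,
#' execution-assay proportions) plus a human-readable `report.txt` echoing
#' the configuration and seed. Outputs are deterministic given the inputs
#' and seed.
#'
#' @param run A `pipeline_run` (or a list with any subset of its result
#'   components; empty results give an empty-but-valid report).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written file paths.
#' @export
write_report <- function(run, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok) sb_io_error(sprintf("cannot create output directory: %s", dir))
  paths <- c()
  wr <- function(x, file) {
    p <- file.path(dir, file)
    write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[file]] <<- p
    p
  }
  if (!is.null(run$summary)) wr(run$summary, "classification_counts.tsv")
  if (!is.null(run$frequencies)) wr(run$frequencies, "frequencies.tsv")
  if (!is.null(run$weights)) wr(run$weights, "weights.tsv")
  if (length(run$relatedness %||% list()) > 0L) {
    wr(do.call(rbind, lapply(run$relatedness, `[[`, "population")),
       "relatedness_population.tsv")
    wr(do.call(rbind, lapply(run$relatedness, `[[`, "colonies")),
       "relatedness_colonies.tsv")
  }
  wr(tests_to_df(run$tests %||% list()), "tests.tsv")
  if (!is.null(run$execution)) wr(run$execution$groups, "execution_groups.tsv")

  rp <- file.path(dir, "report.txt")
  lines <- c("sbdrive pipeline report", strrep("=", 23), "")
  if (!is.null(run$config)) {
    lines <- c(lines, sprintf("master seed: %d", run$config$seed),
               sprintf("replicates: %d resampling / %d bootstrap",
                       run$config$n_reps, run$config$n_boot),
               sprintf("sampling design: all males < %.2f mg; %d per %.2f mg bin up to %.2f mg",
                       run$config$weight_threshold, run$config$bin_cap,
                       run$config$bin_width, run$config$upper_limit), "")
  }
  if (!is.null(run$summary)) {
    s <- run$summary
    lines <- c(lines, "classification counts:",
               sprintf("  %s: %d genotyped, %d single-band, %d confirmed haploid, %d unresolved",
                       s$stage, s$n_genotyped, s$n_single_band,
                       s$n_confirmed_haploid, s$n_unresolved), "")
  }
  if (!is.null(run$frequencies)) {
    f <- run$frequencies
    lines <- c(lines, "haplotype frequencies (point [95% CI]):",
               sprintf("  %-6s %-3s %-16s %.3f [%.3f, %.3f]",
                       f$stage, f$haplotype, f$method, f$point, f$ci_low, f$ci_high), "")
  }
  if (!is.null(run$weights)) {
    w <- run$weights
    lines <- c(lines, "resampled adult haploid weights (mg, one-tailed 95% limits):",
               sprintf("  %-3s %.2f [%.2f, %.2f]", w$haplotype, w$point,
                       w$lower_limit, w$upper_limit), "")
  }
  if (!is.null(run$effective_queens)) {
    q <- run$effective_queens
    lines <- c(lines, sprintf(
      "effective queen number (adults): %.2f (from nestmate r = %.3f, sibling r = %.2f)",
      q$n_e, q$r_input, q$sibling_r), "")
  }
  if (length(run$tests %||% list()) > 0L) {
    td <- tests_to_df(run$tests)
    lines <- c(lines, "test battery:",
               sprintf("  %-28s stat = %9.4g  p = %.4g", td$label, td$statistic,
                       td$p_value), "")
  }
  writeLines(lines, rp)
  paths[["report.txt"]] <- rp
  invisible(unlist(paths))
}
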