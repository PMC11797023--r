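#' Male sample tables
#'
#' A male table holds one row per sampled male: identifiers, life stage,
#' fresh weight in mg, the Gp-9 PCR band pattern, and the genotype at each
#' locus of the microsatellite panel. Genotypes are recorded as two allele
#' labels separated by `/` even for haploid males (equal labels): whether a
#' single-label observation reflects hemizygosity or homozygosity is an
#' inference made downstream, not an input distinction. A missing call is
#' written as the reserved label `.`; rows carrying one are retained but are
#' excluded from ploidy confirmation.
#'
#' Tables produced by [simulate_population()] additionally carry
#' `truth_ploidy`, `truth_genotype` and `truth_mother_id` ground-truth
#' columns.
#'
#' @param x A data.frame with columns `male_id`, `colony_id`, `stage`
#'   (`"adult"` or `"pupa"`), `weight_mg`, `gp9_bands` (e.g. `"517"`,
#'   `"423"`, `"517+423"`), and one column per panel locus holding `a/b`
#'   allele pairs.
#' @param loci Character vector naming the microsatellite panel columns.
#' @return A validated `male_tbl` (a data.frame subclass).
#' @export
male_table <- function(x, loci = default_locus_panel()) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  validate_male_table(x, loci = loci)
  attr(x, "loci") <- loci
  class(x) <- unique(c("male_tbl", class(x)))
  x
}

#' @rdname male_table
#' @export
validate_male_table <- function(x, loci = default_locus_panel()) {
  required <- c("male_id", "colony_id", "stage", "weight_mg", "gp9_bands", loci)
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0L) {
    sb_schema_error(sprintf(
      "male table is missing required column(s): %s",
      paste(missing_cols, collapse = ", ")
    ))
  }
  truth_cols <- c("truth_ploidy", "truth_genotype", "truth_mother_id")
  has_truth <- truth_cols %in% names(x)
  if (any(has_truth) && !all(has_truth)) {
    sb_schema_error("truth_* columns must be present together or not at all")
  }
  if (nrow(x) == 0L) return(invisible(x))

  bad <- function(test, what) {
    rows <- which(test)
    if (length(rows) > 0L) {
      sb_row_error(sprintf(
        "%s in row(s) %s", what,
        paste(utils::head(rows, 10L), collapse = ", ")
      ), rows = rows)
    }
  }
  w <- suppressWarnings(as.numeric(x$weight_mg))
  bad(is.na(w) | w <= 0, "unparseable or non-positive weight_mg")
  bad(!(x$stage %in% c("adult", "pupa")), "stage must be 'adult' or 'pupa'")
  bands <- lapply(x$gp9_bands, parse_bands)
  bad(vapply(bands, is.null, logical(1L)),
      sprintf("gp9_bands must be a non-empty subset of {%s}",
              paste(gp9_product_bp, collapse = ", ")))
  for (loc in loci) {
    g <- parse_genotypes(x[[loc]])
    bad(is.na(g[, 1L]) | is.na(g[, 2L]),
        sprintf("unparseable genotype at locus %s", loc))
  }
  if (any(has_truth)) {
    bad(!(x$truth_ploidy %in% c("haploid", "diploid")),
        "truth_ploidy must be 'haploid' or 'diploid'")
    bad(!(x$truth_genotype %in% supergene_genotypes),
        "truth_genotype must be a supergene genotype")
  }
  invisible(x)
}

# "517+423" -> c(517L, 423L); NULL if empty/invalid.
parse_bands <- function(s) {
  if (is.na(s) || !nzchar(s)) return(NULL)
  v <- suppressWarnings(as.integer(strsplit(as.character(s), "+", fixed = TRUE)[[1L]]))
  if (length(v) == 0L || anyNA(v) || !all(v %in% gp9_product_bp)) return(NULL)
  sort(unique(v), decreasing = TRUE)
}

format_bands <- function(v) paste(sort(unique(v), decreasing = TRUE), collapse = "+")

# Character vector of "a/b" strings -> 2-column character matrix of labels.
# NA in either column marks an unparseable entry; the reserved missing label
# "." parses fine and is handled by the classifier.
parse_genotypes <- function(g) {
  g <- as.character(g)
  ok <- !is.na(g) & grepl("^[^/]+/[^/]+$", g)
  a1 <- rep(NA_character_, length(g)); a2 <- a1
  a1[ok] <- sub("/.*$", "", g[ok])
  a2[ok] <- sub("^.*/", "", g[ok])
  cbind(a1 = a1, a2 = a2)
}

#' Read and write male tables
#'
#' Delimited text with a header row; tab-separated by default, comma via
#' `sep = ","`. Column names can be remapped with `col_map` (a named
#' character vector `c(file_column = "canonical_name")`) to accommodate
#' externally produced tables. Every row is validated against the male-table
#' invariants; malformed rows raise an error naming the row index rather
#' than being silently coerced.
#'
#' @param path File path.
#' @param loci Microsatellite panel column names.
#' @param sep Field separator (`"\t"` or `","`).
#' @param col_map Optional named character vector renaming file columns to
#'   the canonical schema.
#' @return `read_male_table()`: a validated [male_table()].
#' @export
read_male_table <- function(path, loci = default_locus_panel(), sep = "\t",
                            col_map = NULL) {
  if (!file.exists(path)) sb_io_error(sprintf("file not found: %s", path))
  x <- read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                  colClasses = "character", check.names = FALSE)
  if (!is.null(col_map)) {
    hit <- names(x) %in% names(col_map)
    names(x)[hit] <- unname(col_map[names(x)[hit]])
  }
  known <- c("male_id", "colony_id", "stage", "weight_mg", "gp9_bands", loci,
             "truth_ploidy", "truth_genotype", "truth_mother_id")
  unknown <- setdiff(names(x), known)
  if (length(unknown) > 0L) {
    sb_schema_error(sprintf("unknown column(s) in male table: %s (configured loci: %s)",
                            paste(unknown, collapse = ", "),
                            paste(loci, collapse = ", ")))
  }
  if ("weight_mg" %in% names(x)) {
    w <- suppressWarnings(as.numeric(x$weight_mg))
    rows <- which(is.na(w) & !is.na(x$weight_mg))
    if (length(rows) > 0L) {
      sb_row_error(sprintf("unparseable weight_mg in row(s) %s",
                           paste(utils::head(rows, 10L), collapse = ", ")),
                   rows = rows)
    }
    x$weight_mg <- w
  }
  male_table(x, loci = loci)
}

#' @rdname read_male_table
#' @param x A `male_tbl`.
#' @export
write_male_table <- function(x, path, sep = "\t") {
  stopifnot(inherits(x, "male_tbl"))
  ok <- tryCatch({
    write.table(x, path, sep = sep, quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) sb_io_error(sprintf("cannot write male table to %s", path))
  invisible(path)
}

#' Allele-frequency tables
#'
#' Per-locus allele frequencies for the microsatellite panel, used both to
#' quantify the false-haploid misclassification probability and as the
#' reference (base) population for relatedness estimation. Stored as a named
#' list mapping locus name to a named numeric vector of frequencies that sum
#' to one.
#'
#' @param x A named list of named numeric vectors (locus -> allele -> freq).
#' @return An `allele_freqs` object.
#' @export
allele_freqs <- function(x) {
  if (!is.list(x) || is.null(names(x)) || any(!nzchar(names(x)))) {
    sb_validation_error("allele frequencies must be a named list of named numeric vectors")
  }
  for (loc in names(x)) {
    p <- x[[loc]]
    if (!is.numeric(p) || is.null(names(p)) || any(!nzchar(names(p)))) {
      sb_validation_error(sprintf("locus %s: frequencies must be a named numeric vector", loc))
    }
    if (any(p < 0)) sb_validation_error(sprintf("locus %s: negative frequency", loc))
    s <- sum(p)
    if (abs(s - 1) > 1e-6) {
      sb_validation_error(sprintf("locus %s: frequencies sum to %.8f, not 1", loc, s))
    }
    if (sum(p > 0) < 2L) {
      sb_validation_error(sprintf("locus %s: needs >= 2 alleles with positive frequency", loc))
    }
    x[[loc]] <- p / s
  }
  structure(x, class = c("allele_freqs", "list"))
}

#' @rdname allele_freqs
#' @param path Path to a long-format delimited file with columns
#'   `locus`, `allele` and either `frequency` or `count` (counts are
#'   normalised per locus).
#' @param sep Field separator.
#' @export
read_allele_freqs <- function(path, sep = "\t") {
  if (!file.exists(path)) sb_io_error(sprintf("file not found: %s", path))
  x <- read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("locus", "allele") %in% names(x))) {
    sb_schema_error("allele-frequency table needs columns locus, allele, and frequency or count")
  }
  value_col <- intersect(c("frequency", "count"), names(x))
  if (length(value_col) == 0L) {
    sb_schema_error("allele-frequency table needs a 'frequency' or 'count' column")
  }
  value_col <- value_col[1L]
  v <- suppressWarnings(as.numeric(x[[value_col]]))
  if (anyNA(v)) sb_validation_error(sprintf("unparseable %s values", value_col))
  out <- lapply(split(seq_len(nrow(x)), factor(x$locus, levels = unique(x$locus))),
                function(idx) {
    p <- setNames(v[idx], as.character(x$allele[idx]))
    if (value_col == "count") p <- p / sum(p)
    p
  })
  allele_freqs(out)
}

#' @rdname allele_freqs
#' @export
write_allele_freqs <- function(x, path, sep = "\t") {
  stopifnot(inherits(x, "allele_freqs"))
  long <- do.call(rbind, lapply(names(x), function(loc) {
    data.frame(locus = loc, allele = names(x[[loc]]),
               frequency = unname(x[[loc]]), stringsAsFactors = FALSE)
  }))
  write.table(long, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Execution-assay record tables
#'
#' One row per male presented to workers in an execution assay: the colony
#' form of the assay colony, the male's ploidy/supergene class, whether the
#' trial was scored as an execution, and (for executed males) the hourly
#' observation at which it was scored, on a 0-12 h clock.
#'
#' @param x A data.frame with columns `male_id`, `colony_id`, `social_form`
#'   (`"monogyne"`/`"polygyne"`), `ploidy_genotype` (one of `SB`, `Sb`,
#'   `SB/SB`, `SB/Sb`, `Sb/Sb`), `executed` (logical), and optionally
#'   `hour_observed`.
#' @return A validated `execution_tbl` data.frame.
#' @export
execution_table <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  required <- c("male_id", "colony_id", "social_form", "ploidy_genotype", "executed")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0L) {
    sb_schema_error(sprintf("execution table missing column(s): %s",
                            paste(missing_cols, collapse = ", ")))
  }
  if (!all(x$social_form %in% c("monogyne", "polygyne"))) {
    sb_validation_error("social_form must be 'monogyne' or 'polygyne'")
  }
  if (!all(x$ploidy_genotype %in% supergene_genotypes)) {
    sb_validation_error("ploidy_genotype must be a supergene genotype")
  }
  x$executed <- as.logical(x$executed)
  if (anyNA(x$executed)) sb_validation_error("executed must be TRUE/FALSE")
  if ("hour_observed" %in% names(x)) {
    h <- suppressWarnings(as.numeric(x$hour_observed))
    bad <- !is.na(h) & (h < 0 | h > 12 | h != round(h))
    if (any(bad)) {
      sb_row_error(sprintf("hour_observed must be an integer in [0, 12]; bad row(s) %s",
                           paste(utils::head(which(bad), 10L), collapse = ", ")),
                   rows = which(bad))
    }
    x$hour_observed <- as.integer(h)
  }
  class(x) <- unique(c("execution_tbl", class(x)))
  x
}

#' @rdname execution_table
#' @param path,sep File path and field separator.
#' @export
read_execution_table <- function(path, sep = "\t") {
  if (!file.exists(path)) sb_io_error(sprintf("file not found: %s", path))
  execution_table(read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE))
}
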