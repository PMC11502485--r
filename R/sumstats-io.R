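#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>% filter mutate select arrange left_join bind_rows
NULL

SUMSTATS_COLUMNS <- c(
  "variant_id", "chrom", "pos", "effect_allele", "other_allele",
  "eaf", "beta", "se", "pval", "n"
)

#' Construct a validated GWAS summary-statistics table
#'
#' A summary-statistics table holds one association record per variant:
#' alleles, effect-allele frequency, effect size (`beta`), its standard
#' error, p-value and study sample size. All downstream harmonization and
#' Mendelian-randomization machinery consumes this container.
#'
#' @param df Data frame with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#'   `eaf` may be `NA` (some GWAS sources omit frequencies); all other
#'   fields are mandatory.
#' @param trait_name,trait_units Optional trait metadata, stored as
#'   attributes.
#' @param on_invalid `"error"` (default) aborts with row-level messages;
#'   `"drop"` removes offending rows and records them in the
#'   `"diagnostics"` attribute so that every input row is accounted for.
#' @return A `sumstats` tibble in canonical column order.
#' @export
sumstats <- function(df, trait_name = NA_character_, trait_units = NA_character_,
                     on_invalid = c("error", "drop")) {
  on_invalid <- match.arg(on_invalid)
  df <- as_tibble(df)
  missing_cols <- setdiff(setdiff(SUMSTATS_COLUMNS, "eaf"), names(df))
  if (length(missing_cols) > 0) {
    stopf("missing mandatory column(s): %s", paste(missing_cols, collapse = ", "))
  }
  if (!"eaf" %in% names(df)) df$eaf <- NA_real_
  df <- df[SUMSTATS_COLUMNS]
  df$variant_id <- as.character(df$variant_id)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("eaf", "beta", "se", "pval")) df[[col]] <- as.numeric(df[[col]])
  df$n <- as.integer(df$n)

  problems <- validate_sumstats_rows(df)
  if (nrow(problems) > 0) {
    if (on_invalid == "error") {
      stopf(
        "invalid summary-statistics rows:\n%s",
        paste(sprintf("  row %d (%s): %s", problems$row, problems$variant_id,
                      problems$problem), collapse = "\n")
      )
    }
    df <- df[-unique(problems$row), , drop = FALSE]
  }
  if (anyDuplicated(df$variant_id)) {
    stopf("duplicate variant_id: %s",
          paste(unique(df$variant_id[duplicated(df$variant_id)]), collapse = ", "))
  }
  structure(df,
    trait_name = trait_name, trait_units = trait_units,
    diagnostics = problems,
    class = c("sumstats", class(df))
  )
}

validate_sumstats_rows <- function(df) {
  bad <- list()
  flag <- function(idx, problem) {
    if (any(idx)) {
      bad[[length(bad) + 1]] <<- tibble(
        row = which(idx), variant_id = df$variant_id[idx], problem = problem
      )
    }
  }
  valid_allele <- function(a) !is.na(a) & a %in% names(DNA_COMPLEMENT)
  flag(is.na(df$variant_id) | df$variant_id == "", "missing variant_id")
  flag(!valid_allele(df$effect_allele), "effect_allele not a single base in {A,C,G,T}")
  flag(!valid_allele(df$other_allele), "other_allele not a single base in {A,C,G,T}")
  flag(valid_allele(df$effect_allele) & valid_allele(df$other_allele) &
         df$effect_allele == df$other_allele, "effect_allele equals other_allele")
  flag(is.na(df$pos) | df$pos < 1L, "pos must be >= 1")
  flag(!is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1), "eaf outside [0,1]")
  flag(is.na(df$beta) | !is.finite(df$beta), "beta missing or non-finite")
  flag(is.na(df$se) | !is.finite(df$se) | df$se <= 0, "se must be finite and > 0")
  flag(is.na(df$pval) | df$pval <= 0 | df$pval > 1, "pval outside (0,1]")
  flag(is.na(df$n) | df$n <= 1L, "n must be an integer > 1")
  if (length(bad) == 0) {
    return(tibble(row = integer(), variant_id = character(), problem = character()))
  }
  arrange(bind_rows(bad), row)
}

#' Read a GWAS summary-statistics table from TSV
#'
#' Reads a tab-separated file with a header row into a validated
#' [sumstats] table. Non-canonical column headers are renamed through
#' `column_map` so heterogeneous GWAS dialects can be ingested.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param column_map Named character vector mapping file column names to
#'   canonical names, e.g. `c(SNP = "variant_id", A1 = "effect_allele")`.
#' @inheritParams sumstats
#' @return A `sumstats` tibble.
#' @export
read_sumstats <- function(path, column_map = NULL, trait_name = NA_character_,
                          trait_units = NA_character_,
                          on_invalid = c("error", "drop")) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = "NA",
                          colClasses = "character", check.names = FALSE)
  if (!is.null(column_map)) {
    hit <- names(df) %in% names(column_map)
    names(df)[hit] <- unname(column_map[names(df)[hit]])
  }
  missing_cols <- setdiff(setdiff(SUMSTATS_COLUMNS, "eaf"), names(df))
  if (length(missing_cols) > 0) {
    stopf("file %s lacks mandatory column(s): %s", path,
          paste(missing_cols, collapse = ", "))
  }
  sumstats(df, trait_name = trait_name, trait_units = trait_units,
           on_invalid = on_invalid)
}

#' Write a summary-statistics table to TSV
#'
#' Writes canonical column order with full-precision reals (`%.17g`), so
#' `read_sumstats(write_sumstats(x))` reproduces `x` exactly. Missing `eaf`
#' is serialized as the token `NA`.
#'
#' @param table A [sumstats] table (any data frame with canonical columns
#'   is accepted).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(table, path) {
  df <- as.data.frame(table)[SUMSTATS_COLUMNS]
  out <- data.frame(
    variant_id = df$variant_id, chrom = df$chrom,
    pos = as.character(df$pos),
    effect_allele = df$effect_allele, other_allele = df$other_allele,
    eaf = num_full(df$eaf), beta = num_full(df$beta), se = num_full(df$se),
    pval = num_full(df$pval), n = as.character(df$n),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

num_full <- function(x) ifelse(is.na(x), NA_character_, sprintf("%.17g", x))

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("<sumstats> %s records; trait: %s (%s)\n", nrow(x),
              attr(x, "trait_name") %||% NA, attr(x, "trait_units") %||% NA))
  NextMethod()
}
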