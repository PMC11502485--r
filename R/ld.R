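#' Construct an LD reference from pairwise r-squared values
#'
#' The LD reference is the proxy-lookup backend: a long-format table of
#' pairwise r-squared values plus variant positions. Lookup is symmetric,
#' a variant's r-squared with itself is 1 even when no self-pair is stored,
#' and a pair absent from the table is *unknown* (`NA`), never assumed 0.
#'
#' @param pairs Data frame with columns `variant_id_a`, `variant_id_b`,
#'   `r2` (each in `[0,1]`).
#' @param positions Data frame with columns `variant_id`, `chrom`, `pos`.
#' @return An object of class `ld_reference`.
#' @export
ld_reference <- function(pairs, positions) {
  pairs <- tibble::as_tibble(pairs)
  positions <- tibble::as_tibble(positions)
  need_p <- c("variant_id_a", "variant_id_b", "r2")
  if (!all(need_p %in% names(pairs))) {
    stopf("LD pairs need columns: %s", paste(need_p, collapse = ", "))
  }
  if (!all(c("variant_id", "chrom", "pos") %in% names(positions))) {
    stopf("LD positions need columns: variant_id, chrom, pos")
  }
  pairs$r2 <- as.numeric(pairs$r2)
  bad <- which(is.na(pairs$r2) | pairs$r2 < 0 | pairs$r2 > 1)
  if (length(bad) > 0) {
    stopf("r2 outside [0,1] at pair row(s): %s", paste(bad, collapse = ", "))
  }
  pairs <- pairs[pairs$variant_id_a != pairs$variant_id_b, , drop = FALSE]
  lut <- new.env(parent = emptyenv(), size = max(2L * nrow(pairs), 16L))
  for (i in seq_len(nrow(pairs))) {
    assign(pair_key(pairs$variant_id_a[i], pairs$variant_id_b[i]),
           pairs$r2[i], envir = lut)
  }
  positions$variant_id <- as.character(positions$variant_id)
  positions$chrom <- as.character(positions$chrom)
  positions$pos <- as.integer(positions$pos)
  structure(
    list(pairs = pairs, positions = positions, lut = lut),
    class = "ld_reference"
  )
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Read an LD reference from TSV files
#'
#' @param pairs_path TSV with columns `variant_id_a`, `variant_id_b`, `r2`.
#' @param positions_path TSV with columns `variant_id`, `chrom`, `pos`.
#' @return An `ld_reference` object.
#' @export
read_ld_reference <- function(pairs_path, positions_path) {
  for (p in c(pairs_path, positions_path)) {
    if (!file.exists(p)) stopf("file not found: %s", p)
  }
  pairs <- utils::read.delim(pairs_path, sep = "\t", stringsAsFactors = FALSE)
  positions <- utils::read.delim(positions_path, sep = "\t",
                                 stringsAsFactors = FALSE)
  ld_reference(pairs, positions)
}

#' Pairwise r-squared lookup
#'
#' Symmetric: `ld_r2(ld, a, b) == ld_r2(ld, b, a)`. Self-pairs return 1.
#' Unknown pairs return `NA` (r-squared not measured, *not* zero).
#'
#' @param ld An `ld_reference`.
#' @param a,b Variant identifiers.
#' @return Numeric r-squared, or `NA` if the pair is absent.
#' @export
ld_r2 <- function(ld, a, b) {
  stopifnot(inherits(ld, "ld_reference"))
  if (a == b) return(1)
  get0(pair_key(a, b), envir = ld$lut, ifnotfound = NA_real_)
}

ld_position <- function(ld, id) {
  i <- match(id, ld$positions$variant_id)
  if (is.na(i)) return(NULL)
  list(chrom = ld$positions$chrom[i], pos = ld$positions$pos[i])
}

# all stored partners of `id` with their r2
ld_partners <- function(ld, id) {
  p <- ld$pairs
  hit_a <- p$variant_id_a == id
  hit_b <- p$variant_id_b == id
  tibble::tibble(
    variant_id = c(p$variant_id_b[hit_a], p$variant_id_a[hit_b]),
    r2 = c(p$r2[hit_a], p$r2[hit_b])
  )
}

#' @export
print.ld_reference <- function(x, ...) {
  cat(sprintf("<ld_reference> %d pairs, %d positioned variants\n",
              nrow(x$pairs), nrow(x$positions)))
  invisible(x)
}
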