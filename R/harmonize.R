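#' Select genome-wide-significant instruments
#'
#' Returns exactly the exposure records with `pval` strictly below the
#' threshold (boundary equality is excluded, matching the conventional
#' P < 5e-8 genome-wide criterion).
#'
#' @param exposure A [sumstats] table.
#' @param p_threshold Significance threshold in (0,1); default `5e-8`.
#' @return The selected rows, as a tibble.
#' @export
select_instruments <- function(exposure, p_threshold = 5e-8) {
  if (!is.numeric(p_threshold) || length(p_threshold) != 1 ||
      p_threshold <= 0 || p_threshold >= 1) {
    stopf("p_threshold must be a single number in (0,1)")
  }
  tibble::as_tibble(as.data.frame(exposure))[
    which(exposure$pval < p_threshold), , drop = FALSE]
}

#' Align association records onto a reference allele frame
#'
#' Re-expresses each row of `other` on the corresponding `reference` row's
#' effect allele. Matching allele labels pass through unchanged; swapped
#' labels negate `beta` and complement `eaf`; strand-complement labels are
#' relabelled without a sign change. Palindromic variants (A/T or G/C),
#' whose strand cannot be resolved from labels, are aligned by allele-
#' frequency concordance when frequencies are informative and dropped as
#' `"palindromic-ambiguous"` when `eaf` is missing or within
#' `0.5 +/- palindrome_window` in either record.
#'
#' @param reference,other Data frames (row-matched) with columns
#'   `effect_allele`, `other_allele`, `eaf`, `beta`.
#' @param palindrome_window Half-width of the ambiguous frequency band
#'   around 0.5; default 0.08.
#' @return `other` with `beta`/`eaf`/alleles aligned to `reference`, plus
#'   `status` (`"ok"` or `"dropped"`) and `reason` columns.
#' @export
align_alleles <- function(reference, other, palindrome_window = 0.08) {
  stopifnot(nrow(reference) == nrow(other))
  n <- nrow(other)
  out <- tibble::as_tibble(other)
  out$status <- rep("ok", n)
  out$reason <- rep(NA_character_, n)
  if (n == 0) return(out)

  ra <- toupper(reference$effect_allele); rb <- toupper(reference$other_allele)
  oa <- toupper(other$effect_allele);     ob <- toupper(other$other_allele)
  ca <- DNA_COMPLEMENT[oa]; cb <- DNA_COMPLEMENT[ob]

  pal <- is_palindromic(ra, rb)
  direct <- (oa == ra & ob == rb) | (oa == rb & ob == ra)
  compl  <- !pal & !direct & ((ca == ra & cb == rb) | (ca == rb & cb == ra))
  mismatch <- !direct & !compl

  beta <- other$beta
  eaf <- other$eaf

  # strand-complement labels: relabel, no sign change
  oa[compl] <- ca[compl]; ob[compl] <- cb[compl]

  swapped <- !mismatch & oa == rb
  beta[swapped] <- -beta[swapped]
  eaf[swapped] <- 1 - eaf[swapped]

  # palindromic: labels cannot resolve strand; use frequency concordance
  amb <- pal & !mismatch &
    (is.na(reference$eaf) | is.na(eaf) |
       abs(reference$eaf - 0.5) < palindrome_window |
       abs(eaf - 0.5) < palindrome_window)
  flip <- pal & !mismatch & !amb &
    ((reference$eaf < 0.5) != (eaf < 0.5))
  beta[flip] <- -beta[flip]
  eaf[flip] <- 1 - eaf[flip]

  out$beta <- beta
  out$eaf <- eaf
  out$effect_allele <- ra
  out$other_allele <- rb
  out$status[mismatch | amb] <- "dropped"
  out$reason[mismatch] <- "allele-mismatch"
  out$reason[amb] <- "palindromic-ambiguous"
  out
}

#' Orient harmonized records to the exposure-increasing allele
#'
#' Records with a negative SNP-exposure effect have all three betas
#' negated, alleles swapped and `eaf` complemented, so that after
#' orientation every record's effect allele is the exposure-increasing
#' allele (`beta_x >= 0`). Records with `beta_x` exactly 0 cannot define an
#' increasing allele and are flagged `orientable = FALSE`. The map is
#' idempotent: applying it twice equals applying it once.
#'
#' @param records Tibble of harmonized records with columns
#'   `effect_allele`, `other_allele`, `eaf`, `beta_x`, `beta_z`, `beta_y`.
#' @return The oriented tibble with a logical `orientable` column.
#' @export
orient_to_exposure_increasing <- function(records) {
  r <- tibble::as_tibble(records)
  if (nrow(r) == 0) {
    r$orientable <- logical(0)
    return(r)
  }
  neg <- !is.na(r$beta_x) & r$beta_x < 0
  ea <- r$effect_allele
  r$effect_allele[neg] <- r$other_allele[neg]
  r$other_allele[neg] <- ea[neg]
  if ("eaf" %in% names(r)) r$eaf[neg] <- 1 - r$eaf[neg]
  for (col in intersect(c("beta_x", "beta_z", "beta_y"), names(r))) {
    r[[col]][neg] <- -r[[col]][neg]
  }
  r$orientable <- !is.na(r$beta_x) & r$beta_x != 0
  r
}

#' Find an LD proxy for a variant absent from a target table
#'
#' Searches the target table for the best available stand-in: a variant
#' within `max_dist` base pairs of the index position whose known
#' r-squared with the index exceeds `r2_min` (strict). Candidates are
#' ranked by r-squared (descending), then base-pair distance (ascending),
#' then variant id, making the choice deterministic. An index variant that
#' is itself present in the target is returned as its own proxy with
#' r-squared 1.
#'
#' @param variant_id Index variant identifier.
#' @param target A [sumstats] table to search.
#' @param ld An `ld_reference` (may be `NULL`: no proxying).
#' @param r2_min Minimum r-squared, exclusive; default 0.7.
#' @param max_dist Maximum distance in base pairs; default 1e6.
#' @return A list with `proxy_id`, `r2` and `reason` (`NA` on success,
#'   otherwise `"no-proxy"` or `"no-position"`).
#' @export
find_proxy <- function(variant_id, target, ld, r2_min = 0.7, max_dist = 1e6) {
  none <- function(reason) list(proxy_id = NA_character_, r2 = NA_real_,
                                reason = reason)
  if (variant_id %in% target$variant_id) {
    return(list(proxy_id = variant_id, r2 = 1, reason = NA_character_))
  }
  if (is.null(ld)) return(none("no-proxy"))
  idx <- ld_position(ld, variant_id)
  if (is.null(idx)) return(none("no-position"))
  partners <- ld_partners(ld, variant_id)
  partners <- partners[partners$variant_id %in% target$variant_id &
                         !is.na(partners$r2) & partners$r2 > r2_min, ,
                       drop = FALSE]
  if (nrow(partners) == 0) return(none("no-proxy"))
  pos <- ld$positions[match(partners$variant_id, ld$positions$variant_id), ]
  keep <- !is.na(pos$pos) & pos$chrom == idx$chrom &
    abs(pos$pos - idx$pos) <= max_dist
  partners <- partners[keep, , drop = FALSE]
  dist <- abs(pos$pos[keep] - idx$pos)
  if (nrow(partners) == 0) return(none("no-proxy"))
  ord <- order(-partners$r2, dist, partners$variant_id)[1]
  list(proxy_id = partners$variant_id[ord], r2 = partners$r2[ord],
       reason = NA_character_)
}

#' Build the analysis-ready harmonized instrument set
#'
#' Runs the full instrument-construction chain: select exposure variants
#' below `p_threshold`, locate each in the outcome and indicator tables
#' (substituting LD proxies where absent), align alleles onto the exposure
#' frame, and orient every record to the exposure-increasing allele.
#' Instruments are assumed to be pre-resolved independent signals; no LD
#' clumping is performed.
#'
#' A variant absent from the outcome with no usable proxy is dropped
#' (`"no-proxy"`); one absent from the indicator is kept with a missing
#' indicator association (it remains usable unstratified and falls in the
#' unclassified stratum). Every selected instrument appears in the
#' provenance exactly once, so `selected = kept + dropped` always holds.
#'
#' @param exposure,indicator,outcome [sumstats] tables.
#' @param ld An `ld_reference`, or `NULL` to disable proxy search.
#' @param p_threshold Instrument-selection p-value threshold (strict `<`).
#' @param r2_min,max_dist Proxy-search parameters; see [find_proxy()].
#' @param palindrome_window See [align_alleles()].
#' @return A `harmonized_set`: list with `records` (one row per kept
#'   instrument: exposure `beta_x/se_x/p_x/n_x`, indicator
#'   `beta_z/se_z/n_z`, outcome `beta_y/se_y/n_y`, proxy bookkeeping) and
#'   `provenance` (per selected instrument: status, reason, proxy ids).
#' @export
build_instrument_set <- function(exposure, indicator, outcome, ld = NULL,
                                 p_threshold = 5e-8, r2_min = 0.7,
                                 max_dist = 1e6, palindrome_window = 0.08) {
  sel <- select_instruments(exposure, p_threshold)
  n <- nrow(sel)
  prov <- tibble::tibble(
    variant_id = sel$variant_id,
    status = rep("kept", n), reason = rep(NA_character_, n),
    proxy_of = rep(NA_character_, n), proxy_r2 = rep(NA_real_, n),
    indicator_proxy = rep(NA_character_, n),
    indicator_proxy_r2 = rep(NA_real_, n)
  )
  if (n == 0) return(new_harmonized_set(empty_records(), prov))

  pull <- pull_associations(sel, outcome, ld, r2_min, max_dist,
                            palindrome_window)
  y <- pull$assoc
  prov$proxy_of <- pull$proxy_id
  prov$proxy_r2 <- pull$proxy_r2

  pull_z <- pull_associations(sel, indicator, ld, r2_min, max_dist,
                              palindrome_window)
  z <- pull_z$assoc
  prov$indicator_proxy <- pull_z$proxy_id
  prov$indicator_proxy_r2 <- pull_z$proxy_r2

  records <- tibble::tibble(
    variant_id = sel$variant_id,
    chrom = sel$chrom, pos = sel$pos,
    effect_allele = sel$effect_allele, other_allele = sel$other_allele,
    eaf = sel$eaf,
    proxy_of = ifelse(pull$proxy_id == sel$variant_id, NA_character_,
                      pull$proxy_id),
    proxy_r2 = pull$proxy_r2,
    beta_x = sel$beta, se_x = sel$se, p_x = sel$pval, n_x = sel$n,
    beta_z = z$beta, se_z = z$se, n_z = z$n,
    beta_y = y$beta, se_y = y$se, n_y = y$n
  )

  drop_y <- is.na(y$beta)
  prov$status[drop_y] <- "dropped"
  prov$reason[drop_y] <- y$reason[drop_y]
  # indicator failures are soft: the record stays, unclassifiable
  records$beta_z[is.na(z$beta)] <- NA_real_
  records$se_z[is.na(z$beta)] <- NA_real_

  zero_x <- !drop_y & records$beta_x == 0
  prov$status[zero_x] <- "dropped"
  prov$reason[zero_x] <- "zero-exposure-effect"

  keep <- !(drop_y | zero_x)
  proxied <- keep & !is.na(records$proxy_of)
  prov$status[proxied] <- "proxied"

  records <- orient_to_exposure_increasing(records[keep, , drop = FALSE])
  new_harmonized_set(records, prov)
}

# Locate each selected instrument in `target` (directly or via proxy) and
# return its association aligned to the instrument's exposure alleles.
pull_associations <- function(sel, target, ld, r2_min, max_dist,
                              palindrome_window) {
  n_sel <- nrow(sel)
  assoc <- tibble::tibble(
    beta = rep(NA_real_, n_sel), se = rep(NA_real_, n_sel),
    n = rep(NA_integer_, n_sel), reason = rep(NA_character_, n_sel)
  )
  proxy_id <- rep(NA_character_, n_sel)
  proxy_r2 <- rep(NA_real_, n_sel)

  hit <- match(sel$variant_id, target$variant_id)
  present <- !is.na(hit)
  if (any(present)) {
    aligned <- align_alleles(sel[present, , drop = FALSE],
                             tibble::as_tibble(
                               as.data.frame(target))[hit[present], , drop = FALSE],
                             palindrome_window)
    ok <- aligned$status == "ok"
    idx <- which(present)
    assoc$beta[idx[ok]] <- aligned$beta[ok]
    assoc$se[idx[ok]] <- aligned$se[ok]
    assoc$n[idx[ok]] <- aligned$n[ok]
    assoc$reason[idx[!ok]] <- aligned$reason[!ok]
    proxy_id[idx[ok]] <- sel$variant_id[idx[ok]]
    proxy_r2[idx[ok]] <- 1
  }

  for (i in which(!present)) {
    pr <- find_proxy(sel$variant_id[i], target, ld, r2_min, max_dist)
    if (is.na(pr$proxy_id)) {
      assoc$reason[i] <- "no-proxy"
      next
    }
    j <- match(pr$proxy_id, target$variant_id)
    row <- target[j, , drop = FALSE]
    al <- align_proxy(sel[i, , drop = FALSE], row)
    if (is.na(al$beta)) {
      assoc$reason[i] <- al$reason
      next
    }
    assoc$beta[i] <- al$beta
    assoc$se[i] <- row$se
    assoc$n[i] <- row$n
    proxy_id[i] <- pr$proxy_id
    proxy_r2[i] <- pr$r2
  }
  list(assoc = assoc, proxy_id = proxy_id, proxy_r2 = proxy_r2)
}

# A proxy is a different variant: allele labels need not correspond to the
# index variant's, so the sign is aligned by allele-frequency concordance
# (the effect-allele of the proxy is taken to tag the index's effect allele
# when the two effect-allele frequencies fall on the same side of 0.5).
align_proxy <- function(index, proxy_row) {
  same_labels <- proxy_row$effect_allele == index$effect_allele &&
    proxy_row$other_allele == index$other_allele
  swapped_labels <- proxy_row$effect_allele == index$other_allele &&
    proxy_row$other_allele == index$effect_allele
  if (same_labels) {
    return(list(beta = proxy_row$beta, reason = NA_character_))
  }
  if (swapped_labels) {
    return(list(beta = -proxy_row$beta, reason = NA_character_))
  }
  if (is.na(index$eaf) || is.na(proxy_row$eaf)) {
    return(list(beta = NA_real_, reason = "no-proxy"))
  }
  concordant <- (index$eaf < 0.5) == (proxy_row$eaf < 0.5)
  list(beta = if (concordant) proxy_row$beta else -proxy_row$beta,
       reason = NA_character_)
}

empty_records <- function() {
  tibble::tibble(
    variant_id = character(), chrom = character(), pos = integer(),
    effect_allele = character(), other_allele = character(), eaf = numeric(),
    proxy_of = character(), proxy_r2 = numeric(),
    beta_x = numeric(), se_x = numeric(), p_x = numeric(), n_x = integer(),
    beta_z = numeric(), se_z = numeric(), n_z = integer(),
    beta_y = numeric(), se_y = numeric(), n_y = integer(),
    orientable = logical()
  )
}

new_harmonized_set <- function(records, provenance) {
  structure(list(records = records, provenance = provenance),
            class = "harmonized_set")
}

#' @export
print.harmonized_set <- function(x, ...) {
  kept <- nrow(x$records)
  dropped <- sum(x$provenance$status == "dropped")
  proxied <- sum(x$provenance$status == "proxied")
  cat(sprintf(
    "<harmonized_set> %d instruments kept (%d via proxy), %d dropped of %d selected\n",
    kept, proxied, dropped, nrow(x$provenance)))
  invisible(x)
}

as_harmonized_records <- function(set) {
  if (inherits(set, "harmonized_set")) set$records else tibble::as_tibble(set)
}
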