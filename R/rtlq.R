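# Cycles beyond which a qPCR signal is treated as beyond the detection
# threshold and excluded from EMF aggregation.
CT_DETECTION_THRESHOLD <- 45

#' Construct an RTL-Q Ct quadruple
#'
#' RTL-Q measures 2'-O-methylation by reverse-transcribing with a high
#' or a low dNTP concentration using two reverse primers: R_D, placed
#' one nucleotide downstream of the putative 2'Ome site (its extension
#' pauses at a methylated ribose under low dNTPs), and R_U, placed
#' exactly on the site (unaffected). One quadruple holds the four cycle
#' thresholds of one replicate.
#'
#' @param ct_low_rd,ct_high_rd Ct for the downstream primer R_D at low
#'   and high dNTP concentration.
#' @param ct_low_ru,ct_high_ru Ct for the on-site primer R_U at low and
#'   high dNTP concentration.
#' @param replicate_id Optional replicate label.
#' @return An object of class `ct_quadruple`.
#' @export
ct_quadruple <- function(ct_low_rd, ct_high_rd, ct_low_ru, ct_high_ru,
                         replicate_id = NA_character_) {
  cts <- c(ct_low_rd, ct_high_rd, ct_low_ru, ct_high_ru)
  if (length(cts) != 4L || any(!is.finite(cts)) || any(cts <= 0))
    stop("a Ct quadruple needs four finite positive cycle numbers")
  structure(list(ct_low_rd = ct_low_rd, ct_high_rd = ct_high_rd,
                 ct_low_ru = ct_low_ru, ct_high_ru = ct_high_ru,
                 replicate_id = replicate_id),
            class = "ct_quadruple")
}

#' Estimated methylated fraction (EMF) of one Ct quadruple
#'
#' Applies the RTL-Q score
#' `EMF = (Ct_lowRD - Ct_highRD) - (Ct_lowRU - Ct_highRU)`.
#' A methylated site delays only the low-dNTP R_D extension, so EMF > 0
#' indicates methylation and EMF <= 0 its absence. The score is
#' invariant to a common Ct shift (template loading) and changes sign
#' when primer roles are swapped.
#'
#' @param q A [ct_quadruple()].
#' @param ct_threshold Detection ceiling in cycles (default 45). Any Ct
#'   at or above it flags the replicate for exclusion.
#' @return Numeric EMF, with attribute `excluded = TRUE` and
#'   `exclusion_reason = "above detection threshold"` when any Ct is
#'   beyond `ct_threshold`.
#' @export
compute_emf <- function(q, ct_threshold = CT_DETECTION_THRESHOLD) {
  cts <- c(q$ct_low_rd, q$ct_high_rd, q$ct_low_ru, q$ct_high_ru)
  emf <- (q$ct_low_rd - q$ct_high_rd) - (q$ct_low_ru - q$ct_high_ru)
  if (any(cts >= ct_threshold)) {
    attr(emf, "excluded") <- TRUE
    attr(emf, "exclusion_reason") <- "above detection threshold"
  }
  emf
}

#' Aggregate replicate EMFs into a methylation call
#'
#' The per-experiment estimate is the mean of the replicate EMFs;
#' methylation is called present when the mean exceeds zero. Replicates
#' with any Ct beyond the detection threshold are excluded first.
#'
#' @param quadruples List of [ct_quadruple()] objects.
#' @param ct_threshold Passed to [compute_emf()].
#' @return An object of class `emf_result`: list with `emf`,
#'   `methylated`, `n_replicates`, `emf_sem` (0 when n = 1) and
#'   `n_excluded`.
#' @export
aggregate_emf <- function(quadruples, ct_threshold = CT_DETECTION_THRESHOLD) {
  if (inherits(quadruples, "ct_quadruple")) quadruples <- list(quadruples)
  emfs <- lapply(quadruples, compute_emf, ct_threshold = ct_threshold)
  keep <- !vapply(emfs, function(e) isTRUE(attr(e, "excluded")), TRUE)
  vals <- as.numeric(unlist(emfs[keep]))
  if (!length(vals))
    stop("no valid replicates (all beyond the detection threshold)")
  emf <- mean(vals)
  sem <- if (length(vals) > 1L) stats::sd(vals) / sqrt(length(vals)) else 0
  structure(list(emf = emf, methylated = emf > 0,
                 n_replicates = length(vals), emf_sem = sem,
                 n_excluded = sum(!keep)),
            class = "emf_result")
}

#' @export
print.emf_result <- function(x, ...) {
  cat(sprintf("<emf_result> EMF = %.4f +/- %.4f (n = %d%s): %s\n",
              x$emf, x$emf_sem, x$n_replicates,
              if (x$n_excluded) paste0(", ", x$n_excluded, " excluded") else "",
              if (x$methylated) "methylated" else "not methylated"))
  invisible(x)
}

#' Read RTL-Q Ct quadruples from a long-format table
#'
#' Expects columns `sample`, `replicate`, `primer` (`RD`/`RU`) and
#' `dntp` (`low`/`high`) plus `ct`; one quadruple is built per
#' (sample, replicate).
#'
#' @param path CSV or TSV file path (delimiter auto-detected from the
#'   extension).
#' @return Named list (by sample) of lists of [ct_quadruple()].
#' @export
read_ct_quadruples <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("sample", "replicate", "primer", "dntp", "ct")
  if (!all(need %in% names(tab)))
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  tab$primer <- toupper(tab$primer)
  tab$dntp <- tolower(tab$dntp)
  out <- list()
  for (s in unique(tab$sample)) {
    sub <- tab[tab$sample == s, , drop = FALSE]
    quads <- lapply(unique(sub$replicate), function(r) {
      q <- sub[sub$replicate == r, , drop = FALSE]
      get_ct <- function(primer, dntp) {
        v <- q$ct[q$primer == primer & q$dntp == dntp]
        if (length(v) != 1L)
          stop(sprintf("sample '%s' replicate '%s': need exactly one Ct for %s/%s dNTP",
                       s, r, primer, dntp))
        v
      }
      ct_quadruple(get_ct("RD", "low"), get_ct("RD", "high"),
                   get_ct("RU", "low"), get_ct("RU", "high"),
                   replicate_id = as.character(r))
    })
    out[[as.character(s)]] <- quads
  }
  out
}
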