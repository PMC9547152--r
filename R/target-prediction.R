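# Watson-Crick complement lookup; G:U wobble is intentionally NOT in the
# default table (snoRNA guides hybridize by strict Watson-Crick pairing).
.WC_COMP <- c(A = "U", U = "A", C = "G", G = "C")

.is_paired <- function(element_base, target_base, allow_wobble = FALSE) {
  wc <- .WC_COMP[element_base] == target_base
  if (!allow_wobble) return(wc)
  wc | (element_base == "G" & target_base == "U") |
       (element_base == "U" & target_base == "G")
}

.element_sequence <- function(element) {
  if (inherits(element, "antisense_element")) element$sequence
  else normalize_rna(element)
}

#' Find antisense duplexes between a snoRNA element and a target RNA
#'
#' Scans every window of the target (sense strand) for an antiparallel
#' RNA:RNA hybrid with the antisense element: element position 1 (its
#' 5' end) pairs the 3' end of the target window. A window is reported
#' when (i) its longest contiguous run of Watson-Crick pairs is at least
#' `min_core` nt and (ii) all mismatches lie within the outermost
#' `max_terminal_mismatches` positions at each element end — the
#' geometry of a guide duplex whose core is clamped while the outer
#' nucleotides may fray. Hits are sorted by decreasing core length,
#' ties broken by smallest target start.
#'
#' When `element` is an [antisense_element()] (box-adjacent), the
#' predicted 2'Ome target position is placed on each hit with
#' [place_methylation_site()].
#'
#' @param element An [antisense_element()] or a plain RNA/DNA string
#'   (assumed box-adjacent at its 3' end).
#' @param target A [trna_record()] or a plain RNA/DNA string.
#' @param min_core Minimum length of the perfectly complementary core
#'   (default 7 nt).
#' @param max_terminal_mismatches Number of positions at each element
#'   end where mismatches are tolerated (default 2).
#' @param allow_wobble Count G:U wobble pairs as paired (default FALSE).
#' @return A data frame with one row per hit: `target_id`,
#'   `target_start`, `target_end`, `element_start`, `element_end`,
#'   `core_length`, `n_mismatches`, `mismatch_positions`
#'   (comma-separated element-relative positions, 5' to 3') and
#'   `methylation_position` (NA when unplaceable).
#' @export
find_duplex_hits <- function(element, target, min_core = 7L,
                             max_terminal_mismatches = 2L,
                             allow_wobble = FALSE) {
  el_seq <- .element_sequence(element)
  L <- nchar(el_seq)
  if (min_core > L)
    stop("min_core (", min_core, ") exceeds element length (", L, ")")
  if (inherits(target, "trna_record")) {
    tg_seq <- target$sequence
    tg_id <- target$id
  } else {
    tg_seq <- normalize_rna(target)
    tg_id <- "target"
  }
  n <- nchar(tg_seq)
  if (n == 0L) stop("empty target sequence")
  if (n < L) stop("target shorter than element")

  el <- strsplit(el_seq, "")[[1L]]
  tg <- strsplit(tg_seq, "")[[1L]]
  # terminal zones where mismatches are tolerated
  zone <- unique(c(seq_len(max_terminal_mismatches),
                   L - seq_len(max_terminal_mismatches) + 1L))
  zone <- zone[zone >= 1L & zone <= L]

  rows <- vector("list", n - L + 1L)
  for (s in seq_len(n - L + 1L)) {
    # element position e pairs target position s + L - e (antiparallel)
    paired <- .is_paired(el, tg[s + L - seq_len(L)], allow_wobble)
    mism <- which(!paired)
    if (length(mism) && !all(mism %in% zone)) next
    runs <- rle(paired)
    core <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
    if (core < min_core) next
    rows[[s]] <- data.frame(
      target_id = tg_id, target_start = s, target_end = s + L - 1L,
      element_start = if (inherits(element, "antisense_element"))
        element$start else 1L,
      element_end = if (inherits(element, "antisense_element"))
        element$end else L,
      core_length = as.integer(core),
      n_mismatches = length(mism),
      mismatch_positions = paste(mism, collapse = ","),
      stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(hits)) {
    hits <- data.frame(target_id = character(), target_start = integer(),
                       target_end = integer(), element_start = integer(),
                       element_end = integer(), core_length = integer(),
                       n_mismatches = integer(),
                       mismatch_positions = character(),
                       methylation_position = integer(),
                       stringsAsFactors = FALSE)
    return(hits)
  }
  hits <- hits[order(-hits$core_length, hits$target_start), , drop = FALSE]
  rownames(hits) <- NULL
  hits$methylation_position <- vapply(seq_len(nrow(hits)), function(i) {
    res <- tryCatch(place_methylation_site(hits[i, ], element),
                    error = function(e) NA_integer_)
    if (is.list(res)) res$position else res
  }, integer(1))
  hits
}

#' Place the predicted 2'-O-methylation site on a duplex hit
#'
#' C/D-box snoRNAs position the methyltransferase over the target
#' nucleotide paired with the guide residue exactly five nucleotides
#' upstream of the adjacent D or D' box. Counting starts at 1 for the
#' element's 3'-most residue (the nucleotide immediately before the
#' box), so the "+5" residue is element position `L - 4` and, by
#' antiparallel pairing, the methylated target nucleotide is
#' `target_start + 4`.
#'
#' @param hit A single hit row as returned by [find_duplex_hits()] (or
#'   any list with `target_start` and `mismatch_positions`).
#' @param element The antisense element used for the search.
#' @return A list with `position` (1-based target coordinate, or
#'   `NA_integer_`) and `reason` (`NA` or `"unpaired at +5"`).
#' @export
place_methylation_site <- function(hit, element) {
  el_seq <- .element_sequence(element)
  L <- nchar(el_seq)
  if (L < 5L)
    stop("element shorter than 5 nt: cannot apply the +5 upstream rule")
  plus5 <- L - 4L
  mism <- hit$mismatch_positions
  if (is.character(mism))
    mism <- if (nzchar(mism)) as.integer(strsplit(mism, ",")[[1L]])
            else integer(0)
  if (plus5 %in% mism)
    return(list(position = NA_integer_, reason = "unpaired at +5"))
  list(position = as.integer(hit$target_start) + 4L, reason = NA_character_)
}

#' Write duplex hits to a tab-separated file
#'
#' @param hits Data frame from [find_duplex_hits()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_duplex_hits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
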