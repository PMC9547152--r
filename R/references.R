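# -- sequence normalisation ---------------------------------------------------

#' Normalise a nucleotide sequence to the uppercase RNA alphabet
#'
#' DNA input is accepted and silently converted (`T` becomes `U`);
#' mixed case is folded to uppercase. Any character outside `A`, `C`,
#' `G`, `U` after conversion is an error reporting its position.
#'
#' @param x Character vector of sequences.
#' @return Character vector of uppercase RNA sequences.
#' @export
normalize_rna <- function(x) {
  stopifnot(is.character(x))
  out <- chartr("Tt", "Uu", x)
  out <- toupper(out)
  bad <- regexpr("[^ACGU]", out)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("invalid character '%s' at position %d of sequence %d",
                 substr(out[i], bad[i], bad[i]), bad[i], i))
  }
  out
}

# -- tRNA records -------------------------------------------------------------

#' Construct a mature tRNA reference record
#'
#' A `trna_record` holds a mature sense-strand tRNA sequence (stored in
#' the RNA alphabet) together with its identity metadata. All
#' coordinates reported anywhere in the package are 1-based inclusive
#' positions on this sequence.
#'
#' @param id Unique text identifier.
#' @param sequence Nucleotide sequence (DNA or RNA; normalised to RNA).
#' @param amino_acid Three-letter amino-acid code (e.g. `"Leu"`).
#' @param anticodon Three-nucleotide anticodon (DNA or RNA spelling).
#' @param species Optional species label.
#' @param cca_appended Logical; whether the stored sequence carries the
#'   3' CCA. References are stored without CCA by default so that
#'   fragment coordinates such as 47-64 remain stable across sources.
#' @return An object of class `trna_record`.
#' @export
trna_record <- function(id, sequence, amino_acid = NA_character_,
                        anticodon = NA_character_, species = NA_character_,
                        cca_appended = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- unname(normalize_rna(sequence))
  if (!nzchar(sequence)) stop("empty sequence for record '", id, "'")
  len <- nchar(sequence)
  if (len < 60L || len > 100L)
    stop(sprintf("tRNA '%s' has length %d nt; expected 60-100 nt", id, len))
  if (!is.na(anticodon)) {
    anticodon <- normalize_rna(anticodon)
    if (nchar(anticodon) != 3L)
      stop("anticodon must be 3 nt, got '", anticodon, "'")
    if (!grepl(anticodon, sequence, fixed = TRUE))
      stop(sprintf("anticodon '%s' not found in sequence of '%s'",
                   anticodon, id))
  }
  structure(list(id = id, species = species, amino_acid = amino_acid,
                 anticodon = anticodon, sequence = sequence,
                 cca_appended = isTRUE(cca_appended), length = len),
            class = "trna_record")
}

#' @export
print.trna_record <- function(x, ...) {
  cat(sprintf("<trna_record> %s (%s, anticodon %s), %d nt%s\n",
              x$id, x$amino_acid, x$anticodon, x$length,
              if (x$cca_appended) ", CCA-appended" else ""))
  invisible(x)
}

# Parse GtRNAdb-style ids such as "tRNA-Leu-TAA-1-1" for identity
# metadata; returns NAs when the id does not follow that pattern.
.parse_trna_id <- function(id) {
  m <- regmatches(id, regexec("tRNA-([A-Za-z]{3})-([A-Za-z]{3})", id))[[1L]]
  if (length(m) == 3L) list(amino_acid = m[2L], anticodon = m[3L])
  else list(amino_acid = NA_character_, anticodon = NA_character_)
}

#' Read tRNA or snoRNA reference sequences from FASTA
#'
#' Sequences are normalised to the uppercase RNA alphabet. For
#' `kind = "trna"` each record becomes a [trna_record()]; amino acid and
#' anticodon are parsed from GtRNAdb-style identifiers
#' (`tRNA-Leu-TAA-...`) or from `key=value` tokens (`aa=`, `anticodon=`,
#' `species=`) in the description line. For `kind = "snorna"` a named
#' character vector of raw RNA sequences is returned; see [sno_record()]
#' to annotate boxes.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped lines).
#' @param kind `"trna"` or `"snorna"`.
#' @param append_cca For tRNAs, append the 3' CCA tail to every
#'   sequence and flag records as `cca_appended`.
#' @return A list of `trna_record` objects, or a named character vector
#'   of snoRNA sequences.
#' @export
read_fasta_records <- function(path, kind = c("trna", "snorna"),
                               append_cca = FALSE) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA id: '", dup[1L], "'")
  seqs <- normalize_rna(as.character(set))
  if (kind == "snorna") {
    names(seqs) <- ids
    return(seqs)
  }
  recs <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    meta <- .parse_trna_id(ids[i])
    kv <- .parse_header_tokens(headers[i])
    aa <- kv[["aa"]] %||% meta$amino_acid
    ac <- kv[["anticodon"]] %||% meta$anticodon
    sp <- kv[["species"]] %||% NA_character_
    seq <- seqs[i]
    if (append_cca) seq <- paste0(seq, "CCA")
    recs[[i]] <- trna_record(ids[i], seq, amino_acid = aa, anticodon = ac,
                             species = sp, cca_appended = append_cca)
  }
  names(recs) <- ids
  recs
}

.parse_header_tokens <- function(header) {
  toks <- strsplit(header, "\\s+")[[1L]]
  toks <- toks[grepl("=", toks, fixed = TRUE)]
  if (!length(toks)) return(list())
  kv <- strsplit(toks, "=", fixed = TRUE)
  stats::setNames(lapply(kv, `[`, 2L), vapply(kv, `[`, "", 1L))
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

#' Write reference records to FASTA
#'
#' @param records A list of [trna_record()] objects or a named character
#'   vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_records <- function(records, path) {
  if (is.list(records)) {
    seqs <- vapply(records, function(r) r$sequence, "")
    names(seqs) <- vapply(records, function(r) r$id, "")
  } else seqs <- records
  set <- Biostrings::RNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# -- C/D box location ---------------------------------------------------------

BOX_C_CONSENSUS <- "[AG]UGAUGA"   # RUGAUGA, R in {A, G}
BOX_D_CONSENSUS <- "CUGA"

.hamming_hits <- function(seq_chars, pattern_chars, max_mm = 0L,
                          from = 1L, to = length(seq_chars)) {
  k <- length(pattern_chars)
  last <- min(to, length(seq_chars)) - k + 1L
  if (last < from) return(integer(0))
  starts <- from:last
  mm <- vapply(starts, function(s)
    sum(seq_chars[s:(s + k - 1L)] != pattern_chars), integer(1))
  starts[mm <= max_mm]
}

#' Locate C/D-box motifs in a snoRNA sequence
#'
#' Finds the boxes that define a C/D-box snoRNA: the C box (consensus
#' `RUGAUGA`, first match), the D box (`CUGA`, last match — D sits near
#' the snoRNA 3' end), and the D' box (`CUGA` tolerating one mismatch,
#' first internal match after the C box and before the D box). Boxes
#' that cannot be found are simply absent from the result; a missing D
#' box is an error because a C/D snoRNA cannot be processed without it.
#' A C' box is reported when a second `RUGAUGA` lies between D' and D.
#'
#' @param sequence snoRNA sequence (RNA or DNA spelling), at least 40 nt.
#' @param d_prime_max_mismatch Mismatches tolerated in the D' box
#'   (default 1; the D box itself must be exact).
#' @return A named list of `c(start, end)` 1-based inclusive spans, with
#'   elements among `C`, `D_prime`, `C_prime`, `D`.
#' @export
locate_boxes <- function(sequence, d_prime_max_mismatch = 1L) {
  sequence <- normalize_rna(sequence)
  if (nchar(sequence) < 40L)
    stop("sequence too short for box location (< 40 nt)")
  chars <- strsplit(sequence, "")[[1L]]
  boxes <- list()

  d_starts <- gregexpr(BOX_D_CONSENSUS, sequence, fixed = TRUE)[[1L]]
  if (d_starts[1L] == -1L) stop("no D box (no CUGA motif found)")
  d_start <- d_starts[length(d_starts)]
  boxes$D <- c(start = d_start, end = d_start + 3L)

  c_start <- regexpr(BOX_C_CONSENSUS, sequence)
  if (c_start > 0L)
    boxes$C <- c(start = as.integer(c_start), end = as.integer(c_start) + 6L)

  # D': first (possibly degenerate) CUGA strictly between C box and D box
  dp_from <- if (!is.null(boxes$C)) boxes$C[["end"]] + 1L else 2L
  dp <- .hamming_hits(chars, c("C", "U", "G", "A"),
                      max_mm = d_prime_max_mismatch,
                      from = dp_from, to = d_start - 1L)
  dp <- dp[dp + 3L < d_start]
  if (length(dp))
    boxes$D_prime <- c(start = dp[1L], end = dp[1L] + 3L)

  # C': a second C-box-like motif between D' and D
  if (!is.null(boxes$D_prime)) {
    cp_region <- substr(sequence, boxes$D_prime[["end"]] + 1L, d_start - 1L)
    cp <- regexpr(BOX_C_CONSENSUS, cp_region)
    if (cp > 0L) {
      cp_start <- boxes$D_prime[["end"]] + as.integer(cp)
      boxes$C_prime <- c(start = cp_start, end = cp_start + 6L)
    }
  }

  ord <- intersect(c("C", "D_prime", "C_prime", "D"), names(boxes))
  boxes[ord]
}

# -- snoRNA records and antisense elements ------------------------------------

#' Construct an annotated C/D-box snoRNA record
#'
#' Boxes are located with [locate_boxes()] unless a pre-annotated box
#' map is supplied (fixtures ship with annotated boxes so downstream
#' results never depend on motif calling). Antisense elements — the
#' ribonucleoprotein-free stretches directly upstream of the D and D'
#' boxes that base-pair with target RNAs — are extracted for every box
#' with sufficient upstream sequence.
#'
#' @param id Text identifier.
#' @param sequence snoRNA sequence (normalised to RNA).
#' @param boxes Optional named list of `c(start, end)` spans as returned
#'   by [locate_boxes()].
#' @param element_length Antisense element length in nt (default 9: a
#'   7-nt pairing core plus one outer nucleotide at each end).
#' @return An object of class `sno_record` with fields `id`, `sequence`,
#'   `boxes` and `antisense_elements`.
#' @export
sno_record <- function(id, sequence, boxes = NULL, element_length = 9L) {
  sequence <- normalize_rna(sequence)
  if (is.null(boxes)) boxes <- locate_boxes(sequence)
  boxes <- lapply(boxes, function(b) {
    b <- as.integer(b); names(b) <- c("start", "end"); b
  })
  present <- intersect(c("C", "D_prime", "C_prime", "D"), names(boxes))
  starts <- vapply(boxes[present], `[[`, 0L, "start")
  if (is.unsorted(starts, strictly = TRUE))
    stop("box order violated: expected C < D' < C' < D along '", id, "'")
  rec <- structure(list(id = id, sequence = sequence, boxes = boxes,
                        antisense_elements = list()),
                   class = "sno_record")
  for (box in intersect(c("D_prime", "D"), names(boxes))) {
    el <- tryCatch(
      extract_antisense_element(rec, box, length = element_length),
      error = function(e) NULL)
    if (!is.null(el)) rec$antisense_elements[[box]] <- el
  }
  rec
}

#' @export
print.sno_record <- function(x, ...) {
  cat(sprintf("<sno_record> %s, %d nt\n", x$id, nchar(x$sequence)))
  for (nm in names(x$boxes))
    cat(sprintf("  box %-7s %d-%d\n", nm, x$boxes[[nm]][["start"]],
                x$boxes[[nm]][["end"]]))
  for (nm in names(x$antisense_elements)) {
    el <- x$antisense_elements[[nm]]
    cat(sprintf("  element (%s) %d-%d %s\n", nm, el$start, el$end, el$sequence))
  }
  invisible(x)
}

#' Extract the antisense element upstream of a D or D' box
#'
#' The antisense element is the `length`-nt stretch ending exactly one
#' nucleotide before the box start; its 3'-most residue is the "+1"
#' position of the upstream count used to place the methylation site.
#'
#' @param sno A [sno_record()].
#' @param box `"D"` or `"D_prime"`.
#' @param length Element length in nt (>= 7).
#' @return An object of class `antisense_element`: a list with
#'   `sequence`, `start`, `end` (snoRNA coordinates), `adjacent_box` and
#'   `sno_id`.
#' @export
extract_antisense_element <- function(sno, box = c("D_prime", "D"),
                                      length = 9L) {
  box <- match.arg(box)
  length <- as.integer(length)
  if (length < 7L) stop("antisense element length must be >= 7 nt")
  if (is.null(sno$boxes[[box]]))
    stop("box '", box, "' absent from snoRNA '", sno$id, "'")
  box_start <- sno$boxes[[box]][["start"]]
  start <- box_start - length
  if (start < 1L)
    stop(sprintf("insufficient upstream sequence for a %d-nt element before box '%s' (box starts at %d)",
                 length, box, box_start))
  structure(list(sequence = substr(sno$sequence, start, box_start - 1L),
                 start = start, end = box_start - 1L,
                 adjacent_box = box, sno_id = sno$id),
            class = "antisense_element")
}

#' @export
print.antisense_element <- function(x, ...) {
  cat(sprintf("<antisense_element> %s %d-%d (upstream of %s box) %s\n",
              x$sno_id, x$start, x$end, x$adjacent_box, x$sequence))
  invisible(x)
}
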