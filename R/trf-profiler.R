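# tRFs are by definition shorter than this; reads at or above it are
# mature/precursor tRNA, not fragments.
TRF_MAX_LENGTH <- 45L

#' Read small-RNA sequencing reads from FASTQ
#'
#' Qualities are ignored throughout the package; sequences are
#' normalised to the RNA alphabet.
#'
#' @param path Path to an uncompressed or gzipped FASTQ file.
#' @return A named character vector of RNA read sequences (names are
#'   read ids).
#' @export
read_fastq_reads <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readDNAStringSet(path, format = "fastq")
  reads <- normalize_rna(as.character(set))
  names(reads) <- sub("\\s.*$", "", names(set))
  reads
}

#' Assign small-RNA reads to tRNA references
#'
#' A read is assignable iff it matches a reference as an exact,
#' full-length substring (0 mismatches). Uniquely matching reads are
#' assigned first; reads matching several references are then rescued
#' with the single-assignment rule used for multi-mapping small-RNA
#' reads: the whole read count goes to the reference with the highest
#' unique-read count (its "expression"), ties broken by lexicographic
#' reference id. Reads shorter than `min_length` are dropped and
#' counted. The procedure is independent of read input order.
#'
#' @param reads Named character vector of read sequences (RNA or DNA
#'   spelling), e.g. from [read_fastq_reads()].
#' @param refs List of [trna_record()] objects.
#' @param min_length Minimum read length retained (default 15 nt).
#' @param max_length Maximum read length retained (default 50 nt; 0
#'   disables the cap so full-length mature reads pass through).
#' @return A list with `assignments` (data frame: `read_id`,
#'   `parent_id`, `start`, `end`, `length`, `mapping` in
#'   `unique`/`rescued_multi`), `unassigned` (count), `dropped` (count)
#'   and `per_parent_unique` (named unique-read counts).
#' @export
assign_reads <- function(reads, refs, min_length = 15L, max_length = 0L) {
  if (!length(refs)) stop("no reference records supplied")
  if (is.null(names(reads)) || any(!nzchar(names(reads))))
    names(reads) <- sprintf("read%06d", seq_along(reads))
  reads <- normalize_rna(reads)
  len <- nchar(reads)
  keep <- len >= min_length
  if (max_length > 0L) keep <- keep & len <= max_length
  dropped <- sum(!keep)
  reads <- reads[keep]

  ref_seq <- vapply(refs, function(r) r$sequence, "")
  ref_ids <- vapply(refs, function(r) r$id, "")
  names(ref_seq) <- ref_ids

  # reads are heavily duplicated; match each distinct sequence once
  uniq <- unique(unname(reads))
  match_tab <- lapply(uniq, function(s) {
    hits <- lapply(seq_along(ref_seq), function(j) {
      p <- gregexpr(s, ref_seq[j], fixed = TRUE)[[1L]]
      if (p[1L] == -1L) NULL
      else data.frame(parent_id = ref_ids[j], start = as.integer(p[1L]),
                      stringsAsFactors = FALSE)  # first occurrence
    })
    do.call(rbind, hits[!vapply(hits, is.null, TRUE)])
  })
  names(match_tab) <- uniq

  n_refs_hit <- vapply(match_tab, function(m) if (is.null(m)) 0L else nrow(m),
                       integer(1))
  seq_of_read <- unname(reads)
  read_hits <- n_refs_hit[seq_of_read]

  # pass 1: unique reads define per-parent expression
  uni_parent <- vapply(match_tab, function(m)
    if (!is.null(m) && nrow(m) == 1L) m$parent_id[1L] else NA_character_, "")
  parent1 <- uni_parent[seq_of_read]
  per_parent_unique <- table(factor(parent1[!is.na(parent1)],
                                    levels = sort(ref_ids)))
  per_parent_unique <- stats::setNames(as.integer(per_parent_unique),
                                       names(per_parent_unique))

  # pass 2: rescue multimappers to the highest-expression parent
  pick_parent <- vapply(match_tab, function(m) {
    if (is.null(m)) return(NA_character_)
    if (nrow(m) == 1L) return(m$parent_id[1L])
    cand <- sort(m$parent_id)  # lexicographic tie-break
    cand[which.max(per_parent_unique[cand])]
  }, "")
  parent <- pick_parent[seq_of_read]
  start <- vapply(seq_along(seq_of_read), function(i) {
    m <- match_tab[[seq_of_read[i]]]
    if (is.null(m)) return(NA_integer_)
    m$start[match(parent[i], m$parent_id)]
  }, integer(1))

  ok <- !is.na(parent)
  assignments <- data.frame(
    read_id = names(reads)[ok],
    parent_id = parent[ok],
    start = start[ok],
    end = start[ok] + nchar(seq_of_read[ok]) - 1L,
    length = nchar(seq_of_read[ok]),
    mapping = ifelse(read_hits[ok] > 1L, "rescued_multi", "unique"),
    stringsAsFactors = FALSE)
  rownames(assignments) <- NULL
  list(assignments = assignments,
       unassigned = sum(!ok),
       dropped = dropped,
       per_parent_unique = per_parent_unique)
}

#' Group read assignments into named fragment calls
#'
#' Reads sharing (parent, start, end) collapse into one call. Calls
#' shorter than `trf_max_length` are tRFs, named by their 1-based
#' inclusive span on the mature tRNA (`"tRF 47-64"`); calls at or above
#' the boundary are classed `mature` (mature or precursor tRNA).
#'
#' @param assignments Result of [assign_reads()] (or its `assignments`
#'   data frame).
#' @param trf_max_length tRF/mature boundary (default 45 nt).
#' @return Data frame with `parent_id`, `start`, `end`, `length`,
#'   `count`, `class` (`tRF`/`mature`) and `name`, sorted by parent and
#'   decreasing count.
#' @export
call_fragments <- function(assignments, trf_max_length = TRF_MAX_LENGTH) {
  a <- if (is.list(assignments) && !is.data.frame(assignments))
    assignments$assignments else assignments
  if (!nrow(a))
    return(data.frame(parent_id = character(), start = integer(),
                      end = integer(), length = integer(), count = integer(),
                      class = character(), name = character(),
                      stringsAsFactors = FALSE))
  key <- paste(a$parent_id, a$start, a$end, sep = "\r")
  agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
  parts <- strsplit(agg$key, "\r", fixed = TRUE)
  calls <- data.frame(
    parent_id = vapply(parts, `[`, "", 1L),
    start = as.integer(vapply(parts, `[`, "", 2L)),
    end = as.integer(vapply(parts, `[`, "", 3L)),
    count = as.integer(agg$Freq),
    stringsAsFactors = FALSE)
  calls$length <- calls$end - calls$start + 1L
  calls$class <- ifelse(calls$length < trf_max_length, "tRF", "mature")
  calls$name <- ifelse(calls$class == "tRF",
                       sprintf("tRF %d-%d", calls$start, calls$end),
                       sprintf("mature %d-%d", calls$start, calls$end))
  calls <- calls[order(calls$parent_id, -calls$count, calls$start),
                 c("parent_id", "start", "end", "length", "count",
                   "class", "name")]
  rownames(calls) <- NULL
  calls
}

#' Reads-per-million normalisation
#'
#' @param counts Numeric vector of read counts.
#' @param library_size Total assigned reads in the library.
#' @return `counts / library_size * 1e6`.
#' @export
rpm_normalize <- function(counts, library_size) {
  if (length(library_size) != 1L || is.na(library_size) || library_size <= 0)
    stop("library_size must be a single positive count")
  counts / library_size * 1e6
}

#' Fragment length histogram and small/large size classes
#'
#' Tabulates tRF read counts by exact fragment length over the 18-45 nt
#' window and splits them into the small (18-29 nt) and large (30-45
#' nt) classes whose balance shifts with snoRNA-guided methylation.
#' Percentages are relative to all tRNA-assigned reads (tRFs plus
#' mature) unless `total_reads` is given.
#'
#' @param calls Data frame from [call_fragments()].
#' @param range Histogram length window (default `c(18, 45)`).
#' @param small_max Upper bound of the small class (default 29 nt).
#' @param total_reads Denominator for percentages; defaults to the sum
#'   of all call counts.
#' @return A list with `histogram` (data frame `length`, `count`,
#'   `percent`), `small_percent`, `large_percent`, `small_count`,
#'   `large_count` and `total_reads`.
#' @export
length_class_histogram <- function(calls, range = c(18L, 45L),
                                   small_max = 29L, total_reads = NULL) {
  trf <- calls[calls$class == "tRF", , drop = FALSE]
  if (is.null(total_reads)) total_reads <- sum(calls$count)
  lengths <- range[1L]:range[2L]
  counts <- vapply(lengths, function(l)
    sum(trf$count[trf$length == l]), numeric(1))
  hist <- data.frame(length = lengths, count = counts,
                     percent = if (total_reads > 0)
                       100 * counts / total_reads else 0 * counts)
  small <- sum(counts[lengths <= small_max])
  large <- sum(counts[lengths > small_max])
  list(histogram = hist,
       small_count = small, large_count = large,
       small_percent = if (total_reads > 0) 100 * small / total_reads else 0,
       large_percent = if (total_reads > 0) 100 * large / total_reads else 0,
       total_reads = total_reads)
}

#' Per-position read coverage along a tRNA
#'
#' @param calls Data frame from [call_fragments()].
#' @param parent A [trna_record()] present among the calls' parents (or
#'   its id, with `parent_length` supplied).
#' @param parent_length Length override when `parent` is an id.
#' @param trf_only Restrict to tRF-class calls (default FALSE).
#' @return Integer vector of depth, one element per reference position
#'   (5' to 3'; flip with `rev()` for 3'-to-5' display).
#' @export
coverage_profile <- function(calls, parent, parent_length = NULL,
                             trf_only = FALSE) {
  if (inherits(parent, "trna_record")) {
    pid <- parent$id; plen <- parent$length
  } else {
    pid <- parent
    if (is.null(parent_length)) stop("parent_length required with a bare id")
    plen <- as.integer(parent_length)
  }
  sel <- calls[calls$parent_id == pid, , drop = FALSE]
  if (trf_only) sel <- sel[sel$class == "tRF", , drop = FALSE]
  depth <- integer(plen)
  for (i in seq_len(nrow(sel))) {
    span <- sel$start[i]:min(sel$end[i], plen)
    depth[span] <- depth[span] + sel$count[i]
  }
  depth
}

# Parse "tRF 47-64" (also tolerating an en dash) into c(start, end).
.parse_trf_name <- function(name) {
  m <- regmatches(name, regexec("([0-9]+)[^0-9]+([0-9]+)", name))[[1L]]
  if (length(m) != 3L) stop("cannot parse fragment name '", name, "'")
  c(start = as.integer(m[2L]), end = as.integer(m[3L]))
}

#' Share of a fragment family among a tRNA's tRF reads
#'
#' Computes 100 x (reads in the named fragment family) / (all tRF reads
#' of the parent). The family groups 3'-end-jittered variants of the
#' canonical fragment: same start, end within
#' `[end, end + extension_3p]` (default +2 nt, matching the three
#' observed sizes of a nibbled 3' terminus). 5' ends must match
#' exactly.
#'
#' @param calls Data frame from [call_fragments()].
#' @param parent A [trna_record()] or parent id.
#' @param name Canonical fragment name, e.g. `"tRF 47-64"`.
#' @param extension_3p Allowed 3' extension window in nt (default 2).
#' @return Percentage (0-100).
#' @export
fragment_fraction <- function(calls, parent, name, extension_3p = 2L) {
  pid <- if (inherits(parent, "trna_record")) parent$id else parent
  span <- .parse_trf_name(name)
  trf <- calls[calls$parent_id == pid & calls$class == "tRF", , drop = FALSE]
  total <- sum(trf$count)
  if (total == 0L) stop("parent '", pid, "' has no tRF reads")
  fam <- trf$start == span[["start"]] &
    trf$end >= span[["end"]] & trf$end <= span[["end"]] + extension_3p
  100 * sum(trf$count[fam]) / total
}

#' Summarise a profiling run
#'
#' Bundles the analytics reported for a small-RNA library: per-class
#' RPM (reads assigned to tRNA references versus unassigned/other),
#' the per-parent fragment table with RPM, the tRF length histogram and
#' per-parent coverage vectors.
#'
#' @param assignment Result of [assign_reads()].
#' @param refs List of [trna_record()] objects used for assignment.
#' @param class_of Optional named vector mapping parent id to a small-RNA
#'   class label (default: every reference is `"tRNA"`).
#' @return A list with `class_rpm`, `fragments` (calls plus `rpm`),
#'   `length_classes` and `coverage` (named list of depth vectors).
#' @export
profile_summary <- function(assignment, refs, class_of = NULL) {
  calls <- call_fragments(assignment)
  lib <- sum(calls$count)
  if (is.null(class_of)) {
    ids <- vapply(refs, function(r) r$id, "")
    class_of <- stats::setNames(rep("tRNA", length(ids)), ids)
  }
  cls <- class_of[calls$parent_id]
  class_counts <- tapply(calls$count, cls, sum)
  class_rpm <- rpm_normalize(as.numeric(class_counts), lib)
  names(class_rpm) <- names(class_counts)
  calls$rpm <- rpm_normalize(calls$count, lib)
  cov <- lapply(refs, function(r) coverage_profile(calls, r))
  names(cov) <- vapply(refs, function(r) r$id, "")
  list(class_rpm = class_rpm,
       fragments = calls,
       length_classes = length_class_histogram(calls),
       coverage = cov,
       library_size = lib,
       unassigned = assignment$unassigned,
       dropped = assignment$dropped)
}
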