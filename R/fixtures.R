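#' Packaged reference fixtures
#'
#' The package ships small reference fixtures so every analysis stage
#' runs without downloads: a mature tRNA-Leu (anticodon UAA) reference
#' in a mouse and a human variant (differing at one D-arm position, the
#' inter-species difference of this tRNA), and a SNORD113-6-like C/D-box
#' snoRNA whose D'-adjacent antisense element pairs the tRNA T-arm with
#' a perfect 7-nt core flanked by two mismatching outer nucleotides.
#' These sequences are synthetic reconstructions built to carry the
#' documented structural features (box positions, binding-site
#' geometry, fragment coordinates); they are not database sequences, as
#' the fixture file names indicate.
#'
#' @param which One of `"trna_fasta"`, `"snorna_fasta"`, `"boxes_tsv"`,
#'   `"profiles_yaml"`.
#' @return Path to the requested fixture file.
#' @export
snoguard_fixture <- function(which = c("trna_fasta", "snorna_fasta",
                                       "boxes_tsv", "profiles_yaml")) {
  which <- match.arg(which)
  file <- switch(which,
    trna_fasta = "trna_leu_taa_synthetic.fa",
    snorna_fasta = "snord113_6_synthetic.fa",
    boxes_tsv = "snord113_6_synthetic_boxes.tsv",
    profiles_yaml = "cleavage_profiles.yaml")
  system.file("extdata", file, package = "snoguard", mustWork = TRUE)
}

#' Load the packaged tRNA references
#'
#' @return List of [trna_record()] objects (mouse and human variants).
#' @export
load_fixture_trnas <- function() {
  read_fasta_records(snoguard_fixture("trna_fasta"), kind = "trna")
}

#' Load the packaged snoRNA with its pre-annotated boxes
#'
#' The fixture carries a box annotation file so downstream results do
#' not depend on motif calling; [locate_boxes()] recovers the same
#' spans.
#'
#' @param use_annotation Use the shipped box annotation (default TRUE);
#'   otherwise boxes are located de novo.
#' @return A [sno_record()].
#' @export
load_fixture_snorna <- function(use_annotation = TRUE) {
  seqs <- read_fasta_records(snoguard_fixture("snorna_fasta"),
                             kind = "snorna")
  boxes <- NULL
  if (use_annotation) {
    tab <- utils::read.table(snoguard_fixture("boxes_tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
    boxes <- lapply(seq_len(nrow(tab)), function(i)
      c(start = tab$start[i], end = tab$end[i]))
    names(boxes) <- tab$box
  }
  sno_record(names(seqs)[1L], seqs[[1L]], boxes = boxes)
}
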