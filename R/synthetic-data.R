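#' Construct a methylation-dependent cleavage profile
#'
#' The generative model behind the read simulator: each tRNA molecule
#' independently carries the 2'Ome mark with probability
#' `methylated_fraction`, stays intact with probability
#' `intact_fraction`, and otherwise is cleaved at one of the
#' `cut_sites`, drawn with the given weights. On methylated molecules
#' the weight of the protected site — the one whose 3' boundary abuts
#' the methylation position, i.e. the fragment ending one nucleotide
#' before it — is multiplied by `protection_factor` (< 1 means the mark
#' suppresses that cleavage). Fragment 3' ends are extended by a
#' uniform 0..`end_jitter` nt to emulate ragged cleavage termini. This
#' is a phenomenological stand-in for stress-nuclease cleavage, not an
#' enzymatic model.
#'
#' @param parent_id Id of the tRNA reference the profile applies to.
#' @param cut_sites Data frame with columns `start`, `end`, `weight`.
#' @param methylated_fraction Probability m of the 2'Ome mark.
#' @param protection_factor Multiplier on the protected site's weight
#'   for methylated molecules.
#' @param methylation_position 1-based target position of the 2'Ome
#'   site; the protected cut site must end at
#'   `methylation_position - 1`.
#' @param intact_fraction Probability a molecule stays full length.
#' @param end_jitter Maximum 3' extension in nt (default 2).
#' @param abundance_multiplier Relative abundance scale of this
#'   condition (used by the qPCR simulator; default 1).
#' @return An object of class `cleavage_profile`.
#' @export
cleavage_profile <- function(parent_id, cut_sites, methylated_fraction,
                             protection_factor, methylation_position,
                             intact_fraction = 0.3, end_jitter = 2L,
                             abundance_multiplier = 1) {
  cut_sites <- as.data.frame(cut_sites)
  stopifnot(all(c("start", "end", "weight") %in% names(cut_sites)),
            nrow(cut_sites) >= 1L)
  probs <- c(methylated_fraction, intact_fraction)
  if (any(probs < 0) || any(probs > 1))
    stop("methylated_fraction and intact_fraction must lie in [0, 1]")
  if (any(cut_sites$weight < 0) || sum(cut_sites$weight) == 0)
    stop("cut-site weights must be non-negative and not all zero")
  if (protection_factor < 0) stop("protection_factor must be >= 0")
  if (end_jitter < 0) stop("end_jitter must be >= 0")
  protected <- which(cut_sites$end == methylation_position - 1L)
  if (!length(protected) && protection_factor != 1)
    stop("no cut site ends at methylation_position - 1: ",
         "the protected site must abut the 2'Ome position")
  structure(list(parent_id = parent_id, cut_sites = cut_sites,
                 methylated_fraction = methylated_fraction,
                 protection_factor = protection_factor,
                 methylation_position = as.integer(methylation_position),
                 intact_fraction = intact_fraction,
                 end_jitter = as.integer(end_jitter),
                 abundance_multiplier = abundance_multiplier,
                 protected_site = if (length(protected)) protected[1L]
                                  else NA_integer_),
            class = "cleavage_profile")
}

#' @export
print.cleavage_profile <- function(x, ...) {
  cat(sprintf("<cleavage_profile> %s: m = %.3g, protection = %.3g, intact = %.3g\n",
              x$parent_id, x$methylated_fraction, x$protection_factor,
              x$intact_fraction))
  print(x$cut_sites)
  invisible(x)
}

#' Validate a cleavage profile against its reference
#'
#' @param profile A [cleavage_profile()].
#' @param ref The parent [trna_record()].
#' @return `profile`, invisibly; errors when any fragment coordinate
#'   (including maximal 3' jitter at sites other than the 3' terminus)
#'   falls outside the reference.
#' @export
validate_cleavage_profile <- function(profile, ref) {
  if (profile$parent_id != ref$id)
    stop("profile parent '", profile$parent_id, "' does not match reference '",
         ref$id, "'")
  cs <- profile$cut_sites
  if (any(cs$start < 1L) || any(cs$end > ref$length) || any(cs$end < cs$start))
    stop("cut-site coordinates outside reference (length ", ref$length, ")")
  if (profile$methylation_position > ref$length)
    stop("methylation position outside reference")
  invisible(profile)
}

#' Expected share of a fragment family among simulated tRFs
#'
#' Closed-form expectation under the cleavage model: conditioning on a
#' molecule being cleaved, the probability of the protected site is
#' `w_p / (w_p + W)` for unmethylated and `f w_p / (f w_p + W)` for
#' methylated molecules (`f` = protection factor, `W` = total weight of
#' the other sites), mixed by the methylated fraction. For
#' non-protected sites the analogous mixture applies. Returned as a
#' percentage of all tRF reads, which 3'-end jitter does not alter as
#' long as the profiling family window covers the jitter.
#'
#' @param profile A [cleavage_profile()].
#' @param site_index Row of `profile$cut_sites` (default: the protected
#'   site).
#' @return Expected percentage (0-100).
#' @export
expected_fragment_share <- function(profile,
                                    site_index = profile$protected_site) {
  w <- profile$cut_sites$weight
  m <- profile$methylated_fraction
  f <- profile$protection_factor
  p <- profile$protected_site
  w_meth <- w
  if (!is.na(p)) w_meth[p] <- w_meth[p] * f
  share <- (1 - m) * w[site_index] / sum(w) +
    m * w_meth[site_index] / sum(w_meth)
  100 * share
}

#' Simulate small-RNA reads under methylation-dependent cleavage
#'
#' Draws per-molecule methylation state, intact-versus-cleaved fate,
#' cut site and 3' jitter as described in [cleavage_profile()], and
#' emits the resulting sequences as reads together with a ground-truth
#' table of every draw. Given the same seed the output (including any
#' FASTQ written) is byte-identical.
#'
#' @param profile A [cleavage_profile()].
#' @param refs List of [trna_record()] objects (must contain the
#'   profile's parent).
#' @param n_reads Number of molecules to simulate.
#' @param seed Integer seed.
#' @param out_fastq Optional path: write reads as FASTQ (DNA alphabet,
#'   constant quality `I`).
#' @param out_truth Optional path: write the ground-truth TSV.
#' @return A list with `reads` (named character vector, RNA alphabet),
#'   `truth` (data frame: `read_id`, `methylated`, `intact`,
#'   `site_start`, `site_end`, `jitter`, `start`, `end`) and the output
#'   paths used (or NULL).
#' @export
simulate_trna_reads <- function(profile, refs, n_reads, seed,
                                out_fastq = NULL, out_truth = NULL) {
  if (n_reads < 1L) stop("n_reads must be >= 1")
  ids <- vapply(refs, function(r) r$id, "")
  idx <- match(profile$parent_id, ids)
  if (is.na(idx)) stop("reference '", profile$parent_id, "' not supplied")
  ref <- refs[[idx]]
  validate_cleavage_profile(profile, ref)

  set.seed(as.integer(seed))
  n <- as.integer(n_reads)
  meth <- stats::runif(n) < profile$methylated_fraction
  intact <- stats::runif(n) < profile$intact_fraction

  cs <- profile$cut_sites
  k <- nrow(cs)
  w_un <- cs$weight
  w_me <- cs$weight
  if (!is.na(profile$protected_site))
    w_me[profile$protected_site] <- w_me[profile$protected_site] *
      profile$protection_factor
  # full protection can zero out every available cut site for methylated
  # molecules; such molecules cannot be cleaved and stay intact
  if (sum(w_me) == 0) intact <- intact | meth
  if (sum(w_un) == 0) intact <- intact | !meth
  site <- integer(n)
  cut_me <- which(!intact & meth)
  cut_un <- which(!intact & !meth)
  if (length(cut_me))
    site[cut_me] <- sample.int(k, length(cut_me), replace = TRUE, prob = w_me)
  if (length(cut_un))
    site[cut_un] <- sample.int(k, length(cut_un), replace = TRUE, prob = w_un)
  jitter <- sample.int(profile$end_jitter + 1L, n, replace = TRUE) - 1L

  start <- ifelse(intact, 1L, cs$start[pmax(site, 1L)])
  end0 <- ifelse(intact, ref$length, cs$end[pmax(site, 1L)])
  end <- ifelse(intact, ref$length, pmin(end0 + jitter, ref$length))
  seqs <- substring(ref$sequence, start, end)
  read_id <- sprintf("sim%07d", seq_len(n))
  names(seqs) <- read_id

  truth <- data.frame(read_id = read_id, methylated = meth, intact = intact,
                      site_start = ifelse(intact, NA_integer_, cs$start[pmax(site, 1L)]),
                      site_end = ifelse(intact, NA_integer_, end0),
                      jitter = ifelse(intact, 0L, jitter),
                      start = start, end = end,
                      stringsAsFactors = FALSE)
  if (!is.null(out_fastq)) write_fastq(seqs, out_fastq)
  if (!is.null(out_truth))
    utils::write.table(truth, out_truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  list(reads = seqs, truth = truth, fastq = out_fastq, truth_path = out_truth)
}

#' Write reads to FASTQ
#'
#' Sequences are written in the DNA alphabet (U converted to T) with a
#' constant quality of `I` (Phred 40); qualities are ignored by the
#' profiler so the constant is a formality of the format.
#'
#' @param reads Named character vector of sequences.
#' @param path Output path.
#' @param quality_char Quality character (default `"I"`).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, quality_char = "I") {
  dna <- chartr("Uu", "Tt", reads)
  qual <- vapply(nchar(dna), function(l)
    paste(rep(quality_char, l), collapse = ""), "")
  lines <- as.vector(rbind(paste0("@", names(reads)), dna, "+", qual))
  writeLines(lines, path)
  invisible(path)
}

#' Packaged cleavage-profile fixtures
#'
#' Loads the two study-condition profiles shipped with the package —
#' `af25_low` (snoRNA knocked down: low methylated fraction, weak
#' protection of the 47-64 site) and `af25_high` (snoRNA overexpressed:
#' high methylated fraction) — plus stress variants that only scale
#' overall abundance (`*_hypoxia`, `*_oxidative`, `*_starvation`). Both
#' base profiles share cut-site coordinates and weights and differ only
#' in the methylated fraction; their expected 47-64 family shares (50%
#' and 35% of tRFs) are encoded in the fixture parameters and can be
#' recomputed with [expected_fragment_share()].
#'
#' @param path Optional path to a profiles YAML file (defaults to the
#'   packaged fixture).
#' @return Named list of [cleavage_profile()] objects.
#' @export
make_fixture_profiles <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "cleavage_profiles.yaml",
                        package = "snoguard", mustWork = TRUE)
  spec <- yaml::read_yaml(path)
  out <- lapply(spec$profiles, function(p) {
    cleavage_profile(
      parent_id = p$parent_id,
      cut_sites = data.frame(start = vapply(p$cut_sites, `[[`, 0L, "start"),
                             end = vapply(p$cut_sites, `[[`, 0L, "end"),
                             weight = vapply(p$cut_sites, function(s)
                               as.numeric(s$weight), 0)),
      methylated_fraction = p$methylated_fraction,
      protection_factor = p$protection_factor,
      methylation_position = p$methylation_position,
      intact_fraction = p$intact_fraction,
      end_jitter = p$end_jitter,
      abundance_multiplier = p$abundance_multiplier %||% 1)
  })
  names(out) <- vapply(spec$profiles, `[[`, "", "name")
  out
}

#' Parameters of the RTL-Q simulator
#'
#' @param methylated_fraction Fraction m of methylated templates.
#' @param pause_penalty Ct-cycle penalty delta incurred by the low-dNTP
#'   R_D extension at a methylated ribose.
#' @param base_ct Baseline Ct of the assay (default 25 cycles).
#' @param ct_noise_sd Gaussian Ct noise SD (default 0.2 cycles).
#' @return An object of class `rtlq_sim_params`.
#' @export
rtlq_sim_params <- function(methylated_fraction, pause_penalty,
                            base_ct = 25, ct_noise_sd = 0.2) {
  if (methylated_fraction < 0 || methylated_fraction > 1)
    stop("methylated_fraction must lie in [0, 1]")
  if (pause_penalty < 0) stop("pause_penalty must be >= 0")
  if (ct_noise_sd < 0) stop("ct_noise_sd must be >= 0")
  structure(list(methylated_fraction = methylated_fraction,
                 pause_penalty = pause_penalty, base_ct = base_ct,
                 ct_noise_sd = ct_noise_sd),
            class = "rtlq_sim_params")
}

#' Expected EMF under the RTL-Q simulation model
#'
#' The low-dNTP R_D reaction recovers unmethylated templates fully and
#' methylated templates attenuated by `2^-delta`, giving a yield of
#' `(1 - m) + m 2^-delta` and hence an expected EMF of
#' `-log2((1 - m) + m 2^-delta)`: 0 for m = 0 and delta for m = 1.
#'
#' @param methylated_fraction m in \[0, 1\].
#' @param pause_penalty delta >= 0 in Ct cycles.
#' @return Expected EMF in cycles.
#' @export
rtlq_expected_emf <- function(methylated_fraction, pause_penalty) {
  -log2((1 - methylated_fraction) +
          methylated_fraction * 2^-pause_penalty)
}

#' Simulate one RTL-Q Ct quadruple
#'
#' High-dNTP reactions and the on-site R_U primer are unaffected by the
#' mark, so their Ct is `base_ct` plus noise; the low-dNTP R_D reaction
#' loses template to pausing, raising its Ct by
#' `-log2((1 - m) + m 2^-delta)`.
#'
#' @param params An [rtlq_sim_params()].
#' @param seed Optional integer seed.
#' @param replicate_id Optional replicate label.
#' @return A [ct_quadruple()].
#' @export
simulate_rtlq_quadruple <- function(params, seed = NULL,
                                    replicate_id = NA_character_) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  noise <- stats::rnorm(4L, 0, params$ct_noise_sd)
  penalty <- rtlq_expected_emf(params$methylated_fraction,
                               params$pause_penalty)
  ct_quadruple(ct_low_rd = params$base_ct + penalty + noise[1L],
               ct_high_rd = params$base_ct + noise[2L],
               ct_low_ru = params$base_ct + noise[3L],
               ct_high_ru = params$base_ct + noise[4L],
               replicate_id = replicate_id)
}

#' Simulate a qPCR cycle threshold from a relative abundance
#'
#' Standard log2-linear qPCR response:
#' `Ct = base_ct - log2(abundance) + Normal(0, noise_sd)`, so doubling
#' the template lowers Ct by exactly one cycle.
#'
#' @param abundance Positive relative template amount (vectorised).
#' @param base_ct Ct of a unit-abundance template (default 25).
#' @param noise_sd Gaussian noise SD in cycles (default 0.2).
#' @param seed Optional integer seed.
#' @return Simulated Ct values.
#' @export
simulate_qpcr_ct <- function(abundance, base_ct = 25, noise_sd = 0.2,
                             seed = NULL) {
  if (any(abundance <= 0)) stop("abundance must be positive")
  if (!is.null(seed)) set.seed(as.integer(seed))
  base_ct - log2(abundance) + stats::rnorm(length(abundance), 0, noise_sd)
}
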