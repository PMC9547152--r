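#' Build a pipeline run configuration
#'
#' Collects every tunable of an end-to-end run in one validated object.
#' In `simulate` mode the packaged cleavage profiles generate the
#' sequencing reads and Ct tables; in `ingest` mode paths to existing
#' FASTQ/Ct inputs are used instead.
#'
#' @param out_dir Output directory (created if missing).
#' @param mode `"simulate"` or `"ingest"`.
#' @param profiles Profile names from [make_fixture_profiles()] to run
#'   (simulate mode).
#' @param n_reads Reads simulated per profile.
#' @param seed Integer master seed; per-stage seeds derive from it.
#' @param reads_fastq,rtlq_table Named character vectors of input paths
#'   keyed by sample (ingest mode).
#' @param trna_fasta,snorna_fasta Reference FASTA paths (default: the
#'   packaged fixtures).
#' @param min_core,max_terminal_mismatches Duplex-search thresholds.
#' @param trf_max_length tRF/mature boundary in nt.
#' @param alpha,trend Verdict thresholds for group comparisons.
#' @param ct_threshold RTL-Q detection ceiling in cycles.
#' @param rtlq_pause_penalty,rtlq_base_ct,rtlq_noise_sd,rtlq_replicates
#'   RTL-Q simulator settings.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir, mode = c("simulate", "ingest"),
                       profiles = c("af25_low", "af25_high"),
                       n_reads = 20000L, seed = 1L,
                       reads_fastq = NULL, rtlq_table = NULL,
                       trna_fasta = NULL, snorna_fasta = NULL,
                       min_core = 7L, max_terminal_mismatches = 2L,
                       trf_max_length = 45L, alpha = 0.05, trend = 0.1,
                       ct_threshold = 45, rtlq_pause_penalty = 4,
                       rtlq_base_ct = 25, rtlq_noise_sd = 0.2,
                       rtlq_replicates = 12L) {
  cfg <- list(out_dir = out_dir, mode = match.arg(mode),
              profiles = profiles, n_reads = as.integer(n_reads),
              seed = as.integer(seed), reads_fastq = reads_fastq,
              rtlq_table = rtlq_table,
              trna_fasta = trna_fasta %||% snoguard_fixture("trna_fasta"),
              snorna_fasta = snorna_fasta %||% snoguard_fixture("snorna_fasta"),
              min_core = min_core,
              max_terminal_mismatches = max_terminal_mismatches,
              trf_max_length = trf_max_length, alpha = alpha, trend = trend,
              ct_threshold = ct_threshold,
              rtlq_pause_penalty = rtlq_pause_penalty,
              rtlq_base_ct = rtlq_base_ct, rtlq_noise_sd = rtlq_noise_sd,
              rtlq_replicates = as.integer(rtlq_replicates))
  class(cfg) <- "run_config"
  errs <- validate_run_config(cfg)
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  cfg
}

#' Validate a run configuration, reporting every failure
#'
#' @param cfg A `run_config` (or plain list with the same fields).
#' @return Character vector of problems (empty when valid).
#' @export
validate_run_config <- function(cfg) {
  errs <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  chk(is.character(cfg$out_dir) && nzchar(cfg$out_dir),
      "out_dir must be a non-empty path")
  chk(cfg$mode %in% c("simulate", "ingest"), "mode must be simulate/ingest")
  chk(file.exists(cfg$trna_fasta),
      paste0("tRNA FASTA not found: ", cfg$trna_fasta))
  chk(file.exists(cfg$snorna_fasta),
      paste0("snoRNA FASTA not found: ", cfg$snorna_fasta))
  chk(cfg$min_core >= 4 && cfg$min_core <= 20,
      "min_core out of range [4, 20]")
  chk(cfg$max_terminal_mismatches >= 0 && cfg$max_terminal_mismatches <= 4,
      "max_terminal_mismatches out of range [0, 4]")
  chk(cfg$trf_max_length >= 20 && cfg$trf_max_length <= 60,
      "trf_max_length out of range [20, 60]")
  chk(cfg$alpha > 0 && cfg$alpha < cfg$trend && cfg$trend < 1,
      "need 0 < alpha < trend < 1")
  chk(cfg$ct_threshold > 0, "ct_threshold must be positive")
  if (identical(cfg$mode, "simulate")) {
    chk(cfg$n_reads >= 1, "n_reads must be >= 1")
    chk(length(cfg$profiles) >= 1, "at least one profile required")
  } else {
    for (p in c(cfg$reads_fastq, cfg$rtlq_table))
      chk(file.exists(p), paste0("input not found: ", p))
  }
  errs
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [run_config()].
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  spec <- yaml::read_yaml(path)
  do.call(run_config, spec)
}

.stage_seed <- function(cfg, offset) (cfg$seed + offset) %% .Machine$integer.max

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the analysis pipeline end to end
#'
#' Executes, in order: `simulate` (reads, RTL-Q and qPCR Ct tables per
#' condition; skipped in ingest mode), `predict_targets` (snoRNA
#' antisense duplex search against the tRNA references),
#' `profile_trfs` (read assignment, fragment calls, coverage, length
#' histogram, 47-64 family share), `emf` (per-condition methylation
#' call) and `stats` (between-condition comparisons). Each stage reads
#' its inputs from and writes its outputs to `out_dir`, so any stage
#' can be re-run in isolation; a JSON manifest records the seed,
#' configuration and an MD5 checksum per output. Identical
#' configuration and seed reproduce every table byte for byte.
#'
#' @param cfg A [run_config()].
#' @param stages Subset of stages to run (default: all applicable).
#' @return The manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(cfg, stages = c("simulate", "predict_targets",
                                         "profile_trfs", "emf", "stats")) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (cfg$mode == "ingest") stages <- setdiff(stages, "simulate")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()
  refs <- read_fasta_records(cfg$trna_fasta, kind = "trna")
  profiles <- if (cfg$mode == "simulate")
    make_fixture_profiles()[cfg$profiles] else NULL

  if ("simulate" %in% stages)
    outputs <- c(outputs, .stage_simulate(cfg, refs, profiles))
  if ("predict_targets" %in% stages)
    outputs <- c(outputs, .stage_predict(cfg, refs))
  if ("profile_trfs" %in% stages)
    outputs <- c(outputs, .stage_profile(cfg, refs))
  if ("emf" %in% stages)
    outputs <- c(outputs, .stage_emf(cfg))
  if ("stats" %in% stages)
    outputs <- c(outputs, .stage_stats(cfg))

  manifest <- list(
    package = "snoguard",
    version = as.character(utils::packageVersion("snoguard")),
    seed = cfg$seed,
    config = unclass(cfg)[!vapply(unclass(cfg), is.null, TRUE)],
    stages = stages,
    outputs = lapply(stats::setNames(outputs, basename(outputs)), function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))))
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

.sample_names <- function(cfg) {
  if (cfg$mode == "simulate") cfg$profiles else names(cfg$reads_fastq)
}

.stage_simulate <- function(cfg, refs, profiles) {
  out <- character()
  for (i in seq_along(profiles)) {
    name <- names(profiles)[i]
    prof <- profiles[[i]]
    seed_i <- .stage_seed(cfg, 1000L + i)
    fq <- file.path(cfg$out_dir, paste0("reads_", name, ".fastq"))
    tr <- file.path(cfg$out_dir, paste0("truth_", name, ".tsv"))
    simulate_trna_reads(prof, refs, cfg$n_reads, seed = seed_i,
                        out_fastq = fq, out_truth = tr)
    # RTL-Q replicates for this condition's methylated fraction
    set.seed(.stage_seed(cfg, 2000L + i))
    params <- rtlq_sim_params(prof$methylated_fraction,
                              cfg$rtlq_pause_penalty,
                              base_ct = cfg$rtlq_base_ct,
                              ct_noise_sd = cfg$rtlq_noise_sd)
    quads <- lapply(seq_len(cfg$rtlq_replicates), function(r)
      simulate_rtlq_quadruple(params, replicate_id = as.character(r)))
    rtlq <- do.call(rbind, lapply(quads, function(q)
      data.frame(sample = name,
                 replicate = rep(q$replicate_id, 4L),
                 primer = c("RD", "RD", "RU", "RU"),
                 dntp = c("low", "high", "low", "high"),
                 ct = c(q$ct_low_rd, q$ct_high_rd, q$ct_low_ru, q$ct_high_ru),
                 stringsAsFactors = FALSE)))
    rq <- .write_tsv(rtlq, file.path(cfg$out_dir,
                                     paste0("rtlq_", name, ".tsv")))
    # qPCR panel: mature tRNA, tRF and U6 reference Cts
    set.seed(.stage_seed(cfg, 3000L + i))
    n_rep <- 6L
    mult <- prof$abundance_multiplier
    trf_share <- expected_fragment_share(prof) / 100
    qpcr <- data.frame(
      sample = name, replicate = rep(seq_len(n_rep), each = 3L),
      target = rep(c("mature_trna", "trf_47_64", "U6"), n_rep),
      ct = as.vector(rbind(
        simulate_qpcr_ct(rep(mult, n_rep), cfg$rtlq_base_ct,
                         cfg$rtlq_noise_sd),
        simulate_qpcr_ct(rep(mult * trf_share, n_rep),
                         cfg$rtlq_base_ct + 2, cfg$rtlq_noise_sd),
        simulate_qpcr_ct(rep(1, n_rep), cfg$rtlq_base_ct - 5,
                         cfg$rtlq_noise_sd))),
      stringsAsFactors = FALSE)
    qp <- .write_tsv(qpcr, file.path(cfg$out_dir,
                                     paste0("qpcr_", name, ".tsv")))
    out <- c(out, fq, tr, rq, qp)
  }
  out
}

.stage_predict <- function(cfg, refs) {
  sno_seqs <- read_fasta_records(cfg$snorna_fasta, kind = "snorna")
  sno <- sno_record(names(sno_seqs)[1L], sno_seqs[[1L]])
  hits <- do.call(rbind, lapply(refs, function(ref) {
    do.call(rbind, lapply(sno$antisense_elements, function(el)
      find_duplex_hits(el, ref, min_core = cfg$min_core,
                       max_terminal_mismatches = cfg$max_terminal_mismatches)))
  }))
  rownames(hits) <- NULL
  .write_tsv(hits, file.path(cfg$out_dir, "duplex_hits.tsv"))
}

.stage_profile <- function(cfg, refs) {
  out <- character()
  for (name in .sample_names(cfg)) {
    fq <- if (cfg$mode == "simulate")
      file.path(cfg$out_dir, paste0("reads_", name, ".fastq"))
    else cfg$reads_fastq[[name]]
    reads <- read_fastq_reads(fq)
    asg <- assign_reads(reads, refs)
    calls <- call_fragments(asg, trf_max_length = cfg$trf_max_length)
    calls$rpm <- rpm_normalize(calls$count, sum(calls$count))
    out <- c(out, .write_tsv(calls, file.path(
      cfg$out_dir, paste0("fragments_", name, ".tsv"))))
    cov <- data.frame(position = seq_len(refs[[1L]]$length),
                      depth = coverage_profile(calls, refs[[1L]]))
    out <- c(out, .write_tsv(cov, file.path(
      cfg$out_dir, paste0("coverage_", name, ".tsv"))))
    hist <- length_class_histogram(calls)$histogram
    out <- c(out, .write_tsv(hist, file.path(
      cfg$out_dir, paste0("length_histogram_", name, ".tsv"))))
    frac <- data.frame(sample = name, fragment = "tRF 47-64",
                       percent_of_trfs = fragment_fraction(
                         calls, refs[[1L]], "tRF 47-64"))
    out <- c(out, .write_tsv(frac, file.path(
      cfg$out_dir, paste0("fragment_fraction_", name, ".tsv"))))
  }
  out
}

.stage_emf <- function(cfg) {
  rows <- list()
  for (name in .sample_names(cfg)) {
    path <- if (cfg$mode == "simulate")
      file.path(cfg$out_dir, paste0("rtlq_", name, ".tsv"))
    else cfg$rtlq_table[[name]]
    quads <- read_ct_quadruples(path)
    for (s in names(quads)) {
      res <- aggregate_emf(quads[[s]], ct_threshold = cfg$ct_threshold)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s, emf = res$emf, methylated = res$methylated,
        n_replicates = res$n_replicates, emf_sem = res$emf_sem,
        stringsAsFactors = FALSE)
    }
  }
  .write_tsv(do.call(rbind, rows), file.path(cfg$out_dir, "emf.tsv"))
}

.stage_stats <- function(cfg) {
  samples <- .sample_names(cfg)
  rows <- list()
  if (length(samples) >= 2L) {
    a <- samples[1L]; b <- samples[2L]
    # per-replicate EMFs recomputed from the Ct tables
    emfs <- lapply(c(a, b), function(name) {
      path <- if (cfg$mode == "simulate")
        file.path(cfg$out_dir, paste0("rtlq_", name, ".tsv"))
      else cfg$rtlq_table[[name]]
      vapply(read_ct_quadruples(path)[[name]], compute_emf, 0)
    })
    cmp <- compare_groups(emfs[[1L]], emfs[[2L]], paired = FALSE,
                          alpha = cfg$alpha, trend = cfg$trend)
    rows[[1L]] <- data.frame(
      comparison = paste0("EMF: ", a, " vs ", b), method = cmp$method,
      statistic = cmp$statistic, p_value = cmp$p_value,
      verdict = cmp$verdict, stringsAsFactors = FALSE)
    # fragmentation ratio from the simulated qPCR panel
    if (cfg$mode == "simulate") {
      ratios <- lapply(c(a, b), function(name) {
        qp <- utils::read.table(
          file.path(cfg$out_dir, paste0("qpcr_", name, ".tsv")),
          header = TRUE, sep = "\t", stringsAsFactors = FALSE)
        mat <- qp$ct[qp$target == "mature_trna"]
        trf <- qp$ct[qp$target == "trf_47_64"]
        fragmentation_ratio(mat, trf)
      })
      cmp2 <- compare_groups(ratios[[1L]], ratios[[2L]], paired = FALSE,
                             alpha = cfg$alpha, trend = cfg$trend)
      rows[[2L]] <- data.frame(
        comparison = paste0("fragmentation ratio: ", a, " vs ", b),
        method = cmp2$method, statistic = cmp2$statistic,
        p_value = cmp2$p_value, verdict = cmp2$verdict,
        stringsAsFactors = FALSE)
    }
  }
  .write_tsv(do.call(rbind, rows), file.path(cfg$out_dir, "stats.tsv"))
}
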