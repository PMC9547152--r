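refs <- load_fixture_trnas()
profiles <- make_fixture_profiles()

test_that("the same seed reproduces reads, FASTQ bytes and Ct draws", {
  prof <- profiles$af25_low
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- file.path(d1, "r.fastq"); f2 <- file.path(d2, "r.fastq")
  s1 <- simulate_trna_reads(prof, refs, 2000, seed = 7, out_fastq = f1)
  s2 <- simulate_trna_reads(prof, refs, 2000, seed = 7, out_fastq = f2)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  s3 <- simulate_trna_reads(prof, refs, 2000, seed = 8)
  expect_false(identical(s1$truth, s3$truth))

  p <- rtlq_sim_params(0.5, 4)
  expect_identical(simulate_rtlq_quadruple(p, seed = 1),
                   simulate_rtlq_quadruple(p, seed = 1))
})

test_that("intact molecules yield full-length reads and no tRFs", {
  prof <- cleavage_profile("tRNA-Leu-TAA-synthetic-mouse",
                           data.frame(start = 47, end = 64, weight = 1),
                           methylated_fraction = 0.5,
                           protection_factor = 0.5,
                           methylation_position = 65,
                           intact_fraction = 1)
  sim <- simulate_trna_reads(prof, refs, 500, seed = 11)
  expect_true(all(sim$truth$intact))
  expect_true(all(nchar(sim$reads) == refs[[1]]$length))
  calls <- call_fragments(assign_reads(sim$reads, refs))
  expect_identical(sum(calls$class == "tRF"), 0L)
})

test_that("full protection eliminates the protected fragment", {
  prof <- cleavage_profile("tRNA-Leu-TAA-synthetic-mouse",
                           data.frame(start = 47, end = 64, weight = 1),
                           methylated_fraction = 1,
                           protection_factor = 0,
                           methylation_position = 65,
                           intact_fraction = 0)
  sim <- simulate_trna_reads(prof, refs, 500, seed = 12)
  expect_identical(sum(!is.na(sim$truth$site_start)), 0L)
  expect_true(all(nchar(sim$reads) == refs[[1]]$length))
})

test_that("unprotected two-site cleavage splits reads binomially", {
  prof <- cleavage_profile("tRNA-Leu-TAA-synthetic-mouse",
                           data.frame(start = c(1, 47), end = c(30, 64),
                                      weight = c(1, 1)),
                           methylated_fraction = 0,
                           protection_factor = 1,
                           methylation_position = 65,
                           intact_fraction = 0)
  n <- 100000
  sim <- simulate_trna_reads(prof, refs, n, seed = 13)
  share <- mean(sim$truth$site_start == 47)
  se <- sqrt(0.5 * 0.5 / n)
  expect_lt(abs(share - 0.5), 3 * se)
})

test_that("profile validation catches coordinates outside the reference", {
  expect_error(
    validate_cleavage_profile(
      cleavage_profile("tRNA-Leu-TAA-synthetic-mouse",
                       data.frame(start = 47, end = 99, weight = 1),
                       0.5, 0.5, 100, intact_fraction = 0),
      refs[[1]]),
    "outside reference")
  expect_error(cleavage_profile("x", data.frame(start = 1, end = 10,
                                                weight = 1),
                                0.5, 0.5, methylation_position = 20),
               "abut")
  expect_error(cleavage_profile("x", data.frame(start = 1, end = 10,
                                                weight = 0),
                                0.5, 0.5, 11), "not all zero")
})

test_that("fixture profiles encode the documented fragment shares", {
  spec <- yaml::read_yaml(snoguard_fixture("profiles_yaml"))
  documented <- vapply(spec$profiles, function(p)
    if (is.null(p$expected_share_47_64)) NA_real_
    else p$expected_share_47_64, 0)
  names(documented) <- vapply(spec$profiles, `[[`, "", "name")
  expect_equal(expected_fragment_share(profiles$af25_low),
               documented[["af25_low"]])
  expect_equal(expected_fragment_share(profiles$af25_high),
               documented[["af25_high"]])
  # shared cut-site geometry; only the methylated fraction differs
  expect_identical(profiles$af25_low$cut_sites, profiles$af25_high$cut_sites)
  expect_identical(profiles$af25_low$protection_factor,
                   profiles$af25_high$protection_factor)
  expect_true(profiles$af25_low$methylated_fraction <
                profiles$af25_high$methylated_fraction)
})

test_that("more methylation means a smaller protected-fragment share", {
  base <- profiles$af25_low
  shares <- vapply(seq(0, 1, by = 0.1), function(m) {
    p <- base; p$methylated_fraction <- m
    expected_fragment_share(p)
  }, 0)
  expect_true(all(diff(shares) < 0))
})

test_that("profiling simulated reads recovers the generating share", {
  n <- 20000
  sim <- simulate_trna_reads(profiles$af25_low, refs, n, seed = 14)
  calls <- call_fragments(assign_reads(sim$reads, refs))
  got <- fragment_fraction(calls, refs[[1]], "tRF 47-64")
  p <- expected_fragment_share(profiles$af25_low) / 100
  n_trf <- sum(calls$count[calls$class == "tRF"])
  se <- 100 * sqrt(p * (1 - p) / n_trf)
  expect_lt(abs(got - 100 * p), 3 * se)
})

test_that("qPCR simulation follows the log2-linear response", {
  expect_equal(simulate_qpcr_ct(1, base_ct = 25, noise_sd = 0), 25)
  expect_equal(simulate_qpcr_ct(2, base_ct = 25, noise_sd = 0) -
                 simulate_qpcr_ct(4, base_ct = 25, noise_sd = 0), 1)
  expect_error(simulate_qpcr_ct(0), "positive")
  set.seed(45)
  cts <- simulate_qpcr_ct(rep(8, 400), base_ct = 30, noise_sd = 0.3)
  expect_lt(abs(mean(cts) - 27), 3 * 0.3 / sqrt(400))
})

test_that("RTL-Q simulation hits the closed-form EMF in the noiseless limit", {
  q0 <- simulate_rtlq_quadruple(rtlq_sim_params(0, 4, ct_noise_sd = 0))
  expect_equal(compute_emf(q0), 0)
  q1 <- simulate_rtlq_quadruple(rtlq_sim_params(1, 4, ct_noise_sd = 0))
  expect_equal(compute_emf(q1), 4)
  qh <- simulate_rtlq_quadruple(rtlq_sim_params(0.5, 4, ct_noise_sd = 0))
  expect_equal(compute_emf(qh), -log2(0.5 + 0.5 * 2^-4))
  expect_equal(rtlq_expected_emf(0.5, 4), 0.91253716, tolerance = 1e-7)
})

test_that("parameter construction rejects invalid simulator settings", {
  expect_error(rtlq_sim_params(1.5, 4), "\\[0, 1\\]")
  expect_error(rtlq_sim_params(0.5, -1), ">= 0")
  expect_error(simulate_trna_reads(profiles$af25_low, refs, 0, seed = 1),
               ">= 1")
})
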