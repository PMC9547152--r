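test_that("unique exact matches are assigned with correct coordinates", {
  refs <- load_fixture_trnas()[1]
  frag <- substr(refs[[1]]$sequence, 47, 64)
  res <- assign_reads(c(r1 = frag), refs)
  expect_identical(res$assignments$start, 47L)
  expect_identical(res$assignments$end, 64L)
  expect_identical(res$assignments$mapping, "unique")
  expect_identical(res$unassigned, 0L)
})

test_that("multimappers go to the reference with most unique reads", {
  mm <- make_multimap_refs()
  refs <- list(mm$refA, mm$refB)
  uniqA <- substr(mm$refA$sequence, 1, 20)
  uniqB <- substr(mm$refB$sequence, 1, 20)
  reads <- c(setNames(rep(uniqA, 10), sprintf("a%02d", 1:10)),
             setNames(rep(uniqB, 2), sprintf("b%02d", 1:2)),
             shared = mm$shared)
  res <- assign_reads(reads, refs)
  shared_row <- res$assignments[res$assignments$read_id == "shared", ]
  expect_identical(shared_row$parent_id, "refA")
  expect_identical(shared_row$mapping, "rescued_multi")
  expect_identical(unname(res$per_parent_unique["refA"]), 10L)
  expect_identical(unname(res$per_parent_unique["refB"]), 2L)

  # equal unique counts: lexicographic tie-break
  reads_tie <- c(setNames(rep(uniqA, 2), c("a1", "a2")),
                 setNames(rep(uniqB, 2), c("b1", "b2")),
                 shared = mm$shared)
  res_tie <- assign_reads(reads_tie, refs)
  expect_identical(
    res_tie$assignments$parent_id[res_tie$assignments$read_id == "shared"],
    "refA")
})

test_that("mismatching and short reads are unassigned or dropped", {
  refs <- load_fixture_trnas()[1]
  frag <- substr(refs[[1]]$sequence, 47, 64)
  mut <- frag
  substr(mut, 9, 9) <- setdiff(c("A", "C", "G", "U"), substr(frag, 9, 9))[1]
  res <- assign_reads(c(x = mut, y = "ACGUACGUACGU"), refs)
  expect_identical(res$unassigned, 1L)  # the mismatched 18-mer
  expect_identical(res$dropped, 1L)     # the 12-mer, below 15 nt
  expect_identical(nrow(res$assignments), 0L)
  expect_error(assign_reads(c(x = frag), list()), "no reference")
})

test_that("read accounting is conserved and order-independent", {
  set.seed(21)
  refs <- load_fixture_trnas()
  ref <- refs[[1]]
  prof <- make_fixture_profiles()$af25_low
  reads <- simulate_trna_reads(prof, refs, 3000, seed = 5)$reads
  junk <- setNames(replicate(50, random_rna(20)), sprintf("junk%02d", 1:50))
  short <- setNames(replicate(10, random_rna(10)), sprintf("short%02d", 1:10))
  all_reads <- c(reads, junk, short)
  res <- assign_reads(all_reads, refs)
  expect_identical(nrow(res$assignments) + res$unassigned + res$dropped,
                   length(all_reads))

  perm <- sample(length(all_reads))
  res2 <- assign_reads(all_reads[perm], refs)
  tot1 <- table(res$assignments$parent_id)
  tot2 <- table(res2$assignments$parent_id)
  expect_identical(tot1, tot2)
})

test_that("fragment calls group, name and classify reads", {
  refs <- load_fixture_trnas()[1]
  seq <- refs[[1]]$sequence
  frag <- substr(seq, 47, 64)
  reads <- c(r1 = frag, r2 = frag, r3 = frag, full = seq)
  calls <- call_fragments(assign_reads(reads, refs))
  trf <- calls[calls$class == "tRF", ]
  expect_identical(nrow(trf), 1L)
  expect_identical(trf$count, 3L)
  expect_identical(trf$length, 18L)
  expect_identical(trf$name, "tRF 47-64")
  expect_identical(calls$class[calls$start == 1 & calls$end == 85], "mature")
})

test_that("call counts plus mature reads conserve assigned reads", {
  set.seed(22)
  refs <- load_fixture_trnas()
  reads <- simulate_trna_reads(make_fixture_profiles()$af25_high, refs,
                               5000, seed = 9)$reads
  asg <- assign_reads(reads, refs)
  calls <- call_fragments(asg)
  expect_identical(sum(calls$count), nrow(asg$assignments))
})

test_that("RPM normalisation scales and conserves", {
  expect_equal(rpm_normalize(5, 1e6), 5)
  expect_equal(rpm_normalize(1234, 1234), 1e6)
  expect_error(rpm_normalize(5, 0), "positive")
  set.seed(23)
  for (i in 1:10) {
    counts <- rmultinom(1, 1e5, prob = runif(6))[, 1]
    expect_equal(sum(rpm_normalize(counts, sum(counts))), 1e6)
  }
})

test_that("length histogram recovers class proportions", {
  calls <- data.frame(parent_id = "t", start = c(1, 1), end = c(18, 30),
                      length = c(18, 30), count = c(1, 1),
                      class = "tRF", name = c("tRF 1-18", "tRF 1-30"))
  h <- length_class_histogram(calls)
  expect_equal(h$small_percent, 50)
  expect_equal(h$large_percent, 50)

  calls$length <- c(18, 18); calls$end <- c(18, 18)
  h2 <- length_class_histogram(calls)
  expect_equal(h2$small_percent, 100)

  set.seed(24)
  n_small <- 70; n_large <- 30
  calls3 <- data.frame(
    parent_id = "t", start = 1,
    end = c(sample(18:29, n_small, TRUE), sample(30:45, n_large, TRUE)),
    count = 1, class = "tRF", name = "x")
  calls3$length <- calls3$end
  h3 <- length_class_histogram(calls3)
  expect_equal(h3$small_percent, 70)
  expect_equal(h3$large_percent, 30)
  expect_equal(sum(h3$histogram$count), 100)
})

test_that("coverage adds overlapping calls and conserves read mass", {
  ref <- load_fixture_trnas()[[1]]
  calls <- data.frame(parent_id = ref$id, start = c(47, 40, 50),
                      end = c(64, 60, 70), count = c(1, 2, 3))
  calls$length <- calls$end - calls$start + 1
  calls$class <- "tRF"; calls$name <- "x"
  depth <- coverage_profile(calls[1, ], ref)
  expect_identical(length(depth), ref$length)
  expect_true(all(depth[47:64] == 1) && sum(depth) == 18)

  depth2 <- coverage_profile(calls[2:3, ], ref)
  expect_true(all(depth2[50:60] == 5))

  set.seed(25)
  rand <- data.frame(parent_id = ref$id,
                     start = sample(1:60, 30, TRUE))
  rand$end <- pmin(rand$start + sample(17:30, 30, TRUE), ref$length)
  rand$count <- sample(1:9, 30, TRUE)
  rand$length <- rand$end - rand$start + 1
  rand$class <- "tRF"; rand$name <- "x"
  expect_equal(sum(coverage_profile(rand, ref)),
               sum(rand$count * rand$length))
})

test_that("fragment family share matches a brute-force recount", {
  set.seed(26)
  refs <- load_fixture_trnas()
  prof <- make_fixture_profiles()$af25_low
  asg <- assign_reads(simulate_trna_reads(prof, refs, 8000, seed = 3)$reads,
                      refs)
  calls <- call_fragments(asg)
  got <- fragment_fraction(calls, refs[[1]], "tRF 47-64")
  a <- asg$assignments
  trf_reads <- a[a$parent_id == refs[[1]]$id & (a$end - a$start + 1) < 45, ]
  fam <- trf_reads$start == 47 & trf_reads$end >= 64 & trf_reads$end <= 66
  expect_equal(got, 100 * sum(fam) / nrow(trf_reads))

  only <- calls[calls$start == 47 & calls$class == "tRF", ]
  expect_equal(fragment_fraction(only, refs[[1]], "tRF 47-64"), 100)
  empty <- calls[0, ]
  expect_error(fragment_fraction(empty, refs[[1]], "tRF 47-64"), "no tRF")
})

test_that("profile summary bundles RPM, fragments and coverage", {
  refs <- load_fixture_trnas()
  prof <- make_fixture_profiles()$af25_low
  asg <- assign_reads(simulate_trna_reads(prof, refs, 2000, seed = 4)$reads,
                      refs)
  ps <- profile_summary(asg, refs)
  expect_lte(sum(ps$class_rpm), 1e6 + 1e-6)
  expect_equal(sum(ps$fragments$rpm), 1e6)
  expect_identical(names(ps$coverage), unname(vapply(refs, `[[`, "", "id")))
  expect_equal(sum(ps$length_classes$histogram$count),
               sum(ps$fragments$count[ps$fragments$class == "tRF"]))
})
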