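test_that("fixture generation is deterministic and respects the spec", {
  spec <- fixture_spec(c(300, 150),
                       hotspots = data.frame(reference = 1, start = 100,
                                             end = 140, weight = 0.8),
                       reads_per_sample = 150, n_samples = 2, seed = 99)
  fx1 <- generate_fixture(spec)
  fx2 <- generate_fixture(spec)
  expect_identical(fx1$references$sequence, fx2$references$sequence)
  expect_identical(fx1$samples, fx2$samples)
  expect_identical(fx1$truth, fx2$truth)
  expect_identical(names(fx1$samples), c("sample1", "sample2"))
  expect_identical(nrow(fx1$truth), 300L)
  # written files are byte-identical across runs too
  d1 <- tempfile(); d2 <- tempfile()
  generate_fixture(spec, dir = d1); generate_fixture(spec, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # the generator leaves the caller's RNG stream untouched
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(generate_fixture(spec)); after <- runif(1)
  expect_identical(before, after)
})

test_that("hotspot weight 1 puts every read origin inside the hotspot", {
  spec <- fixture_spec(200,
                       hotspots = data.frame(reference = 1, start = 50,
                                             end = 120, weight = 1),
                       reads_per_sample = 100, n_samples = 1, seed = 5)
  fx <- generate_fixture(spec)
  tr <- fx$truth
  expect_true(all(tr$component == "hotspot1"))
  expect_true(all(tr$start >= 50 & tr$start < 120))   # origin overlaps hotspot
})

test_that("observed hotspot fraction is within 3 standard errors of its weight", {
  w <- 0.9
  spec <- fixture_spec(500,
                       hotspots = data.frame(reference = 1, start = 200,
                                             end = 260, weight = w),
                       reads_per_sample = 10000, n_samples = 1, seed = 123)
  fx <- generate_fixture(spec)
  obs <- mean(fx$truth$component == "hotspot1")
  se <- sqrt(w * (1 - w) / 10000)
  expect_lt(abs(obs - w), 3 * se)
})

test_that("truth origins are consistent with the emitted reads", {
  spec <- fixture_spec(250, reads_per_sample = 60, n_samples = 1,
                       mismatch_rate = 0, seed = 17)
  fx <- generate_fixture(spec)
  smp <- suppressMessages(align_reads(fx$samples[[1]], fx$references,
                                      aligner_config(max_mismatches = 0)))
  tr <- fx$truth
  for (i in seq_len(nrow(tr))) {
    a <- smp$alignments[smp$alignments$read_id == tr$read_id[i], ]
    # the true origin must be among the zero-mismatch placements
    expect_true(any(a$reference_id == tr$reference_id[i] &
                      a$start == tr$start[i] & a$end == tr$end[i]))
  }
  # read sequences equal their origin substrings at mismatch rate 0
  expect_identical(fx$samples[[1]]$sequence,
                   substring(fx$references$sequence[match(tr$reference_id,
                                                          fx$references$id)],
                             tr$start + 1, tr$end))
})

test_that("mismatch injection matches the recorded error counts", {
  spec <- fixture_spec(250, reads_per_sample = 80, n_samples = 1,
                       mismatch_rate = 0.05, seed = 19)
  fx <- generate_fixture(spec)
  tr <- fx$truth
  origin <- substring(fx$references$sequence[match(tr$reference_id, fx$references$id)],
                      tr$start + 1, tr$end)
  ham <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, fx$samples[[1]]$sequence, origin)
  expect_equal(unname(ham), tr$n_errors)
  expect_gt(sum(tr$n_errors), 0)
})

test_that("infeasible fixture specs are rejected", {
  expect_error(fixture_spec(100, hotspots = data.frame(
    reference = 1, start = 10, end = 20, weight = 0.5)), "infeasible")
  expect_error(fixture_spec(c(100, 50), hotspots = data.frame(
    reference = 1, start = 10, end = 60, weight = 0.6),
    read_length_range = c(19, 32), reads_per_sample = 10,
    n_samples = 1, seed = 1, mismatch_rate = 2), "mismatch_rate")
})

test_that("antisense islands land where requested", {
  oligo <- strrep("GCAU", 7)
  tx <- plant_antisense_island(300, oligo, 100, seed = 7)
  expect_identical(substr(tx, 101, 128), rna_revcomp(oligo))
  expect_identical(nchar(tx), 300L)
  expect_error(plant_antisense_island(100, oligo, 90), "does not fit")
  # two islands in one transcript are both recoverable
  tx2 <- plant_antisense_island(300, oligo, 100, seed = 8)
  ch <- strsplit(tx2, "")[[1]]
  ch[201:228] <- strsplit(rna_revcomp(oligo), "")[[1]]
  tx2 <- paste(ch, collapse = "")
  scan <- offtarget_scan(data.frame(oligo_id = "o", sequence = oligo),
                         rna_references("t", tx2),
                         params = list(seed = 28L, energy_max = 0))
  expect_identical(sort(scan$hits$start), c(100L, 200L))
})
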