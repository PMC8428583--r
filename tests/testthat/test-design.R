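test_that("oligo enumeration tiles every reference at every length", {
  set.seed(60)
  refs <- make_refs(30)
  ol <- enumerate_oligos(refs, 25, 25)
  expect_identical(nrow(ol), 6L)                      # 30 - 25 + 1
  expect_identical(ol$start, 0:5)
  expect_identical(ol$sequence, rna_revcomp(
    substring(refs$sequence, ol$start + 1, ol$end)))
  expect_identical(ol$oligo_id[1], "ref1|1-25|25")

  short <- make_refs(c(100, 20), ids = c("big", "small"))
  ol2 <- enumerate_oligos(short, 25, 25)
  expect_identical(unique(ol2$reference_id), "big")   # short ref contributes 0

  expect_error(enumerate_oligos(refs, 30, 25), "invalid")
})

test_that("enumeration count matches the closed form over random inputs", {
  set.seed(61)
  for (i in 1:5) {
    lens <- sample(20:120, sample(1:4, 1))
    lmin <- sample(10:25, 1); lmax <- lmin + sample(0:6, 1)
    refs <- make_refs(lens)
    ol <- enumerate_oligos(refs, lmin, lmax)
    expected <- sum(vapply(lens, function(L)
      sum(pmax(0L, L - (lmin:lmax) + 1L)), numeric(1)))
    expect_identical(nrow(ol), as.integer(expected))
    expect_false(anyDuplicated(ol$oligo_id) > 0)
  }
})

test_that("depletion regions include the source interval and all rRNA copies", {
  set.seed(62)
  refs <- make_refs(200)
  ol <- enumerate_oligos(refs, 25, 25)[50, ]
  rg <- depletion_regions_for(ol, refs)
  expect_true(any(rg$reference_id == ol$reference_id &
                    rg$start == ol$start & rg$end == ol$end))
  expect_true(all(rg$complementary_stretch >= design_seed(25)))

  # duplicated rRNA copy: the same region is found on both copies
  two <- rna_references(c("copyA", "copyB"),
                        c(refs$sequence, refs$sequence))
  rg2 <- depletion_regions_for(ol, two)
  expect_identical(sort(unique(rg2$reference_id)), c("copyA", "copyB"))
  for (cp in c("copyA", "copyB")) {
    exp <- oracle_runs(ol$sequence, refs$sequence, design_seed(25), FALSE)
    got <- rg2[rg2$reference_id == cp, ]
    expect_identical(got$start, exp$target_start)
    expect_identical(got$end, exp$target_end)
  }
})

test_that("the depletability rule applies coverage and overhang bounds strictly", {
  region <- list(reference_id = "r", start = 95L, end = 130L)
  a <- data.frame(reference_id = "r", start = 100L, end = 120L)
  expect_true(is_depletable(a, region, 25))           # coverage 20 >= 16, overhang 0
  region2 <- list(reference_id = "r", start = 100L, end = 130L)
  expect_false(is_depletable(data.frame(reference_id = "r", start = 85L, end = 115L),
                             region2, 25))            # coverage 15 < 16
  expect_false(is_depletable(data.frame(reference_id = "r", start = 91L, end = 120L),
                             region2, 25))            # overhang 9 > 8
  expect_false(is_depletable(data.frame(reference_id = "other", start = 100L, end = 120L),
                             region2, 25))            # different reference
  # rule bounds themselves
  expect_identical(depletion_rule(25), list(coverage_min = 16L, overhang_max = 8L))
  expect_identical(depletion_rule(12), list(coverage_min = 10L, overhang_max = 4L))
  expect_identical(depletion_rule(45), list(coverage_min = 30L, overhang_max = 10L))
})

test_that("depleting potential counts each primary read once across regions", {
  set.seed(63)
  refs <- make_refs(300)
  ol <- data.frame(oligo_id = "o", reference_id = "ref1", start = 100L,
                   end = 125L, length = 25L,
                   sequence = rna_revcomp(substr(refs$sequence, 101, 125)))
  regions <- data.frame(reference_id = "ref1",
                        start = c(100L, 110L), end = c(125L, 135L))
  # 100 primary reads, 40 inside the region, 60 far away
  mk <- function(n, lo) data.frame(
    read_id = if (n) sprintf("r%d_%d", lo, seq_len(n)) else character(0),
    reference_id = rep("ref1", n),
    start = rep(lo, n), end = rep(lo + 22L, n),
    is_primary = rep(TRUE, n), mismatches = rep(0L, n))
  smp <- pilot_sample("s", rbind(mk(40, 101L), mk(60, 200L)), refs)
  expect_equal(depleting_potential(ol, smp, regions), 0.4)
  # overlapping regions never double-count a read
  expect_lte(depleting_potential(ol, smp, regions), 1)
  # reads that touch no region
  far <- pilot_sample("f", mk(10, 250L), refs)
  expect_equal(depleting_potential(ol, far, regions), 0)
  # empty sample is an error
  empty <- pilot_sample("e", mk(0, 1L), refs)
  expect_error(depleting_potential(ol, empty, regions), "no primary")
})

test_that("pipeline potentials equal the per-read brute-force oracle", {
  for (trial in 1:6) {
    set.seed(300 + trial)
    lens <- sample(150:400, sample(1:2, 1))
    spec <- fixture_spec(lens, reads_per_sample = 200, n_samples = 1,
                         seed = 300 + trial)
    fx <- generate_fixture(spec)
    smp <- truth_alignments(fx)[[1]]
    for (l in c(12, 20, 25, 30)) {
      ol <- enumerate_oligos(fx$references, l, l)
      ol <- ol[sample(nrow(ol), 2), ]
      for (i in 1:2) {
        rg <- depletion_regions_for(ol[i, ], fx$references)
        got <- depleting_potential(ol[i, ], smp, rg)
        expect_identical(got, oracle_potential(l, rg, smp))
      }
    }
  }
})

test_that("potential is monotone when a depletion region is enlarged", {
  set.seed(70)
  refs <- make_refs(300)
  ol <- list(sequence = rna_revcomp(substr(refs$sequence, 101, 125)))
  spec <- fixture_spec(300, reads_per_sample = 300, n_samples = 1, seed = 70)
  smp <- truth_alignments(generate_fixture(spec))[[1]]
  smp$alignments$reference_id <- "ref1"
  smp <- pilot_sample("s", smp$alignments, refs)
  base <- data.frame(reference_id = "ref1", start = 100L, end = 125L)
  p0 <- depleting_potential(ol, smp, base)
  for (grow in c(5L, 10L, 20L)) {
    bigger <- data.frame(reference_id = "ref1",
                         start = max(0L, 100L - grow), end = 125L + grow)
    expect_gte(depleting_potential(ol, smp, bigger), p0)
  }
})

test_that("potential filtering and overall score use strict inequalities", {
  cfg <- design_config(25, 25)
  # fraction-below exactly 0.75 is kept (not strictly greater)
  expect_true(filter_oligos(matrix(c(0.06, 0.01, 0.01, 0.01), 1), cfg))
  expect_false(filter_oligos(matrix(rep(0.01, 4), 1), cfg))
  # potential exactly at the threshold does not count as below it
  expect_true(filter_oligos(matrix(0.05, 1, 1), cfg))
  expect_error(filter_oligos(matrix(numeric(0), 1, 0), cfg), "no pilot samples")

  expect_equal(overall_depletion_score(c(0.06, 0.04), 0.05), 0.5)
  expect_equal(overall_depletion_score(c(0.2, 0.9, 0.06), 0.05), 1)
  expect_equal(overall_depletion_score(0.05, 0.05), 0)   # strict >
})

test_that("gc_content counts G and C over the length", {
  expect_equal(gc_content("GCGC"), 1)
  expect_equal(gc_content("AUAU"), 0)
  expect_equal(gc_content("ACGU"), 0.5)
  expect_equal(gc_content(c("GGAA", "GCAU")), c(0.5, 0.5))
  expect_error(gc_content(""), "empty")
})

test_that("feature assembly populates every column consistently", {
  set.seed(71)
  refs <- make_refs(80)
  ol <- enumerate_oligos(refs, 25, 25)[c(1, 10), ]
  pots <- matrix(c(0.4, 0.02, 0.3, 0.06), 2, 2,
                 dimnames = list(NULL, c("s1", "s2")))
  f <- assemble_features(ol, pots)
  expect_identical(f$oligo_id, ol$oligo_id)
  expect_identical(f$target_rRNA_position,
                   sprintf("ref1:%d-%d", ol$start + 1, ol$end))
  expect_identical(nchar(f$structure), ol$length)
  expect_equal(f$base_pairing_percentage,
               vapply(f$structure, function(s)
                 2 * sum(strsplit(s, "")[[1]] == "(") / nchar(s), numeric(1),
                 USE.NAMES = FALSE))
  expect_equal(f$overall_depletion_score, c(1, 0.5))
  expect_identical(f[["potential.s1"]], pots[, 1])
  expect_false("n_offtargets" %in% names(f))
  f2 <- assemble_features(ol, pots, offtarget_counts = setNames(c(3L, 0L), ol$oligo_id))
  expect_identical(f2$n_offtargets, c(3L, 0L))
  expect_true(all(f$minimum_hybridization_energy < 0))
  expect_true(all(f$gc_content >= 0 & f$gc_content <= 1))
})

test_that("disjoint oligos capturing disjoint reads have potentials summing <= 1", {
  set.seed(72)
  refs <- make_refs(400)
  spec <- fixture_spec(400, reads_per_sample = 250, n_samples = 1, seed = 72)
  smp <- truth_alignments(generate_fixture(spec))[[1]]
  smp$alignments$reference_id <- "ref1"
  smp <- pilot_sample("s", smp$alignments, refs)
  ol <- enumerate_oligos(refs, 25, 25)
  picks <- ol[match(c(0L, 100L, 200L, 300L), ol$start), ]
  tot <- 0
  for (i in seq_len(nrow(picks))) {
    rg <- depletion_regions_for(picks[i, ], refs)
    tot <- tot + depleting_potential(picks[i, ], smp, rg)
  }
  expect_lte(tot, 1)
})
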