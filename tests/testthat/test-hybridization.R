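test_that("duplex energies follow the shipped nearest-neighbor table", {
  em <- energy_model()
  # degenerate single-pair duplex: initiation only
  expect_equal(duplex_energy("G"), em$init_term)
  # hand sum over the shipped table: GCGC / GCGC pairs GC,CG,GC,CG
  hand <- em$init_term + em$stack_table["GC", "CG"] +
    em$stack_table["CG", "GC"] + em$stack_table["GC", "CG"]
  expect_equal(duplex_energy("GCGC"), hand)
  expect_equal(hand, 4.09 - 3.4 - 2.4 - 3.4)
  # terminal AU ends are penalized
  expect_equal(duplex_energy("AGCA"),
               em$init_term + em$stack_table["AU", "GC"] +
                 em$stack_table["GC", "CG"] + em$stack_table["CG", "AU"] +
                 2 * em$au_end_penalty)
  expect_error(duplex_energy(""), "length 0")
})

test_that("the duplex model is strand-symmetric", {
  set.seed(40)
  for (i in 1:20) {
    a <- random_rna_string(sample(5:30, 1))
    b <- rna_revcomp(a)
    expect_equal(duplex_energy(a, b), duplex_energy(b, a))
  }
})

test_that("Watson-Crick stacks always stabilize; GC beats AU duplexes", {
  st <- energy_model()$stack_table
  wc <- c("CG", "GC", "AU", "UA")
  expect_true(all(st[wc, wc] < 0))
  e_gc <- min_hybridization_energy(strrep("G", 25))
  e_au <- min_hybridization_energy(strrep("A", 25))
  expect_lt(e_gc, e_au)
  set.seed(41)
  for (i in 1:10) {
    expect_lte(min_hybridization_energy(random_rna_string(25)),
               energy_model()$init_term)
  }
})

test_that("duplex_search finds planted targets and nothing spurious", {
  set.seed(42)
  refs <- make_refs(400)
  oligo <- rna_revcomp(substr(refs$sequence, 101, 125))
  h <- duplex_search(oligo, refs, duplex_params(16))
  expect_identical(nrow(h), 1L)
  expect_identical(c(h$target_start, h$target_end), c(100L, 125L))
  expect_identical(h$stretch, 25L)
  expect_identical(c(h$query_start, h$query_end), c(0L, 25L))

  # a poly-A oligo has no complementary run >= 10 in a poly-A reference
  polya <- rna_references("pa", strrep("A", 100))
  expect_identical(nrow(duplex_search(strrep("A", 20), polya, duplex_params(10))), 0L)

  # duplicated target region: two hits with equal energy
  set.seed(43)
  core <- random_rna_string(30)
  dup <- rna_references("dup", paste0(random_rna_string(50), core,
                                      random_rna_string(60), core,
                                      random_rna_string(40)))
  h2 <- duplex_search(rna_revcomp(core), dup, duplex_params(20))
  expect_identical(nrow(h2), 2L)
  expect_equal(h2$energy[1], h2$energy[2])
  expect_identical(h2$target_start, c(50L, 140L))
})

test_that("duplex_search equals the brute-force complementarity oracle", {
  for (trial in 1:6) {
    set.seed(200 + trial)
    refs <- make_refs(300)
    # half the trials: an oligo related to the reference; half: unrelated
    oligo <- if (trial %% 2) {
      st <- sample(250, 1)
      ch <- strsplit(rna_revcomp(substr(refs$sequence, st, st + 24)), "")[[1]]
      p <- sample(25, 2)
      ch[p] <- sample(BASES, 2, replace = TRUE)
      paste(ch, collapse = "")
    } else random_rna_string(25)
    for (s in c(10, 13, 16)) {
      for (wob in c(TRUE, FALSE)) {
        got <- duplex_search(oligo, refs, duplex_params(s, wobble = wob))
        exp <- oracle_runs(oligo, refs$sequence, s, wob)
        expect_identical(nrow(got), nrow(exp))
        if (nrow(got)) {
          expect_identical(got$target_start, exp$target_start)
          expect_identical(got$target_end, exp$target_end)
          expect_identical(got$stretch, exp$stretch)
        }
      }
    }
  }
})

test_that("self-folding returns well-formed minimum-energy structures", {
  expect_identical(self_fold("AAAAAAAA"),
                   list(structure = "........", mfe = 0, bp_fraction = 0))
  expect_identical(self_fold("A"), list(structure = ".", mfe = 0, bp_fraction = 0))
  f <- self_fold("GGGGAAAACCCC")
  expect_lt(f$mfe, 0)
  expect_gt(f$bp_fraction, 0)
  expect_identical(nchar(f$structure), 12L)

  set.seed(50)
  for (i in 1:15) {
    sq <- random_rna_string(sample(15:35, 1))
    f <- self_fold(sq)
    expect_identical(nchar(f$structure), nchar(sq))
    expect_lte(f$mfe, 0)
    ch <- strsplit(f$structure, "")[[1]]
    expect_identical(sum(ch == "("), sum(ch == ")"))
    expect_equal(f$bp_fraction, 2 * sum(ch == "(") / nchar(sq))
    # balanced nesting and hairpin loops of at least 3 unpaired bases
    depth <- 0; stack <- integer(0); ok_hairpin <- TRUE
    for (k in seq_along(ch)) {
      if (ch[k] == "(") { stack <- c(stack, k); depth <- depth + 1 }
      if (ch[k] == ")") {
        expect_gt(depth, 0)
        j <- stack[length(stack)]; stack <- stack[-length(stack)]
        depth <- depth - 1
        if (k - j - 1 < 3 && !any(ch[(j + 1):(k - 1)] %in% c("(", ")"))) {
          ok_hairpin <- FALSE
        }
      }
    }
    expect_true(ok_hairpin)
    expect_identical(depth, 0)
  }
})

test_that("the folding DP matches exhaustive structure enumeration", {
  set.seed(51)
  seqs <- c("GGGGAAAACCCC", "GCAUCAAAUGGC",
            vapply(1:4, function(i) random_rna_string(11), character(1)))
  for (sq in seqs) {
    expect_equal(self_fold(sq)$mfe, oracle_fold_min(sq), info = sq)
  }
})

test_that("design seed lengths follow the two-thirds floor with a 10 nt minimum", {
  expect_identical(design_seed(25), 16L)
  expect_identical(design_seed(12), 10L)
  expect_identical(design_seed(c(15, 30)), c(10L, 20L))
})
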