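# Synthetic pilot-data simulator: rRNA-like references with positional
# hotspots producing concentrated read pileups across replicate samples.
# Every stage of the pipeline is testable against the recorded truth without
# any external data.

#' Specification for a synthetic pilot fixture
#'
#' @param reference_lengths Integer vector of reference lengths (nt).
#' @param hotspots data.frame with columns `reference` (1-based index into
#'   `reference_lengths`), `start`, `end` (0-based half-open interval) and
#'   `weight` (fraction of reads drawn from the hotspot). Weights must sum
#'   to at most 1; the remainder is uniform background.
#' @param reads_per_sample Reads per pilot sample.
#' @param n_samples Number of replicate samples.
#' @param read_length_range Read length bounds, default c(19, 32) — the
#'   usual Ribo-seq size-selection window.
#' @param mismatch_rate Per-base substitution error rate, default 0.
#' @param gc_bias Probability mass on G/C when drawing reference bases
#'   (default 0.5, i.e. uniform composition).
#' @param seed Integer seed; all outputs are deterministic given it.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(reference_lengths, hotspots = NULL,
                         reads_per_sample = 1000L, n_samples = 3L,
                         read_length_range = c(19L, 32L),
                         mismatch_rate = 0, gc_bias = 0.5, seed = 1L) {
  stopifnot(all(reference_lengths >= 1L), reads_per_sample >= 1L,
            n_samples >= 1L, read_length_range[1] >= 1L,
            read_length_range[1] <= read_length_range[2],
            mismatch_rate >= 0, mismatch_rate <= 1)
  if (read_length_range[1] > max(reference_lengths)) {
    stop("minimum read length exceeds every reference length", call. = FALSE)
  }
  if (is.null(hotspots)) {
    hotspots <- data.frame(reference = integer(), start = integer(),
                           end = integer(), weight = numeric())
  }
  if (nrow(hotspots)) {
    stopifnot(all(hotspots$reference %in% seq_along(reference_lengths)),
              all(hotspots$start >= 0L),
              all(hotspots$end <= reference_lengths[hotspots$reference]),
              all(hotspots$end > hotspots$start))
    if (sum(hotspots$weight) > 1 + 1e-9) {
      stop("hotspot weights sum to more than 1", call. = FALSE)
    }
    if (any(hotspots$end - hotspots$start < read_length_range[1])) {
      stop("infeasible spec: hotspot narrower than the minimum read length",
           call. = FALSE)
    }
  }
  structure(list(reference_lengths = as.integer(reference_lengths),
                 hotspots = hotspots,
                 background_weight = 1 - sum(hotspots$weight),
                 reads_per_sample = as.integer(reads_per_sample),
                 n_samples = as.integer(n_samples),
                 read_length_range = as.integer(read_length_range),
                 mismatch_rate = mismatch_rate, gc_bias = gc_bias,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

# run expr with a private RNG stream, restoring the caller's RNG state
with_fixture_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

random_rna <- function(n, gc_bias = 0.5) {
  p <- c(A = (1 - gc_bias) / 2, C = gc_bias / 2, G = gc_bias / 2,
         U = (1 - gc_bias) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Generate a synthetic pilot fixture
#'
#' Draws uniform-random references, then per sample draws each read's origin:
#' with probability equal to its weight, a hotspot (start uniform inside the
#' hotspot, length uniform within the read-length range, clipped at the
#' reference end), otherwise uniform background on a random reference.
#' Substitution errors are applied at `mismatch_rate`. The truth table
#' records every read's sample, reference, interval, originating component
#' and number of injected errors. Fully deterministic given `spec$seed`; the
#' caller's RNG state is left untouched.
#'
#' @param spec A [fixture_spec()].
#' @param dir When non-`NULL`, also writes `references.fa`, one
#'   `<sample>.fq` per sample and `truth.tsv` into `dir`.
#' @return List with `references` ([rna_references()]), `samples` (named
#'   list of data.frames with `read_id`, `sequence`), `truth` (data.frame)
#'   and `spec`.
#' @export
generate_fixture <- function(spec, dir = NULL) {
  hs <- spec$hotspots
  if (nrow(hs)) {
    short <- (hs$end - hs$start) < 1L
    if (any(short)) stop("hotspot narrower than 1 nt", call. = FALSE)
  }
  with_fixture_seed(spec$seed, {
    refs <- rna_references(
      sprintf("synthRNA%d", seq_along(spec$reference_lengths)),
      vapply(spec$reference_lengths, random_rna, character(1),
             gc_bias = spec$gc_bias)
    )
    comp_w <- c(hs$weight, spec$background_weight)
    samples <- list()
    truth <- list()
    for (s in seq_len(spec$n_samples)) {
      n <- spec$reads_per_sample
      comp <- sample.int(length(comp_w), n, replace = TRUE, prob = comp_w)
      rlen <- sample(spec$read_length_range[1]:spec$read_length_range[2],
                     n, replace = TRUE)
      ref_i <- integer(n); start <- integer(n)
      for (r in seq_len(n)) {
        if (comp[r] <= nrow(hs)) {
          h <- hs[comp[r], ]
          ref_i[r] <- h$reference
          start[r] <- h$start + sample.int(h$end - h$start, 1L) - 1L
        } else {
          ref_i[r] <- sample.int(nrow(refs), 1L,
                                 prob = spec$reference_lengths)
          start[r] <- sample.int(spec$reference_lengths[ref_i[r]], 1L) - 1L
        }
        # clip at the reference end; enforce a minimum of 1 nt
        rlen[r] <- min(rlen[r], spec$reference_lengths[ref_i[r]] - start[r])
      }
      seqs <- substring(refs$sequence[ref_i], start + 1L, start + rlen)
      nerr <- integer(n)
      if (spec$mismatch_rate > 0) {
        for (r in seq_len(n)) {
          ch <- strsplit(seqs[r], "", fixed = TRUE)[[1]]
          mut <- which(stats::runif(length(ch)) < spec$mismatch_rate)
          for (m in mut) ch[m] <- sample(setdiff(.RNA_BASES, ch[m]), 1L)
          nerr[r] <- length(mut)
          seqs[r] <- paste(ch, collapse = "")
        }
      }
      sid <- sprintf("sample%d", s)
      rid <- sprintf("%s_read%05d", sid, seq_len(n))
      samples[[sid]] <- data.frame(read_id = rid, sequence = seqs,
                                   stringsAsFactors = FALSE)
      truth[[s]] <- data.frame(
        sample_id = sid, read_id = rid, reference_id = refs$id[ref_i],
        start = start, end = start + rlen,
        component = ifelse(comp <= nrow(hs),
                           sprintf("hotspot%d", comp), "background"),
        n_errors = nerr, stringsAsFactors = FALSE
      )
    }
    truth <- do.call(rbind, truth)
    out <- list(references = refs, samples = samples, truth = truth,
                spec = spec)
    if (!is.null(dir)) {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      write_rna_fasta(refs$id, refs$sequence, file.path(dir, "references.fa"))
      for (sid in names(samples)) {
        sm <- samples[[sid]]
        qual <- vapply(nchar(sm$sequence), function(k) strrep("I", k), character(1))
        writeLines(as.vector(rbind(paste0("@", sm$read_id), sm$sequence,
                                   "+", qual)),
                   file.path(dir, paste0(sid, ".fq")))
      }
      utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    }
    out
  })
}

#' Build alignments directly from a fixture's truth table
#'
#' Converts the recorded read origins into [pilot_sample()] objects (every
#' read primary at its true interval), bypassing the aligner. Useful for
#' exercising the scoring stages in isolation.
#'
#' @param fixture Output of [generate_fixture()].
#' @return Named list of [pilot_sample()] objects.
#' @export
truth_alignments <- function(fixture) {
  out <- list()
  for (sid in names(fixture$samples)) {
    tr <- fixture$truth[fixture$truth$sample_id == sid, , drop = FALSE]
    out[[sid]] <- pilot_sample(sid, data.frame(
      read_id = tr$read_id, reference_id = tr$reference_id,
      start = tr$start, end = tr$end, is_primary = TRUE,
      mismatches = tr$n_errors, stringsAsFactors = FALSE
    ), fixture$references)
  }
  out
}

#' Plant an antisense island inside a random transcript
#'
#' Builds a random transcript of the given length with the oligo's reverse
#' complement placed at `position` — a known off-target for testing
#' [offtarget_scan()].
#'
#' @param transcript_length Total transcript length (nt).
#' @param oligo Oligo sequence whose reverse complement is planted.
#' @param position 0-based start of the island;
#'   `position + nchar(oligo) <= transcript_length`.
#' @param seed Integer seed for the random background.
#' @return Transcript sequence (character scalar).
#' @export
plant_antisense_island <- function(transcript_length, oligo, position, seed = 1L) {
  l <- nchar(oligo)
  if (position < 0L || position + l > transcript_length) {
    stop("island does not fit inside the transcript", call. = FALSE)
  }
  with_fixture_seed(seed, {
    tx <- strsplit(random_rna(transcript_length), "", fixed = TRUE)[[1]]
    tx[(position + 1L):(position + l)] <- strsplit(rna_revcomp(oligo), "",
                                                  fixed = TRUE)[[1]]
    paste(tx, collapse = "")
  })
}
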