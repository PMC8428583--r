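# Substitution-only alignment of pilot reads to the rRNA references.
#
# The model is deliberately simple: a read is placed wherever it matches a
# reference interval end-to-end with at most `max_mismatches` substitutions
# (no indels, no splicing). rRNA fragments are short contiguous pieces of the
# reference, so this recovers the placements a spliced aligner run with
# novel junctions and indels disabled would report, while staying exactly
# checkable against a brute-force oracle. Seeding is an optimization only:
# results are defined by, and must equal, the exhaustive offset scan.

#' Aligner configuration
#'
#' @param max_mismatches Maximum substitutions allowed in an end-to-end
#'   placement (default 2, the classic `-n 2` setting).
#' @param seed_length Seed k-mer length used to find candidate offsets
#'   (default 25); reads shorter than this are seeded at their own length.
#'   Affects speed only, never results.
#' @param revcomp Also scan the reverse-complement strand (default `FALSE`:
#'   Ribo-seq libraries are stranded, rRNA fragments arrive sense).
#' @return A list of class `aligner_config`.
#' @export
aligner_config <- function(max_mismatches = 2L, seed_length = 25L, revcomp = FALSE) {
  stopifnot(max_mismatches >= 0L, seed_length >= 1L)
  structure(list(max_mismatches = as.integer(max_mismatches),
                 seed_length = as.integer(seed_length),
                 revcomp = isTRUE(revcomp)),
            class = "aligner_config")
}

#' Exhaustive Hamming-distance scan of a read against one reference
#'
#' Reports every offset at which the read matches the reference end-to-end
#' with at most `max_mismatches` substitutions, together with the distance.
#' This is the defining brute-force kernel of the aligner.
#'
#' @param read Read sequence (RNA alphabet; non-empty).
#' @param reference Reference sequence (single string).
#' @param max_mismatches Maximum Hamming distance.
#' @return data.frame with columns `start` (0-based) and `mismatches`,
#'   ordered by start; zero rows when the read is longer than the reference.
#' @export
hamming_scan <- function(read, reference, max_mismatches = 2L) {
  if (!nzchar(read)) stop("empty read", call. = FALSE)
  r <- seq_to_int(normalize_rna(read))
  R <- seq_to_int(normalize_rna(reference))
  n <- length(r); L <- length(R)
  if (n > L) {
    return(data.frame(start = integer(), mismatches = integer()))
  }
  starts <- integer(0); mm <- integer(0)
  for (o in 0:(L - n)) {
    d <- sum(R[(o + 1L):(o + n)] != r)
    if (d <= max_mismatches) {
      starts <- c(starts, o); mm <- c(mm, d)
    }
  }
  data.frame(start = starts, mismatches = mm)
}

# candidate placements via pigeonhole seeding: split the read into
# (max_mismatches + 1) segments; any placement within the mismatch budget
# matches at least one segment exactly. Exact segment matches are located
# with fixed-string search, then every candidate offset is Hamming-verified.
seeded_scan <- function(rint, refstr, refint, max_mismatches) {
  n <- length(rint); L <- length(refint)
  if (n > L) return(data.frame(start = integer(), mismatches = integer()))
  k <- max_mismatches + 1L
  # segment boundaries (at least 1 nt each; fall back to full scan if too short)
  if (n < k) k <- n
  bounds <- floor(seq(0L, n, length.out = k + 1L))
  cand <- integer(0)
  readstr <- int_to_seq(rint)
  for (s in seq_len(k)) {
    a <- bounds[s] + 1L; b <- bounds[s + 1L]
    seg <- substr(readstr, a, b)
    m <- gregexpr(seg, refstr, fixed = TRUE)[[1]]
    if (m[1] != -1L) {
      cand <- c(cand, as.integer(m) - 1L - (a - 1L))   # 0-based read start
    }
  }
  cand <- sort(unique(cand[cand >= 0L & cand <= L - n]))
  starts <- integer(0); mm <- integer(0)
  for (o in cand) {
    d <- sum(refint[(o + 1L):(o + n)] != rint)
    if (d <= max_mismatches) {
      starts <- c(starts, o); mm <- c(mm, d)
    }
  }
  data.frame(start = starts, mismatches = mm)
}

#' Align pilot reads to the rRNA references
#'
#' Places each read end-to-end on the references allowing substitutions only.
#' All equally best placements (minimum mismatch count) are reported as
#' alignments; exactly one is flagged primary, chosen deterministically as
#' fewest mismatches, then lowest reference index, then lowest start
#' coordinate. Suboptimal placements within the mismatch budget are reported
#' as secondary. Unalignable reads are dropped (their count is messaged).
#'
#' @param reads data.frame with columns `read_id`, `sequence`
#'   (e.g. from [read_reads()]).
#' @param references [rna_references()].
#' @param config An [aligner_config()].
#' @param sample_id Sample label for the resulting [pilot_sample()].
#' @return A [pilot_sample()].
#' @export
align_reads <- function(reads, references, config = aligner_config(),
                        sample_id = "sample") {
  stopifnot(is.data.frame(reads), all(c("read_id", "sequence") %in% names(reads)))
  refint <- lapply(references$sequence, seq_to_int)
  out <- vector("list", nrow(reads))
  n_unaligned <- 0L
  for (i in seq_len(nrow(reads))) {
    rseq <- normalize_rna(reads$sequence[i])
    rint <- seq_to_int(rseq)
    hits <- NULL
    for (j in seq_len(nrow(references))) {
      h <- seeded_scan(rint, references$sequence[j], refint[[j]], config$max_mismatches)
      if (config$revcomp) {
        rc <- rev(5L - rint)
        h2 <- seeded_scan(rc, references$sequence[j], refint[[j]], config$max_mismatches)
        if (nrow(h2)) h <- rbind(h, h2)
      }
      if (nrow(h)) {
        h$ref_index <- j
        hits <- rbind(hits, h)
      }
    }
    if (is.null(hits) || !nrow(hits)) {
      n_unaligned <- n_unaligned + 1L
      next
    }
    hits <- unique(hits)
    ord <- order(hits$mismatches, hits$ref_index, hits$start)
    hits <- hits[ord, , drop = FALSE]
    out[[i]] <- data.frame(
      read_id = reads$read_id[i],
      reference_id = references$id[hits$ref_index],
      start = as.integer(hits$start),
      end = as.integer(hits$start + length(rint)),
      is_primary = seq_len(nrow(hits)) == 1L,
      mismatches = hits$mismatches,
      stringsAsFactors = FALSE
    )
  }
  if (n_unaligned) message(sprintf("%d read(s) did not align", n_unaligned))
  aln <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(aln)) {
    aln <- data.frame(read_id = character(), reference_id = character(),
                      start = integer(), end = integer(),
                      is_primary = logical(), mismatches = integer())
  }
  pilot_sample(sample_id, aln, references)
}
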