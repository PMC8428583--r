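# Cross-species optimization: adapt a pre-compiled oligo set designed
# against another organism's rRNAs to the target organism's sequences.
#
# Per source oligo: the lowest-energy complementary hit on the target rRNAs
# is taken as its intended depletion target; the new oligo is the perfect
# reverse complement of that interval, extended by one base for each source
# nucleotide left unpaired at the 5' and 3' ends of the interaction (so the
# optimized oligo reaches equivalent coverage), clamped at reference bounds.
# Antisense geometry maps the oligo's 5' dangling end onto the 3' (higher
# coordinate) side of the target interval and vice versa:
#
#   oligo   3'-xxxPPPPPPPP-5'      P = paired, x = unpaired (3' end here)
#   target 5'-...PPPPPPPP...-3'    the oligo 3' overhang extends the target
#                                  interval toward lower coordinates.

#' Unpaired end lengths of a source oligo in an interaction
#'
#' @param oligo_length Length of the source oligo.
#' @param hit One-row hit from [duplex_search()] (uses `query_start`,
#'   `query_end`, 0-based half-open on the oligo).
#' @return Named integer vector: `five_prime` and `three_prime` unpaired
#'   nucleotide counts.
#' @export
dangling_ends <- function(oligo_length, hit) {
  c(five_prime = as.integer(hit$query_start),
    three_prime = as.integer(oligo_length - hit$query_end))
}

#' Optimize a source oligo set for a new organism's rRNAs
#'
#' @param source_oligos data.frame with columns `id` and `sequence`, or a
#'   named character vector of sequences (e.g. from [read_rna_fasta()] rows).
#' @param references Target-organism [rna_references()].
#' @param wobble Count G.U pairs as complementary during the target search
#'   (default `TRUE`).
#' @return data.frame of class `oligo_optimization`, one row per source
#'   oligo: `source_id`, `status` (`"optimized"`, `"unchanged"` or
#'   `"unoptimizable"`), `reference_id`, `start`, `end` (0-based half-open
#'   target interval after extension; `NA` when unoptimizable), `sequence`
#'   (the optimized oligo; `NA` when unoptimizable), `five_prime_extension`,
#'   `three_prime_extension` (bases actually added at the oligo's 5'/3'
#'   ends), `energy` and `stretch` of the accepted interaction, and
#'   `unchanged` (optimized sequence equals the source).
#' @export
optimize_oligos <- function(source_oligos, references, wobble = TRUE) {
  if (!is.data.frame(source_oligos)) {
    source_oligos <- data.frame(id = names(source_oligos),
                                sequence = unname(source_oligos),
                                stringsAsFactors = FALSE)
  }
  if (identical(names(source_oligos)[1:2], c("id", "sequence")) == FALSE) {
    if (all(c("oligo_id", "sequence") %in% names(source_oligos))) {
      source_oligos <- data.frame(id = source_oligos$oligo_id,
                                  sequence = source_oligos$sequence,
                                  stringsAsFactors = FALSE)
    }
  }
  if (!nrow(source_oligos)) stop("no source oligos", call. = FALSE)
  rows <- vector("list", nrow(source_oligos))
  for (i in seq_len(nrow(source_oligos))) {
    sid <- source_oligos$id[i]
    sseq <- normalize_rna(source_oligos$sequence[i])
    l <- nchar(sseq)
    hits <- duplex_search(sseq, references,
                          duplex_params(design_seed(l), energy_max = 0,
                                        wobble = wobble))
    hits <- hits[hits$stretch >= 10L, , drop = FALSE]
    if (!nrow(hits)) {
      rows[[i]] <- data.frame(
        source_id = sid, status = "unoptimizable", reference_id = NA_character_,
        start = NA_integer_, end = NA_integer_, sequence = NA_character_,
        five_prime_extension = NA_integer_, three_prime_extension = NA_integer_,
        energy = NA_real_, stretch = NA_integer_, unchanged = FALSE,
        stringsAsFactors = FALSE
      )
      next
    }
    ord <- order(hits$energy, -hits$stretch,
                 match(hits$reference_id, references$id), hits$target_start)
    best <- hits[ord[1], ]
    de <- dangling_ends(l, best)
    ref <- ref_lookup(references, best$reference_id)
    # oligo 5' overhang extends the target interval 3'-ward (higher coords),
    # oligo 3' overhang extends it 5'-ward (lower coords); clamp at bounds
    ext5 <- min(de[["five_prime"]], ref$length - best$target_end)
    ext3 <- min(de[["three_prime"]], best$target_start)
    nstart <- best$target_start - ext3
    nend <- best$target_end + ext5
    nseq <- rna_revcomp(substr(ref$sequence, nstart + 1L, nend))
    rows[[i]] <- data.frame(
      source_id = sid,
      status = if (identical(nseq, sseq)) "unchanged" else "optimized",
      reference_id = best$reference_id, start = nstart, end = nend,
      sequence = nseq,
      five_prime_extension = as.integer(ext5),
      three_prime_extension = as.integer(ext3),
      energy = best$energy, stretch = best$stretch,
      unchanged = identical(nseq, sseq),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("oligo_optimization", "data.frame")
  out
}

#' @export
print.oligo_optimization <- function(x, ...) {
  cat(sprintf("Cross-species oligo optimization: %d source oligo(s)\n", nrow(x)))
  tab <- table(x$status)
  for (s in names(tab)) cat(sprintf("  %s: %d\n", s, tab[[s]]))
  NextMethod()
}
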