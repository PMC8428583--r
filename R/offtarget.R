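# Off-target prediction: scan designed oligos against protein-coding
# transcripts for near-complementary binding that would risk depleting
# genuine ribosome-protected fragments.

#' Off-target search parameters derived from an oligo set
#'
#' With `E_min` the most negative perfect-duplex energy across all designed
#' oligos and `l_min` the shortest oligo length, the off-target scan uses
#' seed `l'_min = floor(0.75 * l_min)` and energy cutoff
#' `E'_min = min(-25, 0.5 * E_min)` kcal/mol. Both are computed
#' self-consistently from the bundled energy model.
#'
#' @param oligos data.frame with a `sequence` column (designed oligos), or a
#'   character vector of sequences.
#' @return List of class `offtarget_params`: `E_min`, `l_min`, `seed`
#'   (`l'_min`) and `energy_max` (`E'_min`).
#' @export
compute_offtarget_params <- function(oligos) {
  seqs <- if (is.data.frame(oligos)) oligos$sequence else oligos
  if (!length(seqs)) stop("empty oligo set", call. = FALSE)
  E_min <- min(min_hybridization_energy(seqs))
  l_min <- min(nchar(seqs))
  structure(list(
    E_min = E_min, l_min = l_min,
    seed = as.integer(floor(0.75 * l_min)),
    energy_max = min(-25, 0.5 * E_min)
  ), class = "offtarget_params")
}

#' Scan oligos against transcripts for off-target complementarity
#'
#' Runs [duplex_search()] of every oligo against the transcript set with the
#' derived seed and energy cutoff, returning per-oligo hit counts and the
#' full hit detail. Only the sense strand of the transcripts is scanned by
#' default (only sense-strand fragments become RPFs); each maximal
#' complementary run is counted as one off-target.
#'
#' @param oligos data.frame with `oligo_id` and `sequence` columns.
#' @param transcripts [rna_references()] of protein-coding transcripts.
#' @param params [compute_offtarget_params()] output; derived from `oligos`
#'   when `NULL`.
#' @param wobble Count G.U pairs as complementary (default `TRUE`).
#' @param both_strands Also scan the reverse complement of each transcript
#'   (default `FALSE`).
#' @return List with `counts` (named integer vector, oligo_id -> hit count),
#'   `hits` (data.frame: `oligo_id`, `transcript_id`, `start`, `end`,
#'   `energy`, `stretch`, plus `strand` when `both_strands`) and `params`.
#' @export
offtarget_scan <- function(oligos, transcripts, params = NULL,
                           wobble = TRUE, both_strands = FALSE) {
  if (!nrow(transcripts)) stop("no transcripts provided", call. = FALSE)
  if (is.null(params)) params <- compute_offtarget_params(oligos)
  dp <- duplex_params(params$seed, energy_max = params$energy_max,
                      wobble = wobble)
  scan_set <- transcripts
  if (both_strands) {
    rc <- rna_references(paste0(transcripts$id, "_rc"),
                         rna_revcomp(transcripts$sequence))
    scan_set <- rbind(transcripts, rc)
    class(scan_set) <- class(transcripts)
  }
  all_hits <- list(); n <- 0L
  counts <- stats::setNames(integer(nrow(oligos)), oligos$oligo_id)
  for (i in seq_len(nrow(oligos))) {
    h <- duplex_search(oligos$sequence[i], scan_set, dp)
    counts[i] <- nrow(h)
    if (nrow(h)) {
      n <- n + 1L
      all_hits[[n]] <- data.frame(
        oligo_id = oligos$oligo_id[i],
        transcript_id = sub("_rc$", "", h$reference_id),
        start = h$target_start, end = h$target_end,
        energy = h$energy, stretch = h$stretch,
        strand = if (both_strands) ifelse(grepl("_rc$", h$reference_id), "-", "+") else "+",
        stringsAsFactors = FALSE
      )
    }
  }
  hits <- if (n) do.call(rbind, all_hits) else
    data.frame(oligo_id = character(), transcript_id = character(),
               start = integer(), end = integer(), energy = numeric(),
               stretch = integer(), strand = character(),
               stringsAsFactors = FALSE)
  if (!both_strands) hits$strand <- NULL
  rownames(hits) <- NULL
  list(counts = counts, hits = hits, params = params)
}
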