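# Design mode: enumerate candidate antisense oligos tiling the rRNA
# references, find each oligo's depletion regions, score per-sample
# depleting potentials under the coverage/overhang depletability rules,
# filter, and assemble the feature table.

#' Design-mode configuration
#'
#' @param length_min,length_max Desired oligo length range (nt).
#' @param potential_threshold A sample "supports" an oligo when its depleting
#'   potential exceeds this fraction; oligos below it in too many samples are
#'   discarded. Default 0.05.
#' @param sample_fraction_threshold Discard an oligo when the fraction of
#'   samples with potential below `potential_threshold` strictly exceeds
#'   this. Default 0.75.
#' @param temperature_C Duplex temperature; the bundled energy model is
#'   parameterized at 37 (fixed).
#' @return A list of class `design_config`.
#' @export
design_config <- function(length_min = 25L, length_max = 25L,
                          potential_threshold = 0.05,
                          sample_fraction_threshold = 0.75,
                          temperature_C = 37) {
  if (!(length_min >= 1L && length_min <= length_max)) {
    stop("need 1 <= length_min <= length_max", call. = FALSE)
  }
  if (potential_threshold < 0 || potential_threshold > 1 ||
      sample_fraction_threshold < 0 || sample_fraction_threshold > 1) {
    stop("thresholds must lie in [0, 1]", call. = FALSE)
  }
  if (temperature_C != 37) {
    stop("the bundled energy model is parameterized at 37 degrees C only", call. = FALSE)
  }
  structure(list(length_min = as.integer(length_min),
                 length_max = as.integer(length_max),
                 potential_threshold = potential_threshold,
                 sample_fraction_threshold = sample_fraction_threshold,
                 temperature_C = 37),
            class = "design_config")
}

#' Depletability rule bounds for an oligo of length l
#'
#' A read (rRNA fragment) is depletable by a region when it covers at least
#' `coverage_min(l) = max(10, floor(2l/3))` nt inside the region and has at
#' most `overhang_max(l) = min(10, floor(l/3))` nt outside it.
#'
#' @param l Oligo length(s).
#' @return List with integer vectors `coverage_min` and `overhang_max`.
#' @export
depletion_rule <- function(l) {
  list(coverage_min = pmax(10L, as.integer(floor(2 * l / 3))),
       overhang_max = pmin(10L, as.integer(floor(l / 3))))
}

#' Enumerate all candidate oligos tiling the references
#'
#' For each reference of length L and each oligo length l in the range,
#' generates the max(0, L - l + 1) position-specific designs; each oligo
#' sequence is the exact reverse complement of its reference interval. Ids
#' follow the deterministic scheme `ref|start-end|l` with 1-based inclusive
#' coordinates, so runs are reproducible and diffable.
#'
#' @param references [rna_references()].
#' @param length_min,length_max Oligo length range.
#' @return data.frame with columns `oligo_id`, `reference_id`, `start`,
#'   `end` (0-based half-open), `length`, `sequence`; ordered by reference,
#'   then start, then length.
#' @export
enumerate_oligos <- function(references, length_min, length_max) {
  if (!(length_min >= 1 && length_min <= length_max)) {
    stop("invalid oligo length range", call. = FALSE)
  }
  rows <- list(); n <- 0L
  for (j in seq_len(nrow(references))) {
    L <- references$length[j]
    ls <- (length_min:length_max)[length_min:length_max <= L]
    if (!length(ls)) next
    start <- unlist(lapply(ls, function(l) 0:(L - l)))
    len <- rep(ls, times = L - ls + 1L)
    ord <- order(start, len)
    start <- start[ord]; len <- len[ord]
    seqs <- substring(references$sequence[j], start + 1L, start + len)
    n <- n + 1L
    rows[[n]] <- data.frame(
      oligo_id = sprintf("%s|%d-%d|%d", references$id[j], start + 1L, start + len, len),
      reference_id = references$id[j],
      start = start, end = start + len, length = len,
      sequence = rna_revcomp(seqs),
      stringsAsFactors = FALSE
    )
  }
  out <- if (n) do.call(rbind, rows) else
    data.frame(oligo_id = character(), reference_id = character(),
               start = integer(), end = integer(), length = integer(),
               sequence = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Depletion regions of one oligo
#'
#' Every reference interval complementary to the oligo for a contiguous
#' stretch of at least `max(floor(2l/3), 10)` nucleotides (perfect
#' Watson-Crick complementarity; the literal reading of the region
#' definition, so wobble pairs do not extend a region by default). The
#' oligo's own source interval always qualifies. With multiple rRNA copies
#' in the reference set, regions are found on every copy.
#'
#' @param oligo One-row data.frame from [enumerate_oligos()] (or any list
#'   with `sequence`, and optionally `reference_id`/`start`/`end`).
#' @param references [rna_references()].
#' @param wobble Count G.U pairs as complementary (default `FALSE`).
#' @return data.frame with columns `reference_id`, `start`, `end` (0-based
#'   half-open), `complementary_stretch`, `energy`.
#' @export
depletion_regions_for <- function(oligo, references, wobble = FALSE) {
  l <- nchar(oligo$sequence)
  hits <- duplex_search(oligo$sequence, references,
                        duplex_params(design_seed(l), energy_max = 0,
                                      wobble = wobble))
  data.frame(reference_id = hits$reference_id,
             start = hits$target_start, end = hits$target_end,
             complementary_stretch = hits$stretch, energy = hits$energy,
             stringsAsFactors = FALSE)
}

#' Is a read depletable by a depletion region?
#'
#' Applies the coverage/overhang rule (see [depletion_rule()]) to one or more
#' alignments against one region. Alignments on a different reference are
#' never depletable (returns `FALSE`, not an error).
#'
#' @param alignments data.frame with `reference_id`, `start`, `end`.
#' @param region List or one-row data.frame with `reference_id`, `start`, `end`.
#' @param l Oligo length the rule is parameterized by.
#' @return Logical vector, one entry per alignment row.
#' @export
is_depletable <- function(alignments, region, l) {
  rule <- depletion_rule(l)
  inside <- pmax(0L, pmin(alignments$end, region$end) -
                   pmax(alignments$start, region$start))
  outside <- (alignments$end - alignments$start) - inside
  alignments$reference_id == region$reference_id &
    inside >= rule$coverage_min & outside <= rule$overhang_max
}

#' Depleting potential of an oligo in one pilot sample
#'
#' The fraction of the sample's primary-aligned rRNA fragments that are
#' depletable by at least one of the oligo's depletion regions. A read
#' qualifying in several regions counts once.
#'
#' @param oligo One-row oligo data.frame (supplies the length `l`).
#' @param sample A [pilot_sample()] with `n_primary > 0`.
#' @param regions Regions from [depletion_regions_for()].
#' @return Fraction in [0, 1].
#' @export
depleting_potential <- function(oligo, sample, regions) {
  if (sample$n_primary == 0L) {
    stop(sprintf("pilot sample '%s' has no primary alignments", sample$sample_id),
         call. = FALSE)
  }
  a <- sample$alignments[sample$alignments$is_primary, , drop = FALSE]
  if (!nrow(regions) || !nrow(a)) return(0)
  l <- nchar(oligo$sequence)
  dep <- rep(FALSE, nrow(a))
  for (r in seq_len(nrow(regions))) {
    dep <- dep | is_depletable(a, regions[r, ], l)
  }
  sum(dep) / sample$n_primary
}

#' Filter oligos on their per-sample depleting potentials
#'
#' An oligo is discarded when the fraction of pilot samples in which its
#' potential is strictly below `potential_threshold` strictly exceeds
#' `sample_fraction_threshold` (defaults: below 0.05 in more than 75% of
#' samples).
#'
#' @param potentials Numeric matrix, oligos x samples.
#' @param config A [design_config()] (or any list with the two thresholds).
#' @return Logical vector: `TRUE` for oligos kept.
#' @export
filter_oligos <- function(potentials, config = design_config()) {
  if (is.null(dim(potentials))) potentials <- matrix(potentials, nrow = 1)
  if (ncol(potentials) == 0L) stop("no pilot samples", call. = FALSE)
  frac_below <- rowMeans(potentials < config$potential_threshold)
  frac_below <= config$sample_fraction_threshold
}

#' Overall depletion score
#'
#' The fraction of pilot samples in which the oligo's depleting potential is
#' strictly greater than the threshold.
#'
#' @param potentials Numeric vector (one oligo, one entry per sample) or
#'   matrix (oligos x samples).
#' @param threshold Potential threshold (default 0.05).
#' @return Fraction(s) in [0, 1].
#' @export
overall_depletion_score <- function(potentials, threshold = 0.05) {
  if (is.matrix(potentials)) rowMeans(potentials > threshold)
  else mean(potentials > threshold)
}

#' GC content of a sequence
#'
#' @param sequence Character vector of non-empty sequences.
#' @return Fraction(s) of G and C bases.
#' @export
gc_content <- function(sequence) {
  if (any(!nzchar(sequence))) stop("empty sequence", call. = FALSE)
  sequence <- normalize_rna(sequence)
  vapply(strsplit(sequence, "", fixed = TRUE),
         function(ch) mean(ch %in% c("G", "C")), numeric(1))
}

#' Assemble the feature row(s) for designed oligos
#'
#' Computes, per oligo: target position (1-based inclusive,
#' `"refid:start-end"`), GC content, minimum hybridization energy, predicted
#' self-fold (structure, MFE, base-pairing percentage), overall depletion
#' score and the per-sample potentials; `n_offtargets` is included only when
#' off-target counts are supplied.
#'
#' @param oligos data.frame from [enumerate_oligos()].
#' @param potentials Matrix oligos x samples of depleting potentials
#'   (column names = sample ids).
#' @param config [design_config()].
#' @param offtarget_counts Optional named integer vector (oligo_id ->
#'   off-target count).
#' @param fold_engine Passed to [self_fold()].
#' @return data.frame in the fixed report column order.
#' @export
assemble_features <- function(oligos, potentials, config = design_config(),
                              offtarget_counts = NULL,
                              fold_engine = "internal") {
  if (is.null(dim(potentials))) {
    potentials <- matrix(potentials, nrow = nrow(oligos),
                         dimnames = list(NULL, "sample"))
  }
  folds <- lapply(oligos$sequence, self_fold, engine = fold_engine)
  structure_str <- vapply(folds, `[[`, character(1), "structure")
  stopifnot(nchar(structure_str) == oligos$length)
  out <- data.frame(
    oligo_id = oligos$oligo_id,
    target_rRNA_position = sprintf("%s:%d-%d", oligos$reference_id,
                                   oligos$start + 1L, oligos$end),
    length = oligos$length,
    sequence = oligos$sequence,
    gc_content = gc_content(oligos$sequence),
    minimum_hybridization_energy = min_hybridization_energy(oligos$sequence),
    mfe = vapply(folds, `[[`, numeric(1), "mfe"),
    structure = structure_str,
    base_pairing_percentage = vapply(folds, `[[`, numeric(1), "bp_fraction"),
    overall_depletion_score = overall_depletion_score(potentials,
                                                      config$potential_threshold),
    stringsAsFactors = FALSE
  )
  for (s in colnames(potentials)) {
    out[[paste0("potential.", s)]] <- potentials[, s]
  }
  if (!is.null(offtarget_counts)) {
    out$n_offtargets <- as.integer(offtarget_counts[oligos$oligo_id])
  }
  rownames(out) <- NULL
  out
}
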