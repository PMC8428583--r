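# The central entry point: run the whole design mode on references plus
# pilot samples and return a classed result object.

#' Design rRNA depletion oligos from pilot Ribo-seq data
#'
#' Runs the full design mode: enumerate all candidate antisense oligos in
#' the requested length range across the rRNA references, identify each
#' oligo's depletion regions (contiguous complementary stretches of at least
#' `max(floor(2l/3), 10)` nt), compute per-sample depleting potentials under
#' the coverage/overhang depletability rules, discard oligos with potential
#' below `potential_threshold` in more than `sample_fraction_threshold` of
#' the samples, and assemble the feature table (GC content, hybridization
#' energy, self-fold, overall depletion score) for the survivors. When
#' protein-coding transcripts are supplied, surviving oligos are additionally
#' screened for off-target complementarity.
#'
#' @param references [rna_references()] — the rRNAs (multiple copies allowed).
#' @param samples List of [pilot_sample()] objects (every sample must contain
#'   at least one primary alignment).
#' @param config [design_config()] — oligo length range and filter thresholds.
#' @param transcripts Optional [rna_references()] of protein-coding
#'   transcripts for off-target scanning.
#' @param region_wobble Count G.U pairs as complementary when identifying
#'   depletion regions (default `FALSE`, the strict perfect-complementarity
#'   reading).
#' @param fold_engine Passed to [self_fold()].
#' @return An object of class `oligo_design`: a list with `oligos` (surviving
#'   designs), `features` (their report table), `potentials` (matrix,
#'   survivors x samples), `regions` (per-oligo depletion regions),
#'   `n_enumerated`, `n_kept`, `offtargets` (hit detail or `NULL`),
#'   `samples` (summary), `references` and `config`.
#' @examples
#' refs <- rna_references("rRNA1", paste(rep("ACGGUCCAAGGCU", 6), collapse = ""))
#' spec <- fixture_spec(reference_lengths = 120, reads_per_sample = 80,
#'                      n_samples = 2, seed = 7,
#'                      hotspots = data.frame(reference = 1, start = 40,
#'                                            end = 80, weight = 0.9))
#' fx <- generate_fixture(spec)
#' smp <- lapply(fx$samples, align_reads, references = fx$references)
#' fit <- design_oligos(fx$references, smp, design_config(25, 25))
#' print(fit)
#' @export
design_oligos <- function(references, samples, config = design_config(),
                          transcripts = NULL, region_wobble = FALSE,
                          fold_engine = "internal") {
  if (!length(samples)) stop("no pilot samples provided", call. = FALSE)
  if (is.null(names(samples)) || any(!nzchar(names(samples)))) {
    names(samples) <- vapply(samples, `[[`, character(1), "sample_id")
  }
  for (s in samples) {
    if (s$n_primary == 0L) {
      stop(sprintf("pilot sample '%s' has no primary alignments", s$sample_id),
           call. = FALSE)
    }
  }
  oligos <- enumerate_oligos(references, config$length_min, config$length_max)
  message(sprintf("enumerated %d candidate oligo(s)", nrow(oligos)))
  regions <- lapply(seq_len(nrow(oligos)), function(i) {
    depletion_regions_for(oligos[i, ], references, wobble = region_wobble)
  })
  pots <- matrix(0, nrow(oligos), length(samples),
                 dimnames = list(oligos$oligo_id, names(samples)))
  for (i in seq_len(nrow(oligos))) {
    for (k in seq_along(samples)) {
      pots[i, k] <- depleting_potential(oligos[i, ], samples[[k]], regions[[i]])
    }
  }
  keep <- if (nrow(oligos)) filter_oligos(pots, config) else logical(0)
  message(sprintf("%d oligo(s) survive the potential filter", sum(keep)))
  kept <- oligos[keep, , drop = FALSE]
  kept_pots <- pots[keep, , drop = FALSE]
  kept_regions <- regions[keep]
  names(kept_regions) <- kept$oligo_id
  offt <- NULL
  counts <- NULL
  if (!is.null(transcripts) && nrow(kept)) {
    scan <- offtarget_scan(kept, transcripts)
    offt <- scan$hits
    counts <- scan$counts
  }
  features <- if (nrow(kept)) {
    assemble_features(kept, kept_pots, config, offtarget_counts = counts,
                      fold_engine = fold_engine)
  } else {
    empty <- data.frame(matrix(nrow = 0, ncol = length(.FEATURE_COLUMNS),
                               dimnames = list(NULL, .FEATURE_COLUMNS)))
    empty
  }
  structure(list(
    oligos = kept, features = features, potentials = kept_pots,
    regions = kept_regions, n_enumerated = nrow(oligos), n_kept = nrow(kept),
    offtargets = offt,
    samples = data.frame(sample_id = names(samples),
                         n_primary = vapply(samples, `[[`, integer(1), "n_primary")),
    references = references, config = config
  ), class = "oligo_design")
}

#' @export
print.oligo_design <- function(x, ...) {
  cat("Depletion oligo design\n")
  cat(sprintf("  references: %d (%d nt total)\n", nrow(x$references),
              sum(x$references$length)))
  cat(sprintf("  pilot samples: %d\n", nrow(x$samples)))
  cat(sprintf("  oligo lengths: %d-%d nt\n", x$config$length_min, x$config$length_max))
  cat(sprintf("  candidates enumerated: %d; surviving filter: %d\n",
              x$n_enumerated, x$n_kept))
  if (x$n_kept) {
    top <- x$features[order(-x$features$overall_depletion_score,
                            -rowMeans(x$potentials)), , drop = FALSE][1, ]
    cat(sprintf("  top oligo: %s (overall score %.2f, mean potential %.3f)\n",
                top$oligo_id, top$overall_depletion_score,
                mean(x$potentials[top$oligo_id, ])))
  }
  invisible(x)
}

#' @export
summary.oligo_design <- function(object, top = 5L, ...) {
  print(object)
  if (object$n_kept) {
    mp <- rowMeans(object$potentials)
    ord <- order(-mp)
    show <- object$features[ord[seq_len(min(top, object$n_kept))],
                            c("oligo_id", "target_rRNA_position", "gc_content",
                              "minimum_hybridization_energy",
                              "overall_depletion_score"), drop = FALSE]
    show$mean_potential <- mp[ord[seq_len(nrow(show))]]
    cat("\nTop oligos by mean depleting potential:\n")
    print(show, row.names = FALSE, digits = 3)
    invisible(show)
  } else invisible(NULL)
}

#' @export
as.data.frame.oligo_design <- function(x, ...) x$features

#' Plot the positional abundance profile and surviving oligo targets
#'
#' Draws, for one reference, the per-position primary-read abundance profile
#' of each pilot sample (normalized by the supplied denominators, or by each
#' sample's primary-read total) with the target intervals of the surviving
#' oligos underneath.
#'
#' @param x An `oligo_design`.
#' @param samples The list of [pilot_sample()] objects used in the fit.
#' @param reference Reference id (default: first reference).
#' @param denominators Optional named numeric vector of per-sample
#'   normalization denominators.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the matrix of profiles (positions x samples).
#' @export
plot.oligo_design <- function(x, samples, reference = x$references$id[1],
                              denominators = NULL, ...) {
  ref <- ref_lookup(x$references, reference)
  prof <- sapply(samples, function(s) {
    d <- if (!is.null(denominators)) denominators[[s$sample_id]] else s$n_primary
    positional_profile(s, ref$id, x$references, d)
  })
  graphics::matplot(seq_len(ref$length), prof, type = "l", lty = 1,
                    xlab = sprintf("position on %s (nt)", ref$id),
                    ylab = "normalized read abundance", ...)
  tgt <- x$oligos[x$oligos$reference_id == ref$id, , drop = FALSE]
  if (nrow(tgt)) {
    graphics::segments(tgt$start + 1L, 0, tgt$end, 0, lwd = 3,
                       col = grDevices::adjustcolor("grey30", 0.4))
  }
  invisible(prof)
}
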