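# Non-interactive oligo selection: filter the feature table, then build a
# final pick list while pruning highly similar (interval-overlapping)
# designs. "Highly similar" is interval Jaccard >= similarity_overlap on the
# same reference (default 0.5): overlapping designs deplete the same
# fragments.

# Jaccard similarity of two 0-based half-open intervals on the same axis
interval_jaccard <- function(s1, e1, s2, e2) {
  inter <- pmax(0L, pmin(e1, e2) - pmax(s1, s2))
  uni <- (e1 - s1) + (e2 - s2) - inter
  ifelse(uni > 0, inter / uni, 0)
}

# target interval columns from a feature table (parses target_rRNA_position,
# "ref:start-end" 1-based inclusive) unless start/end columns already exist
feature_intervals <- function(features) {
  if (all(c("reference_id", "start", "end") %in% names(features))) {
    return(features[, c("reference_id", "start", "end")])
  }
  m <- regmatches(features$target_rRNA_position,
                  regexec("^(.+):([0-9]+)-([0-9]+)$", features$target_rRNA_position))
  data.frame(
    reference_id = vapply(m, `[`, character(1), 2),
    start = as.integer(vapply(m, `[`, character(1), 3)) - 1L,
    end = as.integer(vapply(m, `[`, character(1), 4)),
    stringsAsFactors = FALSE
  )
}

#' Filter a feature table with per-column bounds
#'
#' Keeps the rows satisfying every predicate; order is preserved. Predicates
#' are given as named lower/upper bounds on numeric feature columns
#' (closed intervals, so `min =` means `>=` and `max =` means `<=`).
#'
#' @param features Feature data.frame (e.g. `fit$features`).
#' @param min,max Named lists, e.g.
#'   `min = list(overall_depletion_score = 0.5)`,
#'   `max = list(minimum_hybridization_energy = -30)`.
#' @return The filtered subset (possibly empty; an unknown column name is an
#'   error).
#' @export
filter_table <- function(features, min = list(), max = list()) {
  for (nm in c(names(min), names(max))) {
    if (!nm %in% names(features)) {
      stop(sprintf("unknown feature column '%s'", nm), call. = FALSE)
    }
  }
  keep <- rep(TRUE, nrow(features))
  for (nm in names(min)) keep <- keep & features[[nm]] >= min[[nm]]
  for (nm in names(max)) keep <- keep & features[[nm]] <= max[[nm]]
  features[keep, , drop = FALSE]
}

#' Start an interactive-style selection state
#'
#' @param features Feature table of the available oligos.
#' @param similarity_overlap Jaccard threshold at or above which two designs
#'   on the same reference count as highly similar (default 0.5).
#' @return List of class `oligo_selection` with `available` (feature rows
#'   still pickable), `selected` (picked rows, in pick order) and the
#'   threshold.
#' @export
selection_start <- function(features, similarity_overlap = 0.5) {
  structure(list(available = features,
                 selected = features[0, , drop = FALSE],
                 similarity_overlap = similarity_overlap),
            class = "oligo_selection")
}

#' Pick one oligo into the selection
#'
#' Moves the oligo to the selection list and removes from the available list
#' every oligo on the same reference whose target interval overlaps the
#' picked one with Jaccard similarity at or above the state's threshold
#' (including the picked oligo itself).
#'
#' @param state An [selection_start()] state.
#' @param oligo_id Id of an oligo still in the available list (picking a
#'   removed or unknown id is an error).
#' @return The updated state.
#' @export
pick <- function(state, oligo_id) {
  i <- match(oligo_id, state$available$oligo_id)
  if (is.na(i)) {
    stop(sprintf("oligo '%s' is not in the available list (already picked or removed?)",
                 oligo_id), call. = FALSE)
  }
  row <- state$available[i, , drop = FALSE]
  iv <- feature_intervals(state$available)
  piv <- iv[i, ]
  jac <- interval_jaccard(piv$start, piv$end, iv$start, iv$end)
  drop <- iv$reference_id == piv$reference_id & jac >= state$similarity_overlap
  state$selected <- rbind(state$selected, row)
  state$available <- state$available[!drop, , drop = FALSE]
  state
}

#' Greedy automatic selection of k non-redundant oligos
#'
#' Repeatedly picks the available oligo with the highest overall depletion
#' score (ties: most negative minimum hybridization energy, then lowest
#' reference index and target start), applying the similarity pruning of
#' [pick()] after each choice, until `k` oligos are selected or none remain.
#'
#' @param features Feature table.
#' @param k Number of oligos wanted (>= 1).
#' @param similarity_overlap Jaccard threshold (default 0.5).
#' @return Character vector of selected oligo ids (possibly fewer than `k`).
#' @export
greedy_autoselect <- function(features, k, similarity_overlap = 0.5) {
  stopifnot(k >= 1L)
  state <- selection_start(features, similarity_overlap)
  picked <- character(0)
  while (length(picked) < k && nrow(state$available)) {
    av <- state$available
    iv <- feature_intervals(av)
    ord <- order(-av$overall_depletion_score,
                 av$minimum_hybridization_energy,
                 match(iv$reference_id, unique(iv$reference_id)),
                 iv$start)
    best <- av$oligo_id[ord[1]]
    state <- pick(state, best)
    picked <- c(picked, best)
  }
  picked
}

#' @export
print.oligo_selection <- function(x, ...) {
  cat(sprintf("oligo selection: %d selected, %d still available (similarity >= %.2f pruned)\n",
              nrow(x$selected), nrow(x$available), x$similarity_overlap))
  if (nrow(x$selected)) print(x$selected$oligo_id)
  invisible(x)
}

#' Write a selection as FASTA and CSV
#'
#' Selected oligos are ordered by reference and target position in the
#' FASTA; the CSV carries their full feature rows.
#'
#' @param state An `oligo_selection` (or a feature-table subset).
#' @param out_dir Output directory.
#' @param prefix File prefix (default `"selected"`).
#' @return Invisibly, the paths written.
#' @export
write_selection <- function(state, out_dir, prefix = "selected") {
  sel <- if (inherits(state, "oligo_selection")) state$selected else state
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  iv <- feature_intervals(sel)
  ord <- order(match(iv$reference_id, unique(iv$reference_id)), iv$start)
  sel <- sel[ord, , drop = FALSE]
  paths <- c(fasta = file.path(out_dir, paste0(prefix, ".fa")),
             csv = file.path(out_dir, paste0(prefix, ".csv")))
  write_rna_fasta(sel$oligo_id, sel$sequence, paths["fasta"])
  utils::write.csv(sel, paths["csv"], row.names = FALSE, quote = FALSE, na = "")
  invisible(paths)
}
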