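# Antisense complementarity search: the seed-and-report engine behind
# depletion-region identification, cross-species optimization and off-target
# scanning.
#
# A "hit" is a maximal contiguous run of base pairs between the oligo and a
# reference in antiparallel (antisense) orientation, of length at least the
# seed `s`, scored with the nearest-neighbor duplex model over the run. With
# the default energy threshold e = 0 every seed hit is reported (run energies
# are negative in practice); no extension beyond the perfectly paired run is
# attempted (the w = 0 semantics: run = maximal complementary stretch).

#' Duplex search parameters
#'
#' @param seed Minimum contiguous complementary stretch `s` (>= 1).
#' @param energy_max Report hits with energy <= this value (kcal/mol);
#'   0 (default) reports all seed hits.
#' @param wobble Count G.U pairs as complementary inside a run
#'   (default `TRUE` for search; depletion-region identification uses
#'   `FALSE`, the literal perfect-complementarity reading).
#' @return A list of class `duplex_params`.
#' @export
duplex_params <- function(seed, energy_max = 0, wobble = TRUE) {
  stopifnot(seed >= 1L)
  structure(list(seed = as.integer(seed), energy_max = energy_max,
                 wobble = isTRUE(wobble)),
            class = "duplex_params")
}

#' Design-mode seed length for an oligo of length l
#'
#' The minimum complementary stretch required of a depletion region:
#' `max(floor(2 * l / 3), 10)` nucleotides.
#'
#' @param l Oligo length(s).
#' @return Integer seed length(s).
#' @export
design_seed <- function(l) {
  pmax(as.integer(floor(2 * l / 3)), 10L)
}

# per-reference maximal-run search on the diagonal lattice.
# rcint: integer codes of revcomp(oligo); refint: integer codes of reference.
# Complementarity of oligo base with reference base is equality of the
# revcomp'd oligo base with the reference base; the wobble pairs (oligo G :
# target U) and (oligo U : target G) appear in revcomp space as (C,U) and
# (A,G).
run_search_one <- function(rcint, refint, seed, wobble, refstr = NULL) {
  l <- length(rcint); L <- length(refint)
  res <- list(); nres <- 0L
  if (L < seed) return(res)
  diagonals <- (-(l - seed)):(L - seed)
  if (!wobble && !is.null(refstr)) {
    # without wobble a run is an exact substring match, so every run of
    # length >= seed contains a complete block from a partition of the
    # query into blocks of floor(seed/2); exact block matches give the
    # only diagonals worth scanning
    b <- max(1L, seed %/% 2L)
    starts <- seq(1L, l - b + 1L, by = b)
    cand <- integer(0)
    qstr <- int_to_seq(rcint)
    for (a in starts) {
      m <- gregexpr(substr(qstr, a, a + b - 1L), refstr, fixed = TRUE)[[1]]
      if (m[1] != -1L) cand <- c(cand, as.integer(m) - a)
    }
    diagonals <- intersect(sort(unique(cand)), diagonals)
    if (!length(diagonals)) return(res)
  }
  for (d in diagonals) {
    i0 <- max(1L, 1L - d); i1 <- min(l, L - d)
    if (i1 - i0 + 1L < seed) next
    idx <- i0:i1
    refslice <- refint[d + idx]
    m <- rcint[idx] == refslice
    if (wobble) {
      m <- m | (rcint[idx] == 2L & refslice == 4L) |   # oligo G : target U
        (rcint[idx] == 1L & refslice == 3L)            # oligo U : target G
    }
    r <- rle(m)
    if (!any(r$values & r$lengths >= seed)) next
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= seed)) {
      k1 <- idx[starts[k]]; k2 <- idx[ends[k]]       # rc-space 1-based inclusive
      nres <- nres + 1L
      res[[nres]] <- c(tstart = d + k1 - 1L, tend = d + k2,   # 0-based half-open
                       q1 = k1, q2 = k2)
    }
  }
  res
}

#' Search references for antisense complementary stretches of an oligo
#'
#' Finds every maximal contiguous complementary run of length at least
#' `params$seed` between the oligo (antisense orientation) and each
#' reference, scores each run with [duplex_energy()], and reports runs with
#' energy at or below `params$energy_max`.
#'
#' @param oligo_sequence Oligo sequence, 5'->3'.
#' @param references [rna_references()] (rRNAs or transcripts).
#' @param params [duplex_params()].
#' @return data.frame with one row per hit: `reference_id`, `target_start`,
#'   `target_end` (0-based half-open on the reference), `query_start`,
#'   `query_end` (0-based half-open on the oligo), `energy` (kcal/mol) and
#'   `stretch` (run length, nt), ordered by reference then target start.
#' @export
duplex_search <- function(oligo_sequence, references, params) {
  oligo_sequence <- normalize_rna(oligo_sequence)
  l <- nchar(oligo_sequence)
  rcint <- seq_to_int(rna_revcomp(oligo_sequence))
  rows <- list(); n <- 0L
  for (j in seq_len(nrow(references))) {
    refint <- seq_to_int(references$sequence[j])
    runs <- run_search_one(rcint, refint, params$seed, params$wobble,
                           refstr = references$sequence[j])
    for (run in runs) {
      qs <- l - run[["q2"]]; qe <- l - run[["q1"]] + 1L   # 0-based half-open on oligo
      osub <- substr(oligo_sequence, qs + 1L, qe)
      tsub <- substr(references$sequence[j], run[["tstart"]] + 1L, run[["tend"]])
      e <- duplex_energy(osub, tsub, wobble = params$wobble)
      if (e <= params$energy_max) {
        n <- n + 1L
        rows[[n]] <- data.frame(
          reference_id = references$id[j],
          target_start = unname(run[["tstart"]]), target_end = unname(run[["tend"]]),
          query_start = qs, query_end = qe,
          energy = e, stretch = unname(run[["q2"]] - run[["q1"]] + 1L),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!n) {
    return(data.frame(reference_id = character(), target_start = integer(),
                      target_end = integer(), query_start = integer(),
                      query_end = integer(), energy = numeric(),
                      stretch = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(match(out$reference_id, references$id), out$target_start), , drop = FALSE]
}
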