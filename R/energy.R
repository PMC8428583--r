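# Nearest-neighbor RNA/RNA duplex thermodynamics at 37 degrees C.
#
# Stack free energies (kcal/mol, Delta-G at 37C) are the published Turner-lab
# nearest-neighbor parameters: Watson-Crick stacks from Xia et al. (1998,
# Biochemistry 37:14719), G.U wobble stacks from Mathews et al. (1999, JMB
# 288:911) as revised in the Turner 2004 parameter set. Duplex initiation
# (+4.09) and the terminal AU/GU end penalty (+0.45) are from Xia et al.
# (1998). The table is shipped as data: no external thermodynamics engine is
# required, and every energy-derived threshold in the pipeline (E_min, the
# off-target cutoff) is computed self-consistently from this model.
#
# Indexing: a base pair is written as a two-letter string, query base first
# ("AU" = A in the query strand paired with U in the target). The stack
# energy of two consecutive pairs p1, p2 along the query 5'->3' direction is
# .STACK_DG[p1, p2].

.PAIR_NAMES <- c("CG", "GC", "GU", "UG", "AU", "UA")

.STACK_DG <- matrix(c(
  # p2:   CG     GC     GU     UG     AU     UA        p1:
        -3.3,  -2.4,  -1.4,  -2.1,  -2.1,  -2.1,    # CG
        -3.4,  -3.3,  -1.5,  -2.5,  -2.4,  -2.2,    # GC
        -2.5,  -2.1,  -0.5,   1.3,  -1.3,  -1.4,    # GU
        -1.5,  -1.4,   0.3,  -0.5,  -1.0,  -0.6,    # UG
        -2.2,  -2.1,  -0.6,  -1.4,  -0.9,  -1.1,    # AU
        -2.4,  -2.1,  -1.0,  -1.3,  -1.3,  -0.9     # UA
), nrow = 6, byrow = TRUE, dimnames = list(.PAIR_NAMES, .PAIR_NAMES))

.DUPLEX_INIT <- 4.09
.AU_END_PENALTY <- 0.45

#' The bundled RNA/RNA nearest-neighbor energy model
#'
#' Returns the stack free-energy table (kcal/mol at 37 degrees C), the duplex
#' initiation term and the terminal AU/GU end penalty used by all energy
#' computations. Watson-Crick stacks follow Xia et al. (1998); G.U wobble
#' stacks follow Mathews et al. (1999)/Turner 2004.
#'
#' @return List with elements `stack_table` (6x6 named matrix over pairs
#'   CG, GC, GU, UG, AU, UA), `init_term` and `au_end_penalty`.
#' @export
energy_model <- function() {
  list(stack_table = .STACK_DG, init_term = .DUPLEX_INIT,
       au_end_penalty = .AU_END_PENALTY)
}

# pair label for query base q and target base t; NA if not a valid pair
pair_label <- function(q, t, wobble = TRUE) {
  p <- paste0(q, t)
  ok <- p %in% c("AU", "UA", "CG", "GC", if (wobble) c("GU", "UG"))
  ifelse(ok, p, NA_character_)
}

#' Free energy of an antiparallel RNA/RNA duplex
#'
#' Scores the duplex formed by `seq_a` (5'->3') and `seq_b` (5'->3') in
#' antiparallel orientation: position i of `seq_a` pairs with position
#' n + 1 - i of `seq_b`. Every position must form a Watson-Crick pair (or a
#' G.U wobble when `wobble = TRUE`). The energy is the duplex initiation term
#' plus the sum of nearest-neighbor stack terms plus a +0.45 kcal/mol penalty
#' for each helix end closed by an AU or GU pair; more negative is more
#' stable.
#'
#' @param seq_a Query sequence (RNA alphabet).
#' @param seq_b Partner sequence; defaults to the reverse complement of
#'   `seq_a` (the perfect duplex).
#' @param wobble Accept G.U pairs (default `TRUE`).
#' @return Free energy in kcal/mol.
#' @export
duplex_energy <- function(seq_a, seq_b = rna_revcomp(seq_a), wobble = TRUE) {
  a <- strsplit(normalize_rna(seq_a), "", fixed = TRUE)[[1]]
  b <- strsplit(normalize_rna(seq_b), "", fixed = TRUE)[[1]]
  n <- length(a)
  if (n < 1L) stop("duplex of length 0", call. = FALSE)
  if (length(b) != n) stop("duplex strands must have equal length", call. = FALSE)
  pairs <- pair_label(a, rev(b), wobble = wobble)
  if (anyNA(pairs)) {
    stop(sprintf("position %d does not form a valid base pair",
                 which(is.na(pairs))[1]), call. = FALSE)
  }
  e <- .DUPLEX_INIT
  if (n > 1L) {
    e <- e + sum(.STACK_DG[cbind(pairs[-n], pairs[-1L])])
    # helix-end penalty per terminus closed by AU or GU (degenerate 1-bp
    # duplex has no stacked helix and scores initiation only)
    for (endp in pairs[c(1L, n)]) {
      if (endp %in% c("AU", "UA", "GU", "UG")) e <- e + .AU_END_PENALTY
    }
  }
  e
}

#' Minimum hybridization energy of an oligo
#'
#' The free energy of the oligo bound in full, perfectly complementary
#' antisense duplex with its target rRNA interval at 37 degrees C — the most
#' stable binding the oligo can achieve.
#'
#' @param sequence Oligo sequence(s), character vector.
#' @return Numeric vector of free energies (kcal/mol).
#' @export
min_hybridization_energy <- function(sequence) {
  vapply(sequence, function(s) duplex_energy(s, rna_revcomp(s), wobble = FALSE),
         numeric(1), USE.NAMES = FALSE)
}
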