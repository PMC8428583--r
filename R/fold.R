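# Oligo self-folding: a nested-secondary-structure dynamic program that
# minimizes stack-based free energy (same nearest-neighbor table as the
# duplex model, G.U wobble allowed, minimum hairpin loop of 3 unpaired
# bases). Isolated pairs carry no stacking energy, so the program never gains
# by adding them; the open chain (energy 0) is always feasible, hence
# MFE <= 0. An installed RNAfold binary can be swapped in behind the same
# contract for full Turner-model loop energies.

#' Predict the self-folding of an oligo
#'
#' Returns the minimum-free-energy nested secondary structure of a single
#' RNA strand under the bundled stack-energy model (see [energy_model()]):
#' the energy of a structure is the sum of nearest-neighbor stack terms over
#' directly nested adjacent pairs, hairpin loops must contain at least 3
#' unpaired bases, and pseudoknots are not considered.
#'
#' @param sequence Oligo sequence (RNA alphabet, length >= 1).
#' @param engine `"internal"` (default) for the bundled dynamic program, or
#'   `"rnafold"` to delegate to an installed RNAfold executable (full Turner
#'   loop model; used only when found on the PATH).
#' @return List with `structure` (dot-bracket string, same length as the
#'   sequence), `mfe` (kcal/mol, <= 0) and `bp_fraction`
#'   (2 * pairs / length, in [0, 1]).
#' @export
self_fold <- function(sequence, engine = c("internal", "rnafold")) {
  engine <- match.arg(engine)
  sequence <- normalize_rna(sequence)
  n <- nchar(sequence)
  if (n < 1L) stop("empty sequence", call. = FALSE)
  if (engine == "rnafold" && nzchar(Sys.which("RNAfold"))) {
    return(self_fold_rnafold(sequence))
  }
  if (n < 5L) {
    return(list(structure = strrep(".", n), mfe = 0, bp_fraction = 0))
  }
  b <- strsplit(sequence, "", fixed = TRUE)[[1]]
  P <- outer(b, b, function(x, y) pair_label(x, y, wobble = TRUE))
  Fm <- matrix(0, n, n)          # F[i,j]: min energy of segment i..j
  Cm <- matrix(Inf, n, n)        # C[i,j]: min energy given (i,j) paired
  for (span in 4:(n - 1)) {
    for (i in 1:(n - span)) {
      j <- i + span
      if (!is.na(P[i, j])) {
        inner <- if (j - 1 >= i + 1) Fm[i + 1, j - 1] else 0
        cij <- inner
        if (!is.na(P[i + 1, j - 1]) && is.finite(Cm[i + 1, j - 1])) {
          cij <- min(cij, .STACK_DG[P[i, j], P[i + 1, j - 1]] + Cm[i + 1, j - 1])
        }
        Cm[i, j] <- cij
      }
      best <- Fm[i, j - 1]                      # j unpaired
      for (k in i:(j - 4)) {
        if (is.finite(Cm[k, j])) {
          cand <- (if (k > i) Fm[i, k - 1] else 0) + Cm[k, j]
          if (cand < best) best <- cand
        }
      }
      Fm[i, j] <- best
    }
  }
  # traceback, preferring unpaired on ties (no zero-energy lone pairs)
  struct <- rep(".", n)
  stack <- list(c(1L, n, 0L))                   # (i, j, inC)
  while (length(stack)) {
    fr <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- fr[1]; j <- fr[2]
    if (j <= i) next
    if (fr[3] == 1L) {                          # inside C[i,j]: (i,j) is paired
      struct[i] <- "("; struct[j] <- ")"
      if (!is.na(P[i + 1, j - 1]) && is.finite(Cm[i + 1, j - 1]) &&
          isTRUE(all.equal(Cm[i, j],
                           .STACK_DG[P[i, j], P[i + 1, j - 1]] + Cm[i + 1, j - 1]))) {
        stack[[length(stack) + 1L]] <- c(i + 1L, j - 1L, 1L)
      } else if (j - 1 >= i + 1) {
        stack[[length(stack) + 1L]] <- c(i + 1L, j - 1L, 0L)
      }
      next
    }
    if (j - i < 4L) next
    if (isTRUE(all.equal(Fm[i, j], Fm[i, j - 1]))) {
      stack[[length(stack) + 1L]] <- c(i, j - 1L, 0L)
      next
    }
    for (k in i:(j - 4)) {
      if (is.finite(Cm[k, j])) {
        cand <- (if (k > i) Fm[i, k - 1] else 0) + Cm[k, j]
        if (isTRUE(all.equal(Fm[i, j], cand))) {
          if (k > i) stack[[length(stack) + 1L]] <- c(i, k - 1L, 0L)
          stack[[length(stack) + 1L]] <- c(k, j, 1L)
          break
        }
      }
    }
  }
  structure_str <- paste(struct, collapse = "")
  npairs <- sum(struct == "(")
  list(structure = structure_str, mfe = Fm[1, n], bp_fraction = 2 * npairs / n)
}

# delegate to an installed RNAfold executable (--noPS, 37C default)
self_fold_rnafold <- function(sequence) {
  out <- system2("RNAfold", c("--noPS"), input = sequence, stdout = TRUE)
  ln <- out[2]
  structure_str <- sub("^([.()]+).*$", "\\1", ln)
  mfe <- as.numeric(sub("^.*\\(\\s*(-?[0-9.]+)\\)\\s*$", "\\1", ln))
  npairs <- sum(strsplit(structure_str, "")[[1]] == "(")
  list(structure = structure_str, mfe = min(mfe, 0),
       bp_fraction = 2 * npairs / nchar(sequence))
}
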