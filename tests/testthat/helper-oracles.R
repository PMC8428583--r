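# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (nested loops, direct rule transcription) so they define
# the semantics the optimized implementations must match.

BASES <- c("A", "C", "G", "U")

random_rna_string <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

make_refs <- function(lengths, ids = sprintf("ref%d", seq_along(lengths))) {
  rna_references(ids, vapply(lengths, random_rna_string, character(1)))
}

# does query base q pair target base t (antiparallel duplex)?
oracle_pair_ok <- function(q, t, wobble) {
  wc <- (q == "A" && t == "U") || (q == "U" && t == "A") ||
    (q == "C" && t == "G") || (q == "G" && t == "C")
  wb <- (q == "G" && t == "U") || (q == "U" && t == "G")
  wc || (wobble && wb)
}

# exhaustive-offset Hamming alignment of one read against one reference
oracle_hamming <- function(read, ref, k) {
  r <- strsplit(read, "")[[1]]; R <- strsplit(ref, "")[[1]]
  n <- length(r); L <- length(R)
  out <- NULL
  if (n > L) return(data.frame(start = integer(), mismatches = integer()))
  for (o in 0:(L - n)) {
    d <- 0L
    for (i in seq_len(n)) if (R[o + i] != r[i]) d <- d + 1L
    if (d <= k) out <- rbind(out, data.frame(start = o, mismatches = d))
  }
  if (is.null(out)) data.frame(start = integer(), mismatches = integer()) else out
}

# all maximal antisense complementary runs of length >= s between an oligo
# and one reference, by pairwise extension over every (oligo, target)
# position pair. Returns target intervals (0-based half-open) with stretch.
oracle_runs <- function(oligo, ref, s, wobble) {
  q <- strsplit(oligo, "")[[1]]; t <- strsplit(ref, "")[[1]]
  l <- length(q); L <- length(t)
  out <- NULL
  for (i in seq_len(l)) {
    for (j in seq_len(L)) {
      # run starting at oligo i paired with target j, extending i+1 <-> j-1
      if (!oracle_pair_ok(q[i], t[j], wobble)) next
      prev_ok <- i > 1 && j < L && oracle_pair_ok(q[i - 1], t[j + 1], wobble)
      if (prev_ok) next                      # not a run start (not maximal)
      len <- 1L
      while (i + len <= l && j - len >= 1 &&
             oracle_pair_ok(q[i + len], t[j - len], wobble)) len <- len + 1L
      if (len >= s) {
        out <- rbind(out, data.frame(target_start = j - len, target_end = j,
                                     stretch = len))
      }
    }
  }
  if (is.null(out)) {
    data.frame(target_start = integer(), target_end = integer(), stretch = integer())
  } else out[order(out$target_start), , drop = FALSE]
}

# direct transcription of the depletability rule for one read and one region
oracle_depletable <- function(a_start, a_end, a_ref, r_start, r_end, r_ref, l) {
  if (a_ref != r_ref) return(FALSE)
  coverage_min <- max(10, floor(2 * l / 3))
  overhang_max <- min(10, floor(l / 3))
  inside <- max(0, min(a_end, r_end) - max(a_start, r_start))
  outside <- (a_end - a_start) - inside
  inside >= coverage_min && outside <= overhang_max
}

# per-read brute-force depleting potential of an oligo in one sample
oracle_potential <- function(oligo_length, regions, sample) {
  a <- sample$alignments[sample$alignments$is_primary, , drop = FALSE]
  ndep <- 0L
  for (r in seq_len(nrow(a))) {
    dep <- FALSE
    for (g in seq_len(nrow(regions))) {
      if (oracle_depletable(a$start[r], a$end[r], a$reference_id[r],
                            regions$start[g], regions$end[g],
                            regions$reference_id[g], oligo_length)) {
        dep <- TRUE
        break
      }
    }
    if (dep) ndep <- ndep + 1L
  }
  ndep / sample$n_primary
}

# exhaustive folding oracle: enumerate every nested structure (pair lists
# with minimum hairpin loop of 3) of a short sequence and return the minimum
# stack-sum energy. Exponential; use only for lengths <= ~12.
oracle_fold_min <- function(sequence) {
  b <- strsplit(sequence, "")[[1]]
  n <- length(b)
  stacks <- energy_model()$stack_table
  all_structs <- function(i, j) {
    if (i >= j) return(list(data.frame(i = integer(), j = integer())))
    out <- all_structs(i + 1, j)                         # i unpaired
    if (i + 4 <= j) {
      for (k in (i + 4):j) {
        if (oracle_pair_ok(b[i], b[k], wobble = TRUE)) {
          inner <- all_structs(i + 1, k - 1)
          outer <- all_structs(k + 1, j)
          for (ins in inner) for (outs in outer) {
            out <- c(out, list(rbind(data.frame(i = i, j = k), ins, outs)))
          }
        }
      }
    }
    out
  }
  structure_energy <- function(pairs) {
    e <- 0
    for (r in seq_len(nrow(pairs))) {
      if (any(pairs$i == pairs$i[r] + 1 & pairs$j == pairs$j[r] - 1)) {
        e <- e + stacks[paste0(b[pairs$i[r]], b[pairs$j[r]]),
                        paste0(b[pairs$i[r] + 1], b[pairs$j[r] - 1])]
      }
    }
    e
  }
  min(vapply(all_structs(1, n), structure_energy, numeric(1)))
}

# write lines to a temp file and return the path
tmpfile_with <- function(lines, ext = ".txt") {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}

# a minimal valid SAM for the given references and alignment rows
sam_text <- function(references, rows) {
  c("@HD\tVN:1.6",
    sprintf("@SQ\tSN:%s\tLN:%d", references$id, references$length),
    rows)
}
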