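# Internal sequence machinery. Everything downstream works on RNA alphabet
# {A,C,G,U}; T is normalized to U at every input boundary.

.RNA_BASES <- c("A", "C", "G", "U")
.RNA_COMPLEMENT <- c(A = "U", C = "G", G = "C", U = "A")

#' Reverse complement of an RNA sequence
#'
#' Complements over the RNA alphabet (A-U, C-G) and reverses. Input containing
#' T (DNA spelling) or lowercase letters is normalized first.
#'
#' @param x Character vector of sequences over \{A,C,G,U,T\} (case-insensitive).
#' @return Character vector of reverse complements, same length as `x`.
#' @examples
#' rna_revcomp("ACGU")   # "ACGU"
#' rna_revcomp("GGAU")   # "AUCC"
#' @export
rna_revcomp <- function(x) {
  x <- normalize_rna(x)
  vapply(strsplit(x, "", fixed = TRUE), function(ch) {
    paste(rev(unname(.RNA_COMPLEMENT[ch])), collapse = "")
  }, character(1))
}

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases and replaces T with U. Does not validate; see
#' [rna_references()] for validating construction.
#'
#' @param x Character vector.
#' @return Character vector over the RNA alphabet spelling.
#' @export
normalize_rna <- function(x) {
  chartr("acgtuT", "ACGUUU", x)
}

# integer encoding A=1 C=2 G=3 U=4; NA for anything else
seq_to_int <- function(x) {
  match(strsplit(x, "", fixed = TRUE)[[1]], .RNA_BASES)
}

int_to_seq <- function(v) {
  paste(.RNA_BASES[v], collapse = "")
}

# validate a single sequence; returns invisible TRUE or stops naming `id`
check_rna_alphabet <- function(seq, id) {
  bad <- regmatches(seq, regexpr("[^ACGU]", seq))
  if (length(bad) && nzchar(bad)) {
    stop(sprintf(
      "record '%s' contains character '%s' outside the A/C/G/U alphabet %s",
      id, bad,
      if (bad %in% c("N", "n")) "(ambiguous bases are rejected: oligo design over N is undefined)"
      else ""
    ), call. = FALSE)
  }
  if (!nzchar(seq)) stop(sprintf("record '%s' has an empty sequence", id), call. = FALSE)
  invisible(TRUE)
}

#' Construct a validated RNA reference set
#'
#' The container used for rRNA references, protein-coding transcripts and any
#' other depletion-intended RNA. Sequences are normalized (T to U, uppercased)
#' and validated: ids must be unique and whitespace-free, sequences non-empty
#' and strictly over \{A,C,G,U\}. Ambiguity codes (including N) are rejected.
#'
#' @param ids Character vector of unique record identifiers.
#' @param sequences Character vector of nucleotide sequences, same length.
#' @return A data.frame of class `rna_references` with columns `id`,
#'   `sequence`, `length`, rows in input order.
#' @seealso [read_rna_fasta()]
#' @export
rna_references <- function(ids, sequences) {
  stopifnot(length(ids) == length(sequences))
  if (length(ids) == 0L) stop("reference set is empty", call. = FALSE)
  ids <- as.character(ids)
  if (anyNA(ids) || any(!nzchar(ids))) stop("reference ids must be non-empty", call. = FALSE)
  if (any(grepl("[[:space:]]", ids))) stop("reference ids must not contain whitespace", call. = FALSE)
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate reference id '%s'", ids[duplicated(ids)][1]), call. = FALSE)
  }
  sequences <- normalize_rna(as.character(sequences))
  for (i in seq_along(ids)) check_rna_alphabet(sequences[i], ids[i])
  out <- data.frame(
    id = ids, sequence = sequences, length = nchar(sequences),
    stringsAsFactors = FALSE
  )
  class(out) <- c("rna_references", "data.frame")
  out
}

# fetch one reference row (by id) or stop
ref_lookup <- function(references, id) {
  i <- match(id, references$id)
  if (is.na(i)) stop(sprintf("unknown reference id '%s'", id), call. = FALSE)
  references[i, , drop = FALSE]
}

#' @export
print.rna_references <- function(x, ...) {
  cat(sprintf("RNA reference set: %d sequence(s), %d nt total\n",
              nrow(x), sum(x$length)))
  for (i in seq_len(min(nrow(x), 10L))) {
    cat(sprintf("  %s  (%d nt)\n", x$id[i], x$length[i]))
  }
  if (nrow(x) > 10L) cat(sprintf("  ... and %d more\n", nrow(x) - 10L))
  invisible(x)
}
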