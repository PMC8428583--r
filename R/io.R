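# Readers and writers for every external format the pipeline touches:
# FASTA/FASTQ in, SAM in/out, FASTA/CSV/BED6/GFF3/TSV out.
#
# Internal coordinates are 0-based half-open everywhere; conversion happens
# only here, at the format boundary (BED stays 0-based half-open, GFF3 and the
# CSV report are 1-based inclusive).

#' Read RNA reference sequences from FASTA
#'
#' Reads a (multi-)FASTA of rRNA references or transcripts. Record ids are the
#' first whitespace-delimited word of each header. T is normalized to U and
#' case folded to upper; records containing any other character (including N)
#' are rejected with an error naming the record.
#'
#' @param path Path to a FASTA file.
#' @return An [rna_references()] data.frame, records in file order.
#' @export
read_rna_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop(sprintf("FASTA file '%s' contains no records", path), call. = FALSE)
  ids <- sub("[[:space:]].*$", "", names(set))
  rna_references(ids, as.character(set))
}

#' Read preprocessed reads from FASTA or FASTQ
#'
#' Reads adapter-trimmed pilot reads. The format is taken from the file
#' extension (`.fq`/`.fastq` read as FASTQ, anything else as FASTA).
#' Sequences are normalized to the RNA alphabet; reads containing characters
#' other than A/C/G/U after normalization are dropped with a message, since a
#' read with an ambiguous base cannot be placed by the substitution-only
#' aligner.
#'
#' @param path Path to a FASTA or FASTQ file of reads.
#' @return A data.frame with columns `read_id` and `sequence`.
#' @export
read_reads <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE)) "fastq" else "fasta"
  set <- Biostrings::readBStringSet(path, format = fmt)
  if (length(set) == 0L) stop(sprintf("no reads in '%s'", path), call. = FALSE)
  ids <- sub("[[:space:]].*$", "", names(set))
  seqs <- normalize_rna(as.character(set))
  ok <- !grepl("[^ACGU]", seqs)
  if (any(!ok)) {
    message(sprintf("dropped %d read(s) with ambiguous bases", sum(!ok)))
  }
  data.frame(read_id = ids[ok], sequence = seqs[ok], stringsAsFactors = FALSE)
}

# ---- SAM ------------------------------------------------------------------

# Reference-consumed span of a CIGAR string: M/=/X/D/N advance the reference,
# I/S/H/P do not.
cigar_ref_span <- function(cigar) {
  ops <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1]]
  if (ops[1] == -1L) stop(sprintf("malformed CIGAR '%s'", cigar), call. = FALSE)
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  n <- as.integer(sub("[A-Z=]$", "", toks))
  op <- sub("^[0-9]+", "", toks)
  sum(n[op %in% c("M", "=", "X", "D", "N")])
}

#' Construct a pilot sample from alignments
#'
#' Bundles one pilot Ribo-seq sample's read alignments. Coordinates are
#' 0-based half-open on the named references. Each read id may appear in
#' several placements but at most one may be flagged primary.
#'
#' @param sample_id Sample label.
#' @param alignments data.frame with columns `read_id`, `reference_id`,
#'   `start`, `end`, `is_primary`, `mismatches`.
#' @param references The [rna_references()] the alignments refer to.
#' @return A list of class `pilot_sample` with elements `sample_id`,
#'   `alignments` and `n_primary`.
#' @export
pilot_sample <- function(sample_id, alignments, references) {
  need <- c("read_id", "reference_id", "start", "end", "is_primary", "mismatches")
  if (!all(need %in% names(alignments))) {
    stop("alignments must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (nrow(alignments)) {
    bad <- !(alignments$reference_id %in% references$id)
    if (any(bad)) {
      stop(sprintf("alignment reference '%s' absent from reference set",
                   alignments$reference_id[bad][1]), call. = FALSE)
    }
    L <- references$length[match(alignments$reference_id, references$id)]
    if (any(alignments$start < 0L | alignments$end <= alignments$start |
              alignments$end > L)) {
      stop("alignment interval out of reference bounds", call. = FALSE)
    }
    prim <- alignments$read_id[alignments$is_primary]
    if (anyDuplicated(prim)) {
      stop(sprintf("read '%s' has more than one primary alignment",
                   prim[duplicated(prim)][1]), call. = FALSE)
    }
  }
  structure(
    list(sample_id = sample_id, alignments = alignments,
         n_primary = sum(alignments$is_primary)),
    class = "pilot_sample"
  )
}

#' @export
print.pilot_sample <- function(x, ...) {
  cat(sprintf("pilot sample '%s': %d alignment(s), %d primary\n",
              x$sample_id, nrow(x$alignments), x$n_primary))
  invisible(x)
}

#' Read rRNA alignments from a SAM file
#'
#' Parses the plain-text SAM dialect the pipeline consumes: only QNAME, FLAG,
#' RNAME, POS and CIGAR are used (plus the NM tag when present, for the
#' mismatch count). Unmapped records are skipped; secondary (0x100) and
#' supplementary (0x800) records are kept with `is_primary = FALSE`. SAM's
#' 1-based positions are converted to the internal 0-based half-open
#' convention, with the end coordinate derived from the CIGAR
#' (M/=/X/D/N advance the reference; I does not).
#'
#' @param path Path to a SAM file.
#' @param references [rna_references()] the file was aligned against; `@SQ`
#'   header lines are checked against it (unknown name or length mismatch is
#'   an error).
#' @param sample_id Sample label; defaults to the file name without extension.
#' @return A [pilot_sample()].
#' @export
read_sam <- function(path, references, sample_id = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (is.null(sample_id)) sample_id <- tools::file_path_sans_ext(basename(path))
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "@")]
  for (h in hdr[startsWith(hdr, "@SQ")]) {
    f <- strsplit(h, "\t", fixed = TRUE)[[1]]
    sn <- sub("^SN:", "", f[startsWith(f, "SN:")][1])
    ln <- as.integer(sub("^LN:", "", f[startsWith(f, "LN:")][1]))
    i <- match(sn, references$id)
    if (is.na(i)) stop(sprintf("SAM header names reference '%s' absent from reference set", sn),
                       call. = FALSE)
    if (!is.na(ln) && ln != references$length[i]) {
      stop(sprintf("SAM header length %d for '%s' does not match reference length %d",
                   ln, sn, references$length[i]), call. = FALSE)
    }
  }
  rec <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (!length(rec)) {
    return(pilot_sample(sample_id, data.frame(
      read_id = character(), reference_id = character(), start = integer(),
      end = integer(), is_primary = logical(), mismatches = integer()
    ), references))
  }
  fields <- strsplit(rec, "\t", fixed = TRUE)
  rows <- lapply(fields, function(f) {
    if (length(f) < 11L) stop("malformed SAM record (fewer than 11 fields)", call. = FALSE)
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) != 0L) return(NULL)           # unmapped
    if (!(f[3] %in% references$id)) {
      stop(sprintf("alignment reference '%s' absent from reference set", f[3]), call. = FALSE)
    }
    start <- as.integer(f[4]) - 1L
    span <- cigar_ref_span(f[6])
    nm <- grep("^NM:i:", f[-(1:11)], value = TRUE)
    data.frame(
      read_id = f[1], reference_id = f[3], start = start, end = start + span,
      is_primary = bitwAnd(flag, 0x100L) == 0L && bitwAnd(flag, 0x800L) == 0L,
      mismatches = if (length(nm)) as.integer(sub("^NM:i:", "", nm[1])) else 0L,
      stringsAsFactors = FALSE
    )
  })
  aln <- do.call(rbind, rows)
  if (is.null(aln)) {
    aln <- data.frame(read_id = character(), reference_id = character(),
                      start = integer(), end = integer(),
                      is_primary = logical(), mismatches = integer())
  }
  pilot_sample(sample_id, aln, references)
}

#' Write a pilot sample as SAM
#'
#' Emits the sample's alignments in the same SAM dialect [read_sam()] consumes,
#' so external aligners can be substituted in either direction. Reads are
#' written with `*` sequence (the alignment interval carries all information
#' the pipeline uses) and a pure-match CIGAR.
#'
#' @param sample A [pilot_sample()].
#' @param references The [rna_references()] aligned against.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sam <- function(sample, references, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", references$id, references$length))
  a <- sample$alignments
  body <- if (nrow(a)) {
    flag <- ifelse(a$is_primary, 0L, 256L)
    sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t*\t*\tNM:i:%d",
            a$read_id, flag, a$reference_id, a$start + 1L,
            ifelse(a$is_primary, 255L, 0L), a$end - a$start, a$mismatches)
  } else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

# ---- positional profile ---------------------------------------------------

#' Normalized positional read abundance profile
#'
#' Per-position count of primary alignments covering each base of one
#' reference, divided by a user-supplied normalization denominator (typically
#' the sample's total number of reads mapped to protein-coding transcripts;
#' `n_primary` is a self-normalizing fallback).
#'
#' @param sample A [pilot_sample()].
#' @param reference Single reference id, or one-row subset of the reference set.
#' @param references The [rna_references()].
#' @param denominator Positive count to divide by.
#' @return Numeric vector of length `reference length`; entry p is
#'   (primary reads covering position p) / denominator.
#' @export
positional_profile <- function(sample, reference, references, denominator) {
  if (!is.numeric(denominator) || length(denominator) != 1L || denominator <= 0) {
    stop("denominator must be a single positive number", call. = FALSE)
  }
  if (is.data.frame(reference)) reference <- reference$id[1]
  ref <- ref_lookup(references, reference)
  L <- ref$length
  a <- sample$alignments
  a <- a[a$is_primary & a$reference_id == ref$id, , drop = FALSE]
  cov <- numeric(L + 1L)
  if (nrow(a)) {
    starts <- tabulate(a$start + 1L, nbins = L + 1L)
    ends <- tabulate(a$end + 1L, nbins = L + 1L)
    cov <- cumsum(starts - ends)
  } else {
    cov <- numeric(L + 1L)
  }
  cov[seq_len(L)] / denominator
}

# ---- oligo report writers -------------------------------------------------

# fixed CSV column order for the feature table
.FEATURE_COLUMNS <- c("oligo_id", "target_rRNA_position", "length", "sequence",
                      "gc_content", "minimum_hybridization_energy", "mfe",
                      "structure", "base_pairing_percentage",
                      "overall_depletion_score")

#' Write oligo design outputs in FASTA, CSV, BED and GFF3
#'
#' Writes the four report files for a set of designed oligos. FASTA holds the
#' oligo sequences keyed by oligo id; CSV holds the full feature table (fixed
#' column order, then one depleting-potential column per pilot sample, then
#' `n_offtargets` when off-target scanning was run); BED6 uses 0-based
#' half-open target intervals; GFF3 uses 1-based inclusive intervals with the
#' features as column-9 attributes. The strand column is `-` in both: oligos
#' are antisense to their reference. An empty design set yields valid
#' headers-only files.
#'
#' @param design An `oligo_design` object from [design_oligos()], or a list
#'   with elements `oligos` and `features`.
#' @param out_dir Output directory (created if needed).
#' @param prefix File name prefix, default `"oligos"`.
#' @return Invisibly, named character vector of the files written.
#' @export
write_oligo_outputs <- function(design, out_dir, prefix = "oligos") {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) {
      stop(sprintf("cannot create output directory '%s'", out_dir), call. = FALSE)
    }
  }
  oligos <- design$oligos
  features <- design$features
  paths <- c(
    fasta = file.path(out_dir, paste0(prefix, ".fa")),
    csv = file.path(out_dir, paste0(prefix, ".csv")),
    bed = file.path(out_dir, paste0(prefix, ".bed")),
    gff3 = file.path(out_dir, paste0(prefix, ".gff3"))
  )
  # FASTA
  if (nrow(oligos)) {
    set <- Biostrings::BStringSet(oligos$sequence)
    names(set) <- oligos$oligo_id
    Biostrings::writeXStringSet(set, paths["fasta"])
  } else {
    writeLines(character(), paths["fasta"])
  }
  # CSV: fixed column order, per-sample potential columns, optional n_offtargets
  utils::write.csv(features, paths["csv"], row.names = FALSE, quote = FALSE, na = "")
  # BED6, 0-based half-open, minus strand
  bed <- if (nrow(oligos)) {
    sprintf("%s\t%d\t%d\t%s\t.\t-", oligos$reference_id, oligos$start,
            oligos$end, oligos$oligo_id)
  } else character()
  writeLines(bed, paths["bed"])
  # GFF3, 1-based inclusive, minus strand, features in attributes
  gff_head <- "##gff-version 3"
  gff <- if (nrow(oligos)) {
    attrs <- vapply(seq_len(nrow(oligos)), function(i) {
      fr <- features[features$oligo_id == oligos$oligo_id[i], , drop = FALSE]
      extra <- if (nrow(fr)) {
        keep <- setdiff(names(fr), c("oligo_id", "target_rRNA_position"))
        paste(sprintf("%s=%s", keep, vapply(fr[1, keep], as.character, character(1))),
              collapse = ";")
      } else ""
      paste0("ID=", oligos$oligo_id[i], if (nzchar(extra)) paste0(";", extra) else "")
    }, character(1))
    sprintf("%s\tribodeplete\tdepletion_oligo\t%d\t%d\t.\t-\t.\t%s",
            oligos$reference_id, oligos$start + 1L, oligos$end, attrs)
  } else character()
  writeLines(c(gff_head, gff), paths["gff3"])
  invisible(paths)
}

#' Write the off-target detail report
#'
#' One TSV row per predicted off-target hit: oligo id, transcript id, 0-based
#' half-open interval on the transcript, duplex free energy (kcal/mol) and the
#' length of the complementary stretch.
#'
#' @param hits data.frame of off-target hits as returned in
#'   `offtarget_scan()$hits`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_offtarget_report <- function(hits, path) {
  utils::write.table(
    hits[, c("oligo_id", "transcript_id", "start", "end", "energy", "stretch")],
    path, sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Write RNA sequences as FASTA
#'
#' @param ids,sequences Parallel character vectors.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_rna_fasta <- function(ids, sequences, path) {
  if (length(ids)) {
    set <- Biostrings::BStringSet(sequences)
    names(set) <- ids
    Biostrings::writeXStringSet(set, path)
  } else {
    writeLines(character(), path)
  }
  invisible(path)
}
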