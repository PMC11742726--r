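#' Construct a table of read pairs
#'
#' The central read container: one row per fragment, with mate 1 and
#' (optionally) mate 2 sequence/quality columns and an optional ground-truth
#' origin label set by the simulator. Single-end data leaves the mate-2
#' columns `NA`.
#'
#' @param read_id Character vector of unique read identifiers.
#' @param seq1,seq2 Mate sequences over `A/C/G/T/N` (`seq2` may be `NA` for
#'   single-end records).
#' @param qual1,qual2 Phred+33 quality strings, same lengths as the
#'   sequences, or `NA` when unavailable.
#' @param origin Optional ground-truth origin, `"human"`, `"microbial"` or
#'   `"unknown"`.
#' @return A `data.frame` of class `read_pairs`.
#' @export
#' @examples
#' read_pairs("r1", "ACGT", qual1 = "IIII")
read_pairs <- function(read_id, seq1, qual1 = NA_character_,
                       seq2 = NA_character_, qual2 = NA_character_,
                       origin = NA_character_) {
  n <- length(read_id)
  df <- data.frame(
    read_id = as.character(read_id),
    seq1 = toupper(as.character(seq1)),
    qual1 = as.character(rep_len(qual1, n)),
    seq2 = toupper(as.character(rep_len(seq2, n))),
    qual2 = as.character(rep_len(qual2, n)),
    origin = as.character(rep_len(origin, n)),
    stringsAsFactors = FALSE
  )
  validate_read_pairs(df)
}

#' @rdname read_pairs
#' @param x A data.frame with `read_pairs` columns.
#' @export
validate_read_pairs <- function(x) {
  stopifnot(is.data.frame(x))
  needed <- c("read_id", "seq1", "qual1", "seq2", "qual2")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols)) {
    stop("read_pairs is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(x$read_id)) {
    stop("duplicate read_id in read_pairs: ",
         x$read_id[duplicated(x$read_id)][1])
  }
  if (nrow(x)) {
    if (any(is.na(x$seq1)) || any(!nzchar(x$seq1))) {
      stop("mate-1 sequences must be non-empty")
    }
    .check_alphabet(x$seq1, "seq1")
    has2 <- !is.na(x$seq2)
    if (any(has2 & !nzchar(x$seq2))) stop("mate-2 sequences must be non-empty")
    if (any(has2)) .check_alphabet(x$seq2[has2], "seq2")
    .check_qual_len(x$seq1, x$qual1, "mate 1")
    .check_qual_len(x$seq2[has2], x$qual2[has2], "mate 2")
  }
  if (!"origin" %in% names(x)) x$origin <- NA_character_
  class(x) <- unique(c("read_pairs", class(x)))
  x
}

.check_alphabet <- function(seqs, what) {
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("non-nucleotide characters in ", what, " (record ", which(bad)[1], ")")
  }
}

.check_qual_len <- function(seqs, quals, what) {
  has_q <- !is.na(quals)
  if (any(has_q & nchar(quals) != nchar(seqs))) {
    bad <- which(has_q & nchar(quals) != nchar(seqs))[1]
    stop("sequence/quality length mismatch for ", what, " record ", bad)
  }
}

# Internal FASTQ loader: returns data.frame(read_id, seq, qual); ids are
# truncated at the first whitespace and stripped of trailing /1 or /2.
.read_one_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  ids <- sub("\\s.*$", "", names(x))
  ids <- sub("/[12]$", "", ids)
  quals <- as.character(S4Vectors::mcols(x)$qualities)
  seqs <- as.character(x)
  bad <- which(nchar(quals) != nchar(seqs))
  if (length(bad)) {
    stop("ragged FASTQ record (sequence/quality length mismatch) at record ",
         bad[1], " of ", path)
  }
  data.frame(read_id = ids, seq = seqs, qual = quals, stringsAsFactors = FALSE)
}

#' Read FASTQ files into a read-pair table
#'
#' Parses one (single-end) or two (paired-end) FASTQ files, gzipped or not.
#' Paired files must list the same reads in the same order.
#'
#' @param path Path to the mate-1 (or single-end) FASTQ file.
#' @param paired_with Optional path to the mate-2 FASTQ file.
#' @return A [read_pairs] table; single-end input leaves `seq2`/`qual2` `NA`.
#' @export
read_fastq <- function(path, paired_with = NULL) {
  r1 <- .read_one_fastq(path)
  if (is.null(paired_with)) {
    if (!nrow(r1)) return(read_pairs(character(), character()))
    return(read_pairs(r1$read_id, r1$seq, r1$qual))
  }
  r2 <- .read_one_fastq(paired_with)
  n1 <- nrow(r1); n2 <- nrow(r2)
  if (n1 != n2) {
    stop("R1/R2 record count mismatch at ordinal ", min(n1, n2) + 1,
         " (", n1, " vs ", n2, " records)")
  }
  if (!n1) return(read_pairs(character(), character()))
  mism <- which(r1$read_id != r2$read_id)
  if (length(mism)) {
    stop("R1/R2 read id mismatch at ordinal ", mism[1], ": '",
         r1$read_id[mism[1]], "' vs '", r2$read_id[mism[1]], "'")
  }
  read_pairs(r1$read_id, r1$seq, r1$qual, r2$seq, r2$qual)
}

#' Write a read-pair table to FASTQ
#'
#' Writes mate 1 to `out1` and, when paired records are present, mate 2 to
#' `out2`. A `.gz` suffix triggers gzip compression. Records without stored
#' qualities are written at a constant placeholder quality (`I`).
#'
#' @param pairs A [read_pairs] table.
#' @param out1 Output path for mate 1 / single-end reads.
#' @param out2 Output path for mate 2 (required when any `seq2` is present).
#' @return Invisibly, the number of records (pairs) written.
#' @export
write_fastq <- function(pairs, out1, out2 = NULL) {
  pairs <- validate_read_pairs(pairs)
  .write_one <- function(ids, seqs, quals, path) {
    quals <- ifelse(is.na(quals), strrep("I", nchar(seqs)), quals)
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    Biostrings::writeXStringSet(
      x, path, format = "fastq",
      qualities = Biostrings::BStringSet(quals),
      compress = grepl("\\.gz$", path)
    )
  }
  if (!nrow(pairs)) {
    .write_one(character(), character(), character(), out1)
    if (!is.null(out2)) .write_one(character(), character(), character(), out2)
    return(invisible(0L))
  }
  has2 <- !is.na(pairs$seq2)
  if (any(has2) && is.null(out2)) {
    stop("paired records present but no out2 path given")
  }
  .write_one(pairs$read_id, pairs$seq1, pairs$qual1, out1)
  if (!is.null(out2)) {
    .write_one(pairs$read_id[has2], pairs$seq2[has2], pairs$qual2[has2], out2)
  }
  invisible(nrow(pairs))
}

#' Bundled Illumina adapter sequences
#'
#' The common TruSeq and Nextera adapter read-through sequences used as the
#' default list for [quality_length_filter()]. This is a representative set,
#' not a byte-exact copy of any trimmer's internal list.
#'
#' @return Named character vector of adapter sequences.
#' @export
pml_adapters <- function() {
  path <- system.file("extdata", "adapters.fa", package = "pmlfilter")
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

# Longest 3'-end suffix-overlap with any adapter prefix, minimum overlap 8 bp.
# Returns the number of bases to clip for each sequence.
.adapter_clip <- function(seqs, adapters, min_overlap = 8L) {
  n <- length(seqs)
  L <- nchar(seqs)
  clip <- integer(n)
  for (a in adapters) {
    omax <- nchar(a)
    for (o in seq.int(min_overlap, omax)) {
      cand <- L >= o
      if (!any(cand)) next
      hit <- cand & substring(seqs, L - o + 1L, L) == substr(a, 1L, o)
      clip[hit] <- pmax(clip[hit], o)
    }
  }
  clip
}

#' Length and adapter pre-filtration of read pairs
#'
#' Mirrors the pre-filtration stage applied before any host filtration:
#' adapter read-through is clipped from the 3' end by exact suffix-overlap
#' matching (minimum overlap 8 bp, longest overlap wins, repeated to a fixed
#' point), then any pair in which either mate is shorter than `min_len` bases
#' is dropped entirely. Quality-window trimming is deliberately not applied;
#' only length and adapter content matter downstream.
#'
#' @param pairs A [read_pairs] table.
#' @param min_len Minimum post-trim mate length in bases (default 45).
#' @param adapters Character vector of adapter sequences ([pml_adapters()] by
#'   default); an empty vector applies the length filter only.
#' @return The filtered [read_pairs] table.
#' @export
quality_length_filter <- function(pairs, min_len = 45L,
                                  adapters = pml_adapters()) {
  stopifnot(min_len >= 1L)
  pairs <- validate_read_pairs(pairs)
  if (!nrow(pairs)) return(pairs)
  trim_mate <- function(seqs, quals) {
    todo <- !is.na(seqs)
    if (length(adapters)) {
      repeat {
        clip <- integer(length(seqs))
        clip[todo] <- .adapter_clip(seqs[todo], adapters)
        if (!any(clip > 0L)) break
        keep_to <- nchar(seqs) - clip
        seqs <- ifelse(clip > 0L, substr(seqs, 1L, keep_to), seqs)
        quals <- ifelse(clip > 0L & !is.na(quals),
                        substr(quals, 1L, keep_to), quals)
      }
    }
    list(seq = seqs, qual = quals)
  }
  m1 <- trim_mate(pairs$seq1, pairs$qual1)
  m2 <- trim_mate(pairs$seq2, pairs$qual2)
  pairs$seq1 <- m1$seq; pairs$qual1 <- m1$qual
  pairs$seq2 <- m2$seq; pairs$qual2 <- m2$qual
  len1 <- nchar(pairs$seq1)
  len2 <- ifelse(is.na(pairs$seq2), NA_integer_, nchar(pairs$seq2))
  keep <- len1 >= min_len & (is.na(len2) | len2 >= min_len)
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  validate_read_pairs(out)
}

#' Re-synchronize independently filtered mate streams
#'
#' After per-mate filtering, reads surviving in only one file are orphans.
#' This pairs up the id-intersection (ordered by the first stream) and
#' reports orphans explicitly rather than dropping them.
#'
#' @param survivors1,survivors2 Data frames with columns `read_id`, `seq`,
#'   `qual` (as returned by the internal FASTQ loader), each id-unique.
#' @return A list with elements `pairs` (a [read_pairs] table) and `orphans`
#'   (a data.frame with a `mate` column indicating the surviving side).
#' @export
resync_pairs <- function(survivors1, survivors2) {
  for (s in list(survivors1, survivors2)) {
    stopifnot(all(c("read_id", "seq") %in% names(s)))
  }
  if (anyDuplicated(survivors1$read_id)) {
    stop("duplicate read id in stream 1: ",
         survivors1$read_id[duplicated(survivors1$read_id)][1])
  }
  if (anyDuplicated(survivors2$read_id)) {
    stop("duplicate read id in stream 2: ",
         survivors2$read_id[duplicated(survivors2$read_id)][1])
  }
  if (is.null(survivors1$qual)) survivors1$qual <- NA_character_
  if (is.null(survivors2$qual)) survivors2$qual <- NA_character_
  idx2 <- match(survivors1$read_id, survivors2$read_id)
  both <- !is.na(idx2)
  pairs <- read_pairs(
    survivors1$read_id[both],
    survivors1$seq[both], survivors1$qual[both],
    survivors2$seq[idx2[both]], survivors2$qual[idx2[both]]
  )
  orph1 <- survivors1[!both, c("read_id", "seq", "qual"), drop = FALSE]
  orph2 <- survivors2[!survivors2$read_id %in% survivors1$read_id,
                      c("read_id", "seq", "qual"), drop = FALSE]
  orphans <- rbind(
    cbind(orph1, mate = if (nrow(orph1)) 1L else integer(0)),
    cbind(orph2, mate = if (nrow(orph2)) 2L else integer(0))
  )
  rownames(orphans) <- NULL
  list(pairs = pairs, orphans = orphans)
}

#' Split a read-pair table into per-mate read tables
#'
#' @param pairs A [read_pairs] table.
#' @return List with data frames `r1` and `r2` (columns `read_id`, `seq`,
#'   `qual`); `r2` contains only the paired records.
#' @export
split_pairs <- function(pairs) {
  pairs <- validate_read_pairs(pairs)
  has2 <- !is.na(pairs$seq2)
  list(
    r1 = data.frame(read_id = pairs$read_id, seq = pairs$seq1,
                    qual = pairs$qual1, stringsAsFactors = FALSE),
    r2 = data.frame(read_id = pairs$read_id[has2], seq = pairs$seq2[has2],
                    qual = pairs$qual2[has2], stringsAsFactors = FALSE)
  )
}
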