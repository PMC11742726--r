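#' Build a searchable host-reference index
#'
#' Concatenates all reference sequences and their reverse complements into a
#' separator-joined text and builds a suffix automaton over it, so that exact
#' matching statistics (per-position longest-match lengths) can be computed
#' for arbitrary reads against either strand. Ambiguous (`N`) reference bases
#' are treated as separators and can never be matched.
#'
#' @param references Named character vector (or `DNAStringSet`) of reference
#'   sequences over `A/C/G/T/N`.
#' @param name Label for the index.
#' @return An object of class `host_index` with fields `name`, `source_ids`,
#'   `total_length` (sum of input sequence lengths) and the searchable text.
#' @export
#' @examples
#' idx <- build_index(c(chr = "ACGTACGTAC"))
#' matching_lengths("ACGT", idx)[[1]]
build_index <- function(references, name = "host") {
  if (methods::is(references, "DNAStringSet")) {
    references <- setNames(as.character(references), names(references))
  }
  references <- toupper(references)
  if (!length(references) || any(!nzchar(references))) {
    stop("build_index needs at least one non-empty reference sequence")
  }
  bad <- grepl("[^ACGTN]", references)
  if (any(bad)) {
    stop("non-nucleotide characters in reference ", which(bad)[1])
  }
  ids <- names(references)
  if (is.null(ids)) ids <- paste0("ref", seq_along(references))
  fwd <- gsub("N", "#", references, fixed = TRUE)
  rev <- gsub("N", "#", revcomp(references), fixed = TRUE)
  text <- paste(c(fwd, rev), collapse = "#")
  env <- new.env(parent = emptyenv())
  env$ptr <- sa_build(text)
  idx <- list(
    name = name,
    source_ids = unname(ids),
    total_length = sum(nchar(references)),
    text = text,
    version = .INDEX_VERSION,
    env = env
  )
  class(idx) <- "host_index"
  idx
}

#' @export
print.host_index <- function(x, ...) {
  cat("host_index '", x$name, "': ", length(x$source_ids),
      " reference(s), ", x$total_length, " bp (both strands indexed)\n",
      sep = "")
  invisible(x)
}

# Return a live automaton pointer, rebuilding it if the external pointer was
# lost (e.g. the index came from an RDS artifact).
.index_ptr <- function(index) {
  stopifnot(inherits(index, "host_index"))
  if (is.null(index$env$ptr) || !sa_valid(index$env$ptr)) {
    index$env$ptr <- sa_build(index$text)
  }
  index$env$ptr
}

#' Per-position pseudo-matching lengths of reads against an index
#'
#' For each read, computes the exact matching-statistics vector: position `i`
#' holds the length of the longest prefix of `read[i:]` that occurs in any
#' indexed reference on either strand. `N` bases match nothing. These are the
#' per-read profiles that the score metrics summarize.
#'
#' @param reads Character vector of read sequences (or a [read_pairs] mate
#'   column).
#' @param index A `host_index` from [build_index()].
#' @return A list of integer vectors, one per read, each of the read's
#'   length.
#' @export
matching_lengths <- function(reads, index) {
  reads <- toupper(as.character(reads))
  if (any(is.na(reads)) || any(!nzchar(reads))) {
    stop("reads must be non-empty, non-NA sequences")
  }
  sa_matching_lengths(.index_ptr(index), reads)
}

#' Read reference sequences from FASTA
#'
#' @param path Multi-record FASTA file (gzip ok).
#' @return Named character vector of sequences.
#' @export
read_fasta_refs <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

#' Save / load a host index artifact
#'
#' The artifact stores the index metadata and searchable text; the automaton
#' itself is rebuilt on load. Loading an artifact with a different format
#' version is an error.
#'
#' @param index A `host_index`.
#' @param path Artifact path (RDS).
#' @return `save_index` returns `path` invisibly; `load_index` returns the
#'   restored `host_index`.
#' @export
save_index <- function(index, path) {
  stopifnot(inherits(index, "host_index"))
  saveRDS(index[c("name", "source_ids", "total_length", "text", "version")],
          path)
  invisible(path)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  x <- readRDS(path)
  if (!identical(x$version, .INDEX_VERSION)) {
    stop("index artifact version '", x$version, "' does not match '",
         .INDEX_VERSION, "'")
  }
  x$env <- new.env(parent = emptyenv())
  x$env$ptr <- sa_build(x$text)
  class(x) <- "host_index"
  x
}
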