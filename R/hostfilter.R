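#' Deterministic internal seed-and-extend aligner
#'
#' A hermetic aligner used by the alignment-based filtration stages: exact
#' k-mer seeds against both strands of the reference set, ungapped extension
#' along the seed diagonal, and a "mapped" call when identity reaches
#' `min_ident` over at least `min_len` bases. A pair counts as mapped when
#' either mate maps.
#'
#' @param k Seed length in bases.
#' @param min_len Minimum aligned overlap in bases.
#' @param min_ident Minimum identity over the overlap.
#' @return An object of class `pml_aligner` with an `align(pairs, refs)`
#'   function returning one logical (`pair mapped`) per input pair.
#' @export
internal_aligner <- function(k = 15L, min_len = 60L, min_ident = 0.9) {
  stopifnot(k >= 4L, k <= 31L, min_len >= k, min_ident > 0, min_ident <= 1)
  align <- function(pairs, refs) {
    pairs <- validate_read_pairs(pairs)
    if (!nrow(pairs)) return(logical(0))
    text <- .ref_text(refs)
    m1 <- seed_align(text, pairs$seq1, as.integer(k), as.integer(min_len),
                     min_ident)
    m2 <- seed_align(text, pairs$seq2, as.integer(k), as.integer(min_len),
                     min_ident)
    m1 | (!is.na(m2) & m2)
  }
  structure(list(name = "internal-seed-extend", align = align,
                 params = list(k = k, min_len = min_len,
                               min_ident = min_ident)),
            class = "pml_aligner")
}

# Both strands of a reference set, separator-joined; N behaves as a separator.
.ref_text <- function(refs) {
  refs <- .resolve_refs(refs)
  paste(gsub("N", "#", c(refs, revcomp(refs)), fixed = TRUE), collapse = "#")
}

# Accept a named character vector of sequences or a FASTA path.
.resolve_refs <- function(refs) {
  if (is.character(refs) && length(refs) == 1L && file.exists(refs) &&
      !grepl("^[ACGTN]+$", toupper(refs))) {
    refs <- read_fasta_refs(refs)
  }
  refs <- toupper(refs)
  if (!length(refs) || any(!nzchar(refs))) stop("empty reference set")
  refs
}

#' External minimap2/samtools aligner adapter
#'
#' Invokes `minimap2 -2 -ax sr` and extracts unmapped reads with
#' `samtools fastq -f 12 -F 256 -N` (paired) or `-f 4 -F 256` (single-end),
#' i.e. a pair survives only when both mates are unmapped. Requires both
#' binaries on `PATH`.
#'
#' @param minimap2,samtools Binary names or paths.
#' @return A `pml_aligner` whose `align(pairs, refs)` returns one logical
#'   (`pair mapped`) per pair.
#' @export
minimap2_aligner <- function(minimap2 = "minimap2", samtools = "samtools") {
  for (bin in c(minimap2, samtools)) {
    if (!nzchar(Sys.which(bin))) stop("external tool not found on PATH: ", bin)
  }
  align <- function(pairs, refs) {
    pairs <- validate_read_pairs(pairs)
    if (!nrow(pairs)) return(logical(0))
    refs <- .resolve_refs(refs)
    td <- tempfile("mm2_")
    dir.create(td)
    on.exit(unlink(td, recursive = TRUE), add = TRUE)
    ref_fa <- file.path(td, "ref.fa")
    ids <- names(refs)
    if (is.null(ids)) ids <- paste0("ref", seq_along(refs))
    writeLines(paste0(">", ids, "\n", refs), ref_fa)
    paired <- any(!is.na(pairs$seq2))
    r1 <- file.path(td, "r1.fq"); r2 <- file.path(td, "r2.fq")
    sam <- file.path(td, "out.sam")
    o1 <- file.path(td, "un1.fq"); o2 <- file.path(td, "un2.fq")
    if (paired) {
      write_fastq(pairs, r1, r2)
      system2(minimap2, c("-2", "-ax", "sr", ref_fa, r1, r2),
              stdout = sam, stderr = FALSE)
      system2(samtools, c("fastq", "-f", "12", "-F", "256", "-N",
                          "-1", o1, "-2", o2, sam),
              stdout = FALSE, stderr = FALSE)
      surv <- .read_one_fastq(o1)$read_id
    } else {
      write_fastq(pairs, r1)
      system2(minimap2, c("-2", "-ax", "sr", ref_fa, r1),
              stdout = sam, stderr = FALSE)
      system2(samtools, c("fastq", "-f", "4", "-F", "256", "-0", o1, sam),
              stdout = FALSE, stderr = FALSE)
      surv <- .read_one_fastq(o1)$read_id
    }
    !(pairs$read_id %in% surv)
  }
  structure(list(name = "minimap2", align = align, params = list()),
            class = "pml_aligner")
}

#' Alignment-based filtration stage
#'
#' A pair survives if and only if both mates fail to align to the stage's
#' reference (single-end: the read is unmapped).
#'
#' @param pairs A [read_pairs] table.
#' @param reference Named character vector of reference sequences or a FASTA
#'   path.
#' @param aligner A `pml_aligner` ([internal_aligner()] by default).
#' @return The surviving [read_pairs] table.
#' @export
align_filter_stage <- function(pairs, reference,
                               aligner = internal_aligner()) {
  stopifnot(inherits(aligner, "pml_aligner"))
  pairs <- validate_read_pairs(pairs)
  if (!nrow(pairs)) return(pairs)
  mapped <- aligner$align(pairs, reference)
  out <- pairs[!mapped, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Index-based filtration stage
#'
#' Scores every mate's pseudo-matching-length profile against the host index
#' and removes a pair when either mate is classified host.
#'
#' @param pairs A [read_pairs] table.
#' @param index A `host_index` from [build_index()].
#' @param config A [score_config()].
#' @return The surviving [read_pairs] table.
#' @export
index_filter_stage <- function(pairs, index, config = score_config()) {
  pairs <- validate_read_pairs(pairs)
  if (!nrow(pairs)) return(pairs)
  host1 <- classify_reads(matching_lengths(pairs$seq1, index),
                          config) == "host"
  has2 <- !is.na(pairs$seq2)
  host2 <- rep(FALSE, nrow(pairs))
  if (any(has2)) {
    host2[has2] <- classify_reads(matching_lengths(pairs$seq2[has2], index),
                                  config) == "host"
  }
  out <- pairs[!(host1 | host2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compose a filtration plan
#'
#' A plan is an ordered list of stages, each either an alignment stage
#' (`stage_align`) or an index stage (`stage_index`), applied sequentially.
#'
#' @param ... Stage descriptors from [stage_align()] / [stage_index()].
#' @return An object of class `filtration_plan`.
#' @export
filtration_plan <- function(...) {
  stages <- list(...)
  if (length(stages) == 1L && is.list(stages[[1]]) &&
      !inherits(stages[[1]], "pml_stage")) {
    stages <- stages[[1]]
  }
  if (!length(stages)) stop("a filtration plan needs at least one stage")
  ok <- vapply(stages, inherits, logical(1), what = "pml_stage")
  if (!all(ok)) stop("all plan elements must be stage_align()/stage_index()")
  structure(list(stages = stages), class = "filtration_plan")
}

#' @rdname filtration_plan
#' @param reference Reference sequences (named character vector) or FASTA
#'   path for an alignment stage.
#' @param label Stage label used in reports.
#' @export
stage_align <- function(reference, label = "align") {
  structure(list(type = "align", reference = reference, label = label),
            class = "pml_stage")
}

#' @rdname filtration_plan
#' @param index A `host_index` for an index stage.
#' @param config A [score_config()] for the index stage.
#' @export
stage_index <- function(index, config = score_config(), label = "index") {
  stopifnot(inherits(index, "host_index"))
  structure(list(type = "index", index = index, config = config,
                 label = label),
            class = "pml_stage")
}

#' Preset filtration methods
#'
#' Builds the three benchmark pipelines from a named reference collection:
#' * Method 1: align to the primary reference, align to the secondary
#'   reference, then index-filter against the aggregate of all references.
#' * Method 2: align to primary, secondary and each pangenome haplotype in
#'   turn, then index-filter against the aggregate.
#' * Method 3: index-filter against the aggregate only.
#'
#' Method 2's stages are a superset of Method 1's, which superset Method
#' 3's, so survivor sets are nested (Method 2 is the most stringent).
#'
#' @param n Method number, 1, 2 or 3.
#' @param refs A list with named character vectors `primary_ref`,
#'   `secondary_ref` and `pangenome_set` (each element one sequence;
#'   `pangenome_set` may hold many). Methods 1-2 need all three; Method 3
#'   needs whatever should be indexed.
#' @param config A [score_config()] for the final index stage.
#' @return A `filtration_plan`.
#' @export
preset_method <- function(n, refs, config = score_config()) {
  stopifnot(n %in% 1:3)
  need <- if (n == 3) character(0) else c("primary_ref", "secondary_ref")
  if (n == 2) need <- c(need, "pangenome_set")
  missing_refs <- setdiff(need, names(refs)[!vapply(refs, is.null, logical(1))])
  if (length(missing_refs)) {
    stop("method ", n, " requires reference set(s): ",
         paste(missing_refs, collapse = ", "))
  }
  all_refs <- unlist(refs[intersect(c("primary_ref", "secondary_ref",
                                      "pangenome_set"), names(refs))])
  if (!length(all_refs)) stop("no reference sequences supplied")
  idx <- build_index(all_refs, name = "aggregate")
  stages <- list()
  if (n <= 2) {
    stages <- c(stages, list(stage_align(refs$primary_ref, "align:primary"),
                             stage_align(refs$secondary_ref,
                                         "align:secondary")))
  }
  if (n == 2) {
    pg <- refs$pangenome_set
    ids <- names(pg)
    if (is.null(ids)) ids <- paste0("pangenome", seq_along(pg))
    for (i in seq_along(pg)) {
      stages <- c(stages, list(stage_align(pg[i],
                                           paste0("align:", ids[i]))))
    }
  }
  stages <- c(stages, list(stage_index(idx, config, "index:aggregate")))
  filtration_plan(stages)
}

#' Run a filtration plan
#'
#' Applies the plan's stages in order, keeping a telescoping per-stage report
#' (survivors of stage k are the input of stage k+1; removed + survivors
#' equal the input at every stage).
#'
#' @param pairs A [read_pairs] table.
#' @param plan A `filtration_plan`.
#' @param aligner The `pml_aligner` used by alignment stages.
#' @param audit When `TRUE`, attach a per-read removal-stage audit table.
#' @return A list with `survivors` (a [read_pairs] table) and `report` (a
#'   data.frame with columns `stage`, `type`, `label`, `input`, `removed`,
#'   `survivors`); with `audit = TRUE` also `audit` (read_id, removed_stage).
#' @export
run_plan <- function(pairs, plan, aligner = internal_aligner(),
                     audit = FALSE) {
  stopifnot(inherits(plan, "filtration_plan"))
  pairs <- validate_read_pairs(pairs)
  cur <- pairs
  report <- vector("list", length(plan$stages))
  audit_tbl <- if (audit) {
    data.frame(read_id = pairs$read_id, removed_stage = NA_integer_,
               stringsAsFactors = FALSE)
  }
  for (s in seq_along(plan$stages)) {
    st <- plan$stages[[s]]
    n_in <- nrow(cur)
    out <- tryCatch(
      switch(st$type,
        align = align_filter_stage(cur, st$reference, aligner),
        index = index_filter_stage(cur, st$index, st$config),
        stop("unknown stage type: ", st$type)
      ),
      error = function(e) stop("stage ", s, " (", st$label, ") failed: ",
                               conditionMessage(e), call. = FALSE)
    )
    if (audit && n_in > nrow(out)) {
      gone <- setdiff(cur$read_id, out$read_id)
      audit_tbl$removed_stage[audit_tbl$read_id %in% gone] <- s
    }
    report[[s]] <- data.frame(stage = s, type = st$type, label = st$label,
                              input = n_in, removed = n_in - nrow(out),
                              survivors = nrow(out))
    cur <- out
  }
  res <- list(survivors = cur, report = do.call(rbind, report))
  if (audit) res$audit <- audit_tbl
  res
}
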