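# Shared fixture builders and independent oracles.

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Independent brute-force matching-statistics oracle: for every read start
# position, binary-search the longest prefix found verbatim (fixed-string
# search) in the two-strand separator-joined reference text. Shares no code
# with the suffix-automaton path.
oracle_text <- function(refs) {
  paste(c(gsub("N", "#", refs, fixed = TRUE),
          gsub("N", "#", revcomp(refs), fixed = TRUE)), collapse = "#")
}

oracle_matching_lengths <- function(read, text) {
  L <- nchar(read)
  vapply(seq_len(L), function(i) {
    lo <- 0L
    hi <- L - i + 1L
    while (lo < hi) {
      mid <- as.integer((lo + hi + 1L) %/% 2L)
      if (grepl(substr(read, i, i + mid - 1L), text, fixed = TRUE)) {
        lo <- mid
      } else {
        hi <- mid - 1L
      }
    }
    lo
  }, integer(1))
}

# A fully-decayed PML vector: runs of the given lengths separated by zero
# gaps, padded with zeros to length L.
pml_with_runs <- function(run_lengths, L, gap = 1L) {
  v <- integer(0)
  for (r in run_lengths) v <- c(v, seq.int(r, 1L), rep(0L, gap))
  stopifnot(length(v) <= L)
  c(v, rep(0L, L - length(v)))
}

# Small deterministic paired-end fixture written as FASTQ files.
write_pair_fixture <- function(dir, n = 4L, rl = 60L, seed = 11L) {
  set.seed(seed)
  ids <- sprintf("fx%03d", seq_len(n))
  p <- read_pairs(ids,
                  vapply(seq_len(n), function(i) random_dna(rl), ""),
                  strrep("I", rl),
                  vapply(seq_len(n), function(i) random_dna(rl), ""),
                  strrep("F", rl))
  r1 <- file.path(dir, "fx_R1.fastq")
  r2 <- file.path(dir, "fx_R2.fastq")
  write_fastq(p, r1, r2)
  list(pairs = p, r1 = r1, r2 = r2)
}

# Benchmark fixture shared by the filtration tests: a base genome, held-out
# haplotypes that generate the human reads, held-in haplotypes acting as
# secondary assembly / pangenome references, and random microbial genomes.
make_benchmark_fixture <- function(seed, n_pairs, genome_len = 10000L,
                                   n_sim_haps = 10L, n_microbes = 10L) {
  base <- make_genome(genome_len, seed = seed, id = "base")
  haps <- make_haplotypes(base, n_sim_haps + 3L, seed = seed + 1L)
  microbes <- lapply(seq_len(n_microbes), function(i) {
    make_genome(genome_len, gc = 0.5, seed = seed + 100L + i,
                id = paste0("mic", i), kind = "microbial")
  })
  spec <- mixture_spec(n_reads = n_pairs, seed = seed)
  mix <- make_mixture(haps[seq_len(n_sim_haps)], microbes, spec)
  hap_seq <- function(h) setNames(h$sequence, h$id)
  list(
    base = base, haps = haps, microbes = microbes, spec = spec, mix = mix,
    refs = list(
      primary_ref = c(base = base$sequence),
      secondary_ref = hap_seq(haps[[n_sim_haps + 1L]]),
      pangenome_set = c(hap_seq(haps[[n_sim_haps + 2L]]),
                        hap_seq(haps[[n_sim_haps + 3L]]))
    )
  )
}
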