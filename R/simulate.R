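#' Synthetic genome constructor
#'
#' @param length Genome length in bases.
#' @param gc GC content as a proportion (default 0.41, human-like).
#' @param seed Integer seed (mandatory; all simulator randomness is seeded).
#' @param id Genome identifier.
#' @param kind One of `"human_base"`, `"human_haplotype"`, `"microbial"`.
#' @return An object of class `synthetic_genome` with fields `id`,
#'   `sequence`, `kind`, `parent`, `variant_log`.
#' @export
make_genome <- function(length, gc = 0.41, seed, id = NULL,
                        kind = c("human_base", "microbial",
                                 "human_haplotype")) {
  stopifnot(length >= 1)
  if (!is.numeric(gc) || gc < 0 || gc > 1) stop("gc must be in [0, 1]")
  kind <- match.arg(kind)
  set.seed(.sub_seed(seed, 1L))
  bases <- sample(c("A", "T", "G", "C"), length, replace = TRUE,
                  prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
  if (is.null(id)) id <- paste0(substr(kind, 1, 1), "_", seed)
  structure(list(id = id, sequence = paste(bases, collapse = ""),
                 kind = kind, parent = NULL, variant_log = NULL),
            class = "synthetic_genome")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat("synthetic_genome '", x$id, "' (", x$kind, "): ",
      nchar(x$sequence), " bp",
      if (!is.null(x$parent)) paste0(", parent ", x$parent), "\n", sep = "")
  invisible(x)
}

#' Apply a variant log to a parent sequence
#'
#' Replays SNPs, deletions and insertions (1-based positions on the parent,
#' non-overlapping) onto a parent sequence; the inverse of reading a
#' haplotype's `variant_log`.
#'
#' @param sequence Parent nucleotide string.
#' @param variant_log Data frame with `position`, `ref_allele`,
#'   `alt_allele`.
#' @return The derived sequence.
#' @export
apply_variants <- function(sequence, variant_log) {
  if (is.null(variant_log) || !nrow(variant_log)) return(sequence)
  vl <- variant_log[order(variant_log$position), , drop = FALSE]
  out <- character(2 * nrow(vl) + 1)
  cursor <- 1L
  k <- 0L
  for (i in seq_len(nrow(vl))) {
    pos <- vl$position[i]
    ref <- vl$ref_allele[i]
    alt <- vl$alt_allele[i]
    k <- k + 1L
    out[k] <- substr(sequence, cursor, pos - 1L)
    k <- k + 1L
    out[k] <- alt
    cursor <- pos + nchar(ref)
  }
  out[k + 1L] <- substr(sequence, cursor, nchar(sequence))
  paste(out[seq_len(k + 1L)], collapse = "")
}

#' Derive mutated haplotypes from a base genome
#'
#' Emulates population-level pangenome diversity: each haplotype carries
#' independent substitutions at `snp_rate` and short (1-3 bp) insertions or
#' deletions at `indel_rate` per base, recorded in a complete `variant_log`
#' sufficient to reconstruct the haplotype from its parent.
#'
#' @param base A `synthetic_genome` (the shared base assembly).
#' @param n Number of haplotypes.
#' @param snp_rate,indel_rate Per-base event rates, each in `[0, 0.05]`.
#' @param seed Integer seed.
#' @return A list of `synthetic_genome` objects of kind `human_haplotype`.
#' @export
make_haplotypes <- function(base, n, snp_rate = 0.001, indel_rate = 1e-4,
                            seed) {
  stopifnot(inherits(base, "synthetic_genome"),
            snp_rate >= 0, snp_rate <= 0.05,
            indel_rate >= 0, indel_rate <= 0.05, n >= 1)
  L <- nchar(base$sequence)
  lapply(seq_len(n), function(h) {
    set.seed(.sub_seed(seed, h))
    n_snp <- rbinom(1, L, snp_rate)
    n_ind <- rbinom(1, L, indel_rate)
    # sample distinct, non-adjacent positions so variants never overlap
    pos_all <- sort(sample.int(L - 4L, n_snp + n_ind))
    if (length(pos_all) > 1L) {
      pos_all <- pos_all[c(TRUE, diff(pos_all) > 4L)]
    }
    is_snp <- seq_along(pos_all) %in%
      sample.int(length(pos_all), min(n_snp, length(pos_all)))
    vl <- do.call(rbind, lapply(seq_along(pos_all), function(i) {
      pos <- pos_all[i]
      ref1 <- substr(base$sequence, pos, pos)
      if (is_snp[i]) {
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref1), 1)
        data.frame(position = pos, ref_allele = ref1, alt_allele = alt)
      } else if (runif(1) < 0.5) { # deletion of 1-3 bases after the anchor
        dl <- sample(1:3, 1)
        data.frame(position = pos,
                   ref_allele = substr(base$sequence, pos, pos + dl),
                   alt_allele = ref1)
      } else { # insertion of 1-3 bases after the anchor
        ins <- paste(sample(c("A", "C", "G", "T"), sample(1:3, 1),
                            replace = TRUE), collapse = "")
        data.frame(position = pos, ref_allele = ref1,
                   alt_allele = paste0(ref1, ins))
      }
    }))
    if (is.null(vl)) {
      vl <- data.frame(position = integer(), ref_allele = character(),
                       alt_allele = character())
    }
    structure(list(id = paste0(base$id, "_hap", h),
                   sequence = apply_variants(base$sequence, vl),
                   kind = "human_haplotype", parent = base$id,
                   variant_log = vl),
              class = "synthetic_genome")
  })
}

#' Mixture simulation settings
#'
#' Defaults encode the benchmark design: 150 bp paired reads, an even
#' human/microbial split, a low i.i.d. substitution error rate and a
#' human-library-like insert distribution.
#'
#' @param n_reads Number of read pairs in a mixture.
#' @param frac_human Proportion of pairs drawn from human haplotypes.
#' @param read_length Read length in bases.
#' @param error_rate Per-base substitution error probability.
#' @param insert_mean,insert_sd Fragment length distribution in bases.
#' @param seed Integer seed (mandatory).
#' @return An object of class `mixture_spec`.
#' @export
mixture_spec <- function(n_reads = 10000L, frac_human = 0.5,
                         read_length = 150L, error_rate = 0.005,
                         insert_mean = 350, insert_sd = 35, seed) {
  stopifnot(frac_human >= 0, frac_human <= 1, n_reads >= 0,
            read_length >= 1, error_rate >= 0, error_rate < 1,
            insert_mean >= read_length, insert_sd >= 0)
  if (missing(seed) || is.null(seed)) {
    stop("mixture_spec requires an explicit seed")
  }
  structure(list(n_reads = as.integer(n_reads), frac_human = frac_human,
                 read_length = as.integer(read_length),
                 error_rate = error_rate, insert_mean = insert_mean,
                 insert_sd = insert_sd, seed = as.integer(seed)),
            class = "mixture_spec")
}

# i.i.d. substitution errors on a character-matrix of reads
.add_errors <- function(seqs, error_rate) {
  if (error_rate <= 0 || !length(seqs)) return(seqs)
  vapply(seqs, function(s) {
    b <- strsplit(s, "")[[1]]
    hit <- which(runif(length(b)) < error_rate)
    for (i in hit) b[i] <- sample(setdiff(c("A", "C", "G", "T"), b[i]), 1)
    paste(b, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate paired-end reads from one genome
#'
#' Fragments are drawn uniformly from either strand with a normal insert
#' length distribution; mate 1 reads the fragment's 5' end, mate 2 is the
#' reverse complement of the 3' end. Substitution errors are i.i.d. at
#' `spec$error_rate`; qualities are constant Phred 35. Ground-truth labels
#' and reference-coordinate placements are attached.
#'
#' @param genome A `synthetic_genome`.
#' @param n_pairs Number of pairs to draw.
#' @param spec A [mixture_spec()].
#' @param id_prefix Prefix for generated read ids.
#' @param stream Sub-stream index so different genomes get independent
#'   randomness under one master seed.
#' @return A [read_pairs] table with extra columns `src_genome`,
#'   `frag_start`, `frag_end`, `strand`.
#' @export
simulate_reads <- function(genome, n_pairs, spec, id_prefix = genome$id,
                           stream = 1L) {
  stopifnot(inherits(genome, "synthetic_genome"),
            inherits(spec, "mixture_spec"), n_pairs >= 0)
  L <- nchar(genome$sequence)
  rl <- spec$read_length
  if (L < spec$insert_mean + 4 * spec$insert_sd) {
    stop("genome '", genome$id, "' too short (", L,
         " bp) for insert distribution")
  }
  empty <- read_pairs(character(), character())
  empty$src_genome <- character(0); empty$frag_start <- integer(0)
  empty$frag_end <- integer(0); empty$strand <- character(0)
  if (n_pairs == 0) return(empty)
  set.seed(.sub_seed(spec$seed, stream))
  frag <- pmin(pmax(round(rnorm(n_pairs, spec$insert_mean, spec$insert_sd)),
                    rl), L)
  start <- vapply(frag, function(f) sample.int(L - f + 1L, 1L), integer(1))
  end <- start + frag - 1L
  strand <- sample(c("+", "-"), n_pairs, replace = TRUE)
  left <- substr(rep(genome$sequence, n_pairs), start, start + rl - 1L)
  right <- substr(rep(genome$sequence, n_pairs), end - rl + 1L, end)
  # mate 2 as sequenced is the reverse complement of the fragment's far end
  # in sequencing orientation; on the minus strand that is the plus-strand
  # left end read forward
  seq1 <- ifelse(strand == "+", left, revcomp(right))
  seq2 <- ifelse(strand == "+", revcomp(right), left)
  seq1 <- .add_errors(seq1, spec$error_rate)
  seq2 <- .add_errors(seq2, spec$error_rate)
  qual <- strrep("D", rl) # Phred 35
  origin <- switch(genome$kind, microbial = "microbial", "human")
  out <- read_pairs(sprintf("%s_%06d", id_prefix, seq_len(n_pairs)),
                    seq1, qual, seq2, qual, origin = origin)
  out$src_genome <- genome$id
  out$frag_start <- as.integer(start)
  out$frag_end <- as.integer(end)
  out$strand <- strand
  out
}

#' Simulate a labeled human/microbial read mixture
#'
#' Draws `spec$frac_human` of the pairs from the supplied human haplotypes
#' and the rest from the microbial genomes (spread uniformly across genomes
#' within each side), then shuffles deterministically under the spec seed.
#'
#' @param human_haplotypes List of `synthetic_genome` objects (human side).
#' @param microbial_genomes List of `synthetic_genome` objects (microbial
#'   side).
#' @param spec A [mixture_spec()].
#' @return A list with `pairs` (shuffled [read_pairs] with truth columns)
#'   and `truth` (data.frame `read_id`, `origin`, `source_genome`).
#' @export
make_mixture <- function(human_haplotypes, microbial_genomes, spec) {
  stopifnot(inherits(spec, "mixture_spec"))
  if ((spec$frac_human > 0 && !length(human_haplotypes)) ||
      (spec$frac_human < 1 && !length(microbial_genomes))) {
    stop("both genome lists must be non-empty for a mixed draw")
  }
  n_h <- round(spec$n_reads * spec$frac_human)
  n_m <- spec$n_reads - n_h
  spread <- function(total, k) {
    if (k == 0) return(integer(0))
    base <- rep(total %/% k, k)
    extra <- total %% k
    if (extra > 0) base[seq_len(extra)] <- base[seq_len(extra)] + 1L
    base
  }
  stream <- 0L
  sim_side <- function(genomes, counts, prefix) {
    out <- vector("list", length(genomes))
    for (i in seq_along(genomes)) {
      stream <<- stream + 1L
      out[[i]] <- simulate_reads(genomes[[i]], counts[i], spec,
                                 id_prefix = paste0(prefix, i),
                                 stream = stream)
    }
    do.call(rbind, out)
  }
  hp <- sim_side(human_haplotypes, spread(n_h, length(human_haplotypes)), "h")
  mp <- sim_side(microbial_genomes, spread(n_m, length(microbial_genomes)),
                 "m")
  all_pairs <- rbind(hp, mp)
  set.seed(.sub_seed(spec$seed, 999983L))
  if (!is.null(all_pairs) && nrow(all_pairs)) {
    all_pairs <- all_pairs[sample.int(nrow(all_pairs)), , drop = FALSE]
    rownames(all_pairs) <- NULL
  } else {
    all_pairs <- simulate_reads(human_haplotypes[[1]], 0L, spec)
  }
  all_pairs <- validate_read_pairs(all_pairs)
  truth <- data.frame(read_id = all_pairs$read_id,
                      origin = all_pairs$origin,
                      source_genome = all_pairs$src_genome,
                      stringsAsFactors = FALSE)
  list(pairs = all_pairs, truth = truth)
}

#' Held-out reference selection
#'
#' Removes the genomes whose reads went into a mixture from the reference
#' collection used for filtration, so that filtration is evaluated against
#' unseen haplotypes.
#'
#' @param genomes List of `synthetic_genome` objects (base plus haplotypes).
#' @param exclude Character vector of genome ids used for simulation.
#' @return The retained sublist.
#' @export
holdout_references <- function(genomes, exclude) {
  ids <- vapply(genomes, function(g) g$id, character(1))
  unknown <- setdiff(exclude, ids)
  if (length(unknown)) {
    stop("exclude ids not present: ", paste(unknown, collapse = ", "))
  }
  keep <- !(ids %in% exclude)
  if (!any(keep)) stop("exclusion would empty the reference set")
  genomes[keep]
}

#' Filtration benchmark against ground truth
#'
#' @param survivor_ids Read ids surviving filtration.
#' @param truth Truth table from [make_mixture()].
#' @return An object of class `benchmark_result` with counts
#'   `human_remaining`, `human_removed`, `microbial_remaining`,
#'   `microbial_lost`, `total_human`, `total_microbial`.
#' @export
benchmark_filtration <- function(survivor_ids, truth) {
  unknown <- setdiff(survivor_ids, truth$read_id)
  if (length(unknown)) {
    stop("survivor id not in truth table: ", unknown[1])
  }
  surv <- truth$read_id %in% survivor_ids
  human <- truth$origin == "human"
  res <- list(
    human_remaining = sum(surv & human),
    human_removed = sum(!surv & human),
    microbial_remaining = sum(surv & !human),
    microbial_lost = sum(!surv & !human),
    total_human = sum(human),
    total_microbial = sum(!human)
  )
  structure(res, class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("benchmark_result: human ", x$human_remaining, "/", x$total_human,
      " remaining; microbial ", x$microbial_lost, "/", x$total_microbial,
      " lost\n", sep = "")
  invisible(x)
}

#' Coverage depth/breadth artifact diagnostic
#'
#' Computes per-base depth from read placements via a difference array and
#' summarizes it as breadth (covered fraction), mean depth, and the ratio of
#' the densest 1 kb window to the mean depth. A sharp coverage peak with low
#' breadth is the signature of artifactual mismapping to a low-complexity
#' locus rather than genuine presence of the genome.
#'
#' @param placements Data frame with 1-based inclusive `start`, `end`
#'   columns.
#' @param genome_length Genome length in bases.
#' @param window Window size for the peak statistic (bases).
#' @param breadth_max,peak_min Artifact-flag defaults: flagged when breadth
#'   < `breadth_max` and peak ratio > `peak_min`.
#' @return A list with `breadth`, `mean_depth`, `peak_ratio`, `artifact`
#'   (logical, `NA` when not evaluable).
#' @export
coverage_profile <- function(placements, genome_length, window = 1000L,
                             breadth_max = 0.01, peak_min = 10) {
  stopifnot(genome_length >= 1)
  if (nrow(placements)) {
    if (any(placements$start < 1) || any(placements$end > genome_length) ||
        any(placements$end < placements$start)) {
      stop("invalid interval in placements")
    }
  }
  d <- numeric(genome_length + 1L)
  if (nrow(placements)) {
    add <- tabulate(placements$start, nbins = genome_length + 1L)
    rem <- tabulate(placements$end + 1L, nbins = genome_length + 1L)
    d <- add - rem
  }
  depth <- cumsum(d[seq_len(genome_length)])
  breadth <- mean(depth > 0)
  mean_depth <- mean(depth)
  if (mean_depth == 0) {
    return(list(breadth = 0, mean_depth = 0, peak_ratio = NA_real_,
                artifact = NA))
  }
  win_id <- (seq_len(genome_length) - 1L) %/% window
  win_mean <- tapply(depth, win_id, mean)
  peak_ratio <- max(win_mean) / mean_depth
  list(breadth = breadth, mean_depth = mean_depth, peak_ratio = peak_ratio,
       artifact = breadth < breadth_max && peak_ratio > peak_min)
}

#' Reference-oriented per-mate placements from simulated pairs
#'
#' Expands a simulated [read_pairs] table (with truth columns) into one row
#' per mate with reference coordinates and the mate sequence re-oriented to
#' the reference strand, ready for pileup or coverage computation.
#'
#' @param pairs A simulated [read_pairs] table carrying `src_genome`,
#'   `frag_start`, `frag_end`, `strand`.
#' @param mapq Constant mapping quality to attach.
#' @return Data frame with `read_id`, `mate`, `src_genome`, `start`, `end`,
#'   `seq` (reference-oriented), `qual`, `mapq`.
#' @export
reads_placements <- function(pairs, mapq = 60L) {
  stopifnot(all(c("src_genome", "frag_start", "frag_end", "strand") %in%
                  names(pairs)))
  if (!nrow(pairs)) {
    return(data.frame(read_id = character(), mate = integer(),
                      src_genome = character(), start = integer(),
                      end = integer(), seq = character(),
                      qual = character(), mapq = integer()))
  }
  rl1 <- nchar(pairs$seq1)
  rl2 <- nchar(pairs$seq2)
  plus <- pairs$strand == "+"
  # left segment = [frag_start, frag_start + rl - 1], right = [end - rl + 1, end]
  m1 <- data.frame(
    read_id = pairs$read_id, mate = 1L, src_genome = pairs$src_genome,
    start = ifelse(plus, pairs$frag_start, pairs$frag_end - rl1 + 1L),
    end = ifelse(plus, pairs$frag_start + rl1 - 1L, pairs$frag_end),
    seq = ifelse(plus, pairs$seq1, revcomp(pairs$seq1)),
    qual = pairs$qual1, mapq = mapq, stringsAsFactors = FALSE
  )
  has2 <- !is.na(pairs$seq2)
  m2 <- data.frame(
    read_id = pairs$read_id[has2], mate = 2L,
    src_genome = pairs$src_genome[has2],
    start = ifelse(plus[has2], pairs$frag_end[has2] - rl2[has2] + 1L,
                   pairs$frag_start[has2]),
    end = ifelse(plus[has2], pairs$frag_end[has2],
                 pairs$frag_start[has2] + rl2[has2] - 1L),
    seq = ifelse(plus[has2], revcomp(pairs$seq2[has2]), pairs$seq2[has2]),
    qual = pairs$qual2[has2], mapq = mapq, stringsAsFactors = FALSE
  )
  out <- rbind(m1, m2)
  rownames(out) <- NULL
  out
}

#' Simulate an HWE genotype panel over a base genome
#'
#' Places biallelic SNP sites at random positions of the base genome, draws
#' alternative-allele frequencies uniformly from `maf_range`, and samples
#' genotypes for every panel member under Hardy-Weinberg equilibrium.
#'
#' @param genome A `synthetic_genome` providing coordinates and reference
#'   alleles.
#' @param n_samples Number of panel members.
#' @param n_sites Number of SNP sites.
#' @param seed Integer seed.
#' @param maf_range Range of alternative-allele frequencies.
#' @return A [genotype_panel] object.
#' @export
simulate_genotype_panel <- function(genome, n_samples, n_sites, seed,
                                    maf_range = c(0.05, 0.95)) {
  stopifnot(inherits(genome, "synthetic_genome"), n_samples >= 1,
            n_sites >= 1)
  L <- nchar(genome$sequence)
  stopifnot(n_sites <= L - 2)
  set.seed(.sub_seed(seed, 17L))
  pos <- sort(sample.int(L - 1L, n_sites))
  ref <- substring(genome$sequence, pos, pos)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                character(1), USE.NAMES = FALSE)
  p <- runif(n_sites, maf_range[1], maf_range[2])
  g <- matrix(rbinom(n_sites * n_samples, 2L,
                     rep(p, times = n_samples)),
              nrow = n_sites, ncol = n_samples)
  sites <- data.frame(site = paste0("s", seq_len(n_sites)), pos = pos,
                      ref = ref, alt = alt, p = p,
                      stringsAsFactors = FALSE)
  genotype_panel(sites, g,
                 samples = sprintf("sample%03d", seq_len(n_samples)))
}

#' Diploid donor haplotypes carrying a panel member's genotypes
#'
#' Builds the two haplotype sequences of one panel member by substituting
#' that sample's alternative alleles into the base genome (heterozygous
#' sites phased at random under the seed). Reads simulated from these
#' haplotypes are the "leaked" host reads of the designated true donor.
#'
#' @param panel A [genotype_panel].
#' @param genome The base `synthetic_genome` the panel was simulated on.
#' @param donor Sample index or name.
#' @param seed Integer seed (for phasing).
#' @return List of two `synthetic_genome` haplotypes (SNP-only variant
#'   logs, so haplotype coordinates match base coordinates).
#' @export
donor_haplotypes <- function(panel, genome, donor, seed) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (is.character(donor)) donor <- match(donor, panel$samples)
  stopifnot(!is.na(donor), donor >= 1, donor <= length(panel$samples))
  g <- panel$genotypes[, donor]
  set.seed(.sub_seed(seed, 29L))
  to_hap1 <- g == 2L | (g == 1L & runif(length(g)) < 0.5)
  to_hap2 <- g == 2L | (g == 1L & !to_hap1)
  mk <- function(mask, tag) {
    vl <- data.frame(position = panel$sites$pos[mask],
                     ref_allele = panel$sites$ref[mask],
                     alt_allele = panel$sites$alt[mask],
                     stringsAsFactors = FALSE)
    structure(list(id = paste0(panel$samples[donor], "_", tag),
                   sequence = apply_variants(genome$sequence, vl),
                   kind = "human_haplotype", parent = genome$id,
                   variant_log = vl),
              class = "synthetic_genome")
  }
  list(mk(to_hap1, "hapA"), mk(to_hap2, "hapB"))
}
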