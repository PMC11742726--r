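#' Genotype panel container
#'
#' Site-by-sample genotypes with per-site alternative-allele frequencies:
#' the inputs of the re-identification likelihood model. Genotypes are
#' alternative-allele counts (0 = Ref/Ref, 1 = Ref/Alt, 2 = Alt/Alt); only
#' biallelic SNPs are admitted.
#'
#' @param sites Data frame with columns `site`, `pos`, `ref`, `alt`, `p`
#'   (alternative-allele frequency in `[0, 1]`).
#' @param genotypes Integer matrix, sites x samples, values in `{0, 1, 2}`,
#'   no missing values.
#' @param samples Sample names (defaults to the matrix column names).
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(sites, genotypes, samples = colnames(genotypes)) {
  genotypes <- as.matrix(genotypes)
  stopifnot(is.data.frame(sites),
            all(c("site", "pos", "ref", "alt", "p") %in% names(sites)),
            nrow(sites) == nrow(genotypes))
  if (is.null(samples)) samples <- paste0("sample", seq_len(ncol(genotypes)))
  stopifnot(length(samples) == ncol(genotypes))
  if (any(is.na(genotypes)) || !all(genotypes %in% 0:2)) {
    stop("genotypes must be complete and in {0, 1, 2}")
  }
  if (any(sites$p < 0 | sites$p > 1)) stop("allele frequency p outside [0, 1]")
  bad <- !(sites$ref %in% c("A", "C", "G", "T")) |
    !(sites$alt %in% c("A", "C", "G", "T")) | sites$ref == sites$alt
  if (any(bad)) stop("sites must be biallelic SNPs (record ", which(bad)[1], ")")
  if (anyDuplicated(sites$site)) stop("duplicate site ids")
  structure(list(sites = sites, genotypes = genotypes,
                 samples = as.character(samples)),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel: ", nrow(x$sites), " sites x ", length(x$samples),
      " samples\n", sep = "")
  invisible(x)
}

#' Read a genotype panel from TSV
#'
#' Expected columns: `site`, `pos`, `ref`, `alt`, `p`, then one 0/1/2 column
#' per sample.
#'
#' @param path TSV file path.
#' @return A [genotype_panel].
#' @export
read_genotype_panel_tsv <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta <- c("site", "pos", "ref", "alt", "p")
  if (!all(meta %in% names(x))) {
    stop("panel TSV must have columns: ", paste(meta, collapse = ", "))
  }
  samp <- setdiff(names(x), meta)
  if (!length(samp)) stop("panel TSV has no sample columns")
  genotype_panel(x[meta], as.matrix(x[samp]), samples = samp)
}

#' Read a genotype panel from VCF
#'
#' Extracts GT fields with `vcfR`, keeps biallelic SNPs only (multi-allelic
#' or non-SNP records are excluded with a message), and derives allele
#' frequencies from the panel itself unless `p` is supplied.
#'
#' @param path VCF file path.
#' @param p Optional externally supplied alternative-allele frequencies
#'   (one per retained site, in file order).
#' @return A [genotype_panel].
#' @export
read_genotype_panel_vcf <- function(path, p = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_genotype_panel_vcf requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  keep <- fix$REF %in% c("A", "C", "G", "T") &
    fix$ALT %in% c("A", "C", "G", "T")
  if (any(!keep)) {
    message(sum(!keep), " multi-allelic or non-SNP site(s) excluded")
  }
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  dose <- matrix(0L, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dose[] <- vapply(gsub("\\|", "/", gt), function(x) {
    a <- strsplit(x, "/")[[1]]
    sum(a == "1")
  }, integer(1))
  if (is.null(p)) p <- rowMeans(dose) / 2
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, ":", fix$POS), fix$ID)
  sites <- data.frame(site = ids, pos = as.integer(fix$POS), ref = fix$REF,
                      alt = fix$ALT, p = p, stringsAsFactors = FALSE)
  genotype_panel(sites, dose, samples = colnames(gt))
}

#' Re-identification analysis settings
#'
#' @param epsilon Per-base read error probability (default 1e-6).
#' @param prune_window,prune_step,r2_max LD-pruning parameters: sliding
#'   windows of `prune_window` sites advanced by `prune_step`, removing one
#'   of any pair with squared genotype correlation above `r2_max`.
#' @param min_mapq,min_baseq Pileup quality cutoffs.
#' @param alpha Family-wise significance level for Bonferroni lines.
#' @return An object of class `reident_config`.
#' @export
reident_config <- function(epsilon = 1e-6, prune_window = 100L,
                           prune_step = 30L, r2_max = 0.1, min_mapq = 40L,
                           min_baseq = 20L, alpha = 0.05) {
  stopifnot(epsilon > 0, epsilon < 0.5, prune_window >= 1, prune_step >= 1,
            r2_max >= 0, r2_max <= 1, alpha > 0, alpha < 1)
  structure(list(epsilon = epsilon, prune_window = as.integer(prune_window),
                 prune_step = as.integer(prune_step), r2_max = r2_max,
                 min_mapq = as.integer(min_mapq),
                 min_baseq = as.integer(min_baseq), alpha = alpha),
            class = "reident_config")
}

#' Per-site read likelihood of a genotype
#'
#' Likelihood that a diploid genotype with `g` alternative alleles produced
#' `k` reference-allele reads out of `n` covering reads, with per-base error
#' probability `eps`:
#' \deqn{L(g, n, k) = 2^{-n} \, [(2-g)\epsilon + g(1-\epsilon)]^{n-k} \,
#'   [g\epsilon + (2-g)(1-\epsilon)]^{k}.}
#' Computed in log space; vectorized over sites.
#'
#' @param g Genotype(s) in `{0, 1, 2}`.
#' @param n,k Covering reads and reference-allele reads per site.
#' @param eps Error probability.
#' @param log Return log-likelihood?
#' @return Numeric vector of (log-)likelihoods.
#' @export
#' @examples
#' site_likelihood(1, n = 4, k = 2) # 2^-4: heterozygotes are uninformative
site_likelihood <- function(g, n, k, eps = 1e-6, log = FALSE) {
  if (any(!(g %in% 0:2))) stop("genotype g must be 0, 1 or 2")
  stopifnot(all(n >= 1), all(k >= 0), all(k <= n), eps > 0, eps < 0.5)
  ll <- -n * base::log(2) +
    (n - k) * base::log((2 - g) * eps + g * (1 - eps)) +
    k * base::log(g * eps + (2 - g) * (1 - eps))
  if (log) ll else exp(ll)
}

#' Likelihood score of one genotype sample
#'
#' Sum over sites of the log per-site likelihoods: the evidence that this
#' sample's genotypes produced the observed leaked-read pileup.
#'
#' @param g Integer vector of the sample's genotypes over the pileup sites.
#' @param pileup Data frame with columns `n`, `k` aligned with `g`.
#' @param eps Error probability.
#' @return The scalar likelihood score (natural log); 0 for an empty site
#'   set.
#' @export
likelihood_score <- function(g, pileup, eps = 1e-6) {
  stopifnot(length(g) == nrow(pileup))
  if (!nrow(pileup)) return(0)
  if (any(pileup$n == 0)) stop("pileup contains uncovered sites (n = 0)")
  sum(site_likelihood(g, pileup$n, pileup$k, eps, log = TRUE))
}

#' Background moments of the likelihood score under HWE
#'
#' Expectation and variance of the likelihood score for a genotype drawn at
#' random from a population with the panel's allele frequencies, assuming
#' Hardy-Weinberg genotype frequencies \{(1-p)^2, 2p(1-p), p^2\} and
#' independent sites; totals are sums of per-site moments.
#'
#' @param p Alternative-allele frequency per pileup site.
#' @param pileup Data frame with columns `n`, `k` aligned with `p`.
#' @param eps Error probability.
#' @return List with scalars `E` and `V` and a per-site data.frame.
#' @export
background_moments <- function(p, pileup, eps = 1e-6) {
  stopifnot(length(p) == nrow(pileup), all(p >= 0), all(p <= 1))
  if (!nrow(pileup)) return(list(E = 0, V = 0, per_site = data.frame()))
  if (any(pileup$n == 0)) stop("pileup contains uncovered sites (n = 0)")
  ll0 <- site_likelihood(0L, pileup$n, pileup$k, eps, log = TRUE)
  ll1 <- site_likelihood(1L, pileup$n, pileup$k, eps, log = TRUE)
  ll2 <- site_likelihood(2L, pileup$n, pileup$k, eps, log = TRUE)
  w0 <- (1 - p)^2
  w1 <- 2 * p * (1 - p)
  w2 <- p^2
  Ei <- w0 * ll0 + w1 * ll1 + w2 * ll2
  Vi <- w0 * (ll0 - Ei)^2 + w1 * (ll1 - Ei)^2 + w2 * (ll2 - Ei)^2
  list(E = sum(Ei), V = sum(Vi),
       per_site = data.frame(E = Ei, V = Vi))
}

#' Standardize a likelihood score and test it
#'
#' Standardizes against the population background and converts to a
#' two-sided p-value under the standard normal. A candidate match must have
#' its score above the background (`z > 0`); a large negative `z` is
#' reported but is not a match.
#'
#' @param LS Likelihood score(s).
#' @param E,V Background mean and variance from [background_moments()].
#' @return Data frame with `z`, `p`, `match_direction` (logical, `z > 0`).
#' @export
standardize_and_test <- function(LS, E, V) {
  if (!is.finite(V) || V <= 0) {
    stop("background variance must be positive (not-evaluable site set)")
  }
  z <- (LS - E) / sqrt(V)
  data.frame(z = z, p = 2 * pnorm(-abs(z)), match_direction = z > 0)
}

#' Greedy LD pruning of panel sites
#'
#' Sliding windows of `window` sites advanced by `step`: within each window,
#' while any retained pair has squared Pearson genotype correlation above
#' `r2_max`, the member with the lower minor-allele frequency is dropped
#' (ties drop the later position). Returns the retained site ids.
#'
#' @param panel A [genotype_panel].
#' @param window,step,r2_max Pruning parameters.
#' @return Character vector of retained site ids.
#' @export
ld_prune <- function(panel, window = 100L, step = 30L, r2_max = 0.1) {
  stopifnot(inherits(panel, "genotype_panel"), window >= 1, step >= 1)
  N <- nrow(panel$sites)
  if (N == 0) stop("ld_prune needs at least one site")
  ord <- order(panel$sites$pos)
  g <- panel$genotypes[ord, , drop = FALSE]
  maf <- pmin(panel$sites$p[ord], 1 - panel$sites$p[ord])
  pos <- panel$sites$pos[ord]
  keep <- rep(TRUE, N)
  for (ws in seq(1L, max(N - 1L, 1L), by = step)) {
    idx <- ws:min(ws + window - 1L, N)
    repeat {
      act <- idx[keep[idx]]
      if (length(act) < 2) break
      cm <- suppressWarnings(stats::cor(t(g[act, , drop = FALSE])))
      cm[is.na(cm)] <- 0
      r2 <- cm^2
      diag(r2) <- 0
      if (max(r2) <= r2_max) break
      hit <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
      a <- act[hit[1]]; b <- act[hit[2]]
      drop <- if (maf[a] < maf[b]) a
              else if (maf[b] < maf[a]) b
              else if (pos[a] >= pos[b]) a else b
      keep[drop] <- FALSE
    }
    if (max(idx) == N) break
  }
  panel$sites$site[ord][keep]
}

#' Pileup counts at panel sites from placed reads
#'
#' Counts, at every panel SNP site, the reads passing the mapping-quality
#' cutoff that overlap the site with a base passing the base-quality cutoff
#' (`n`), and how many of those carry the reference allele (`k`); reads
#' carrying any other allele count toward `n` only. Sites covered by no read
#' are excluded.
#'
#' @param reads Data frame with columns `start`, `seq` (reference-oriented),
#'   `qual` (Phred+33, may be `NA`), `mapq` (as from [reads_placements()]).
#' @param sites Data frame with columns `site`, `pos`, `ref`.
#' @param min_mapq,min_baseq Quality cutoffs.
#' @return Data frame `site`, `pos`, `n`, `k` for covered sites, in site
#'   order.
#' @export
pileup_from_reads <- function(reads, sites, min_mapq = 40L,
                              min_baseq = 20L) {
  stopifnot(all(c("start", "seq") %in% names(reads)),
            all(c("site", "pos", "ref") %in% names(sites)))
  if (is.null(reads$mapq)) reads$mapq <- 60L
  if (is.null(reads$qual)) reads$qual <- NA_character_
  reads <- reads[reads$mapq >= min_mapq, , drop = FALSE]
  empty <- data.frame(site = character(), pos = integer(), n = integer(),
                      k = integer())
  if (!nrow(reads) || !nrow(sites)) return(empty)
  rr <- IRanges::IRanges(start = reads$start,
                         end = reads$start + nchar(reads$seq) - 1L)
  sr <- IRanges::IRanges(start = sites$pos, width = 1L)
  ov <- IRanges::findOverlaps(sr, rr)
  if (!length(ov)) return(empty)
  si <- S4Vectors::queryHits(ov)
  ri <- S4Vectors::subjectHits(ov)
  off <- sites$pos[si] - reads$start[ri] + 1L
  base <- substring(reads$seq[ri], off, off)
  qchar <- substring(reads$qual[ri], off, off)
  bq <- ifelse(is.na(reads$qual[ri]) | qchar == "", Inf,
               as.integer(vapply(qchar, function(c) utf8ToInt(c),
                                 integer(1))) - 33L)
  pass <- bq >= min_baseq & base %in% c("A", "C", "G", "T")
  si <- si[pass]; base <- base[pass]
  if (!length(si)) return(empty)
  n <- tabulate(si, nbins = nrow(sites))
  k <- tabulate(si[base == sites$ref[si]], nbins = nrow(sites))
  covered <- n > 0
  data.frame(site = sites$site[covered], pos = sites$pos[covered],
             n = n[covered], k = k[covered], stringsAsFactors = FALSE)
}

#' Bonferroni bookkeeping for an all-vs-all design
#'
#' @param J Number of genotype samples.
#' @param M Number of metagenome read sets.
#' @param alpha Family-wise level.
#' @return List with `n_tests` (`J * M`), `study_wide` (`alpha / (J * M)`)
#'   and `per_panel` (`alpha / J`) thresholds.
#' @export
#' @examples
#' reident_design(343, 343) # 117649 tests
reident_design <- function(J, M, alpha = 0.05) {
  stopifnot(J >= 1, M >= 1)
  list(n_tests = J * M, study_wide = alpha / (J * M), per_panel = alpha / J)
}

#' All-vs-all re-identification scan
#'
#' For each metagenome read set: restrict the panel to sites covered by at
#' least one passing read, LD-prune the covered sites, rebuild the pileup on
#' the retained sites, score every panel sample, standardize against the
#' HWE background and convert to two-sided p-values. Read sets with no
#' usable site (or zero background variance) are marked not-evaluable.
#'
#' @param read_sets Named list of placed-read data frames (see
#'   [pileup_from_reads()]).
#' @param panel A [genotype_panel].
#' @param config A [reident_config()].
#' @return An object of class `reident_result`: matrices `p` and `z`
#'   (samples x read sets), `evaluable` and `bases_used` per read set,
#'   `design` (from [reident_design()]), and `significant` (data.frame of
#'   pairs with `z > 0` below the study-wide line).
#' @export
all_vs_all <- function(read_sets, panel, config = reident_config()) {
  stopifnot(inherits(panel, "genotype_panel"),
            inherits(config, "reident_config"))
  if (!length(read_sets)) stop("at least one read set is required")
  if (is.null(names(read_sets))) {
    names(read_sets) <- paste0("metagenome", seq_along(read_sets))
  }
  J <- length(panel$samples)
  M <- length(read_sets)
  design <- reident_design(J, M, config$alpha)
  p_mat <- matrix(NA_real_, J, M, dimnames = list(panel$samples,
                                                  names(read_sets)))
  z_mat <- p_mat
  bases_used <- setNames(numeric(M), names(read_sets))
  evaluable <- setNames(logical(M), names(read_sets))
  for (m in seq_len(M)) {
    pu <- pileup_from_reads(read_sets[[m]], panel$sites,
                            min_mapq = config$min_mapq,
                            min_baseq = config$min_baseq)
    if (!nrow(pu)) next
    covered <- panel$sites$site %in% pu$site
    sub <- genotype_panel(panel$sites[covered, , drop = FALSE],
                          panel$genotypes[covered, , drop = FALSE],
                          panel$samples)
    kept <- ld_prune(sub, window = config$prune_window,
                     step = config$prune_step, r2_max = config$r2_max)
    use <- match(kept, pu$site)
    pu <- pu[use[!is.na(use)], , drop = FALSE]
    prow <- match(pu$site, panel$sites$site)
    if (!nrow(pu)) next
    bases_used[m] <- sum(pu$n)
    bg <- background_moments(panel$sites$p[prow], pu, config$epsilon)
    if (!is.finite(bg$V) || bg$V <= 0) next
    LS <- vapply(seq_len(J), function(j) {
      likelihood_score(panel$genotypes[prow, j], pu, config$epsilon)
    }, numeric(1))
    st <- standardize_and_test(LS, bg$E, bg$V)
    p_mat[, m] <- st$p
    z_mat[, m] <- st$z
    evaluable[m] <- TRUE
  }
  hits <- which(p_mat < design$study_wide & z_mat > 0, arr.ind = TRUE)
  significant <- data.frame(
    sample = rownames(p_mat)[hits[, 1]],
    read_set = colnames(p_mat)[hits[, 2]],
    p = p_mat[hits], z = z_mat[hits], stringsAsFactors = FALSE
  )
  structure(list(p = p_mat, z = z_mat, evaluable = evaluable,
                 bases_used = bases_used, design = design,
                 significant = significant, config = config),
            class = "reident_result")
}

#' @export
print.reident_result <- function(x, ...) {
  cat("reident_result: ", nrow(x$p), " genotype sample(s) x ", ncol(x$p),
      " metagenome(s) = ", x$design$n_tests, " tests\n",
      "  study-wide line p = ", signif(x$design$study_wide, 3),
      ", per-panel line p = ", signif(x$design$per_panel, 3), "\n",
      "  evaluable read sets: ", sum(x$evaluable), "/",
      length(x$evaluable), "; significant pairs: ", nrow(x$significant),
      "\n", sep = "")
  invisible(x)
}
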