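test_that("per-site likelihoods match the closed form", {
  # heterozygotes make both alleles equally likely: exactly 2^-n
  for (n in c(1, 4, 10)) {
    for (k in c(0, n %/% 2, n)) {
      expect_equal(site_likelihood(1, n, k), 2^-n)
    }
  }
  # homozygous reference with all-reference reads approaches 1 as eps -> 0
  expect_equal(site_likelihood(0, 5, 5, eps = 1e-12), (1 - 1e-12)^5,
               tolerance = 1e-15)
  # hand-substituted case: g=0, n=3, k=1 -> eps^2 (1 - eps)
  eps <- 1e-6
  expect_equal(site_likelihood(0, 3, 1, eps), eps^2 * (1 - eps))
  # g/k symmetry: swapping ref and alt flips g and k together
  expect_equal(site_likelihood(0, 7, 2, eps), site_likelihood(2, 7, 5, eps))
  expect_error(site_likelihood(3, 2, 1), "genotype")
  expect_error(site_likelihood(0, 2, 3))
})

test_that("log-space evaluation stays finite at deep coverage", {
  ll <- site_likelihood(0, n = 1e4, k = 1e4, log = TRUE)
  expect_true(is.finite(ll))
  expect_equal(ll, -1e4 * log(2) + 1e4 * log(2 * (1 - 1e-6)))
  # the worst case: all reads contradict the genotype
  expect_true(is.finite(site_likelihood(0, 1e4, 0, log = TRUE)))
})

test_that("likelihood scores sum per-site logs", {
  expect_equal(likelihood_score(1L, data.frame(n = 4, k = 2)), -4 * log(2))
  expect_equal(likelihood_score(integer(), data.frame(n = integer(),
                                                      k = integer())), 0)
  set.seed(27)
  n <- sample(1:6, 50, replace = TRUE)
  k <- vapply(n, function(x) sample(0:x, 1), integer(1))
  g <- sample(0:2, 50, replace = TRUE)
  pu <- data.frame(n = n, k = k)
  expect_equal(likelihood_score(g, pu),
               sum(log(site_likelihood(g, n, k))))
  expect_error(likelihood_score(0L, data.frame(n = 0, k = 0)), "n = 0")
})

test_that("background moments agree with the HWE mixture by hand", {
  # degenerate population: p = 0 fixes g = 0, so V = 0
  pu <- data.frame(n = c(3, 2), k = c(3, 1))
  bg0 <- background_moments(c(0, 0), pu)
  expect_equal(bg0$E, sum(site_likelihood(0, pu$n, pu$k, log = TRUE)))
  expect_equal(bg0$V, 0)
  # p = 0.5, single site n=1, k=1: weights forced to 1/4, 1/2, 1/4
  pu1 <- data.frame(n = 1, k = 1)
  lls <- vapply(0:2, site_likelihood, numeric(1), n = 1, k = 1, log = TRUE)
  bg <- background_moments(0.5, pu1)
  expect_equal(bg$E, 0.25 * lls[1] + 0.5 * lls[2] + 0.25 * lls[3])
  expect_equal(bg$V, sum(c(0.25, 0.5, 0.25) * (lls - bg$E)^2))
  expect_error(background_moments(1.5, pu1), "p")
})

test_that("background moments match Monte-Carlo genotype draws", {
  set.seed(29)
  N <- 60
  p <- runif(N, 0.1, 0.9)
  n <- sample(1:5, N, replace = TRUE)
  k <- vapply(n, function(x) sample(0:x, 1), integer(1))
  pu <- data.frame(n = n, k = k)
  bg <- background_moments(p, pu)
  B <- 2e4
  ll <- cbind(site_likelihood(0, n, k, log = TRUE),
              site_likelihood(1, n, k, log = TRUE),
              site_likelihood(2, n, k, log = TRUE))
  draws <- matrix(rbinom(N * B, 2, p), nrow = N)
  picked <- ll[cbind(rep(seq_len(N), B), as.vector(draws) + 1L)]
  ls_draws <- colSums(matrix(picked, nrow = N))
  se_mean <- stats::sd(ls_draws) / sqrt(B)
  expect_lt(abs(mean(ls_draws) - bg$E), 4 * se_mean)
  dev <- (ls_draws - mean(ls_draws))^2
  se_var <- stats::sd(dev) / sqrt(B)
  expect_lt(abs(var(ls_draws) - bg$V), 4 * se_var)
})

test_that("standardization and the two-sided normal test behave", {
  st <- standardize_and_test(c(-2, 0, 2), 0, 1)
  expect_equal(st$z, c(-2, 0, 2))
  expect_equal(st$p[2], 1)
  expect_equal(st$p[1], st$p[3]) # sign symmetry
  expect_equal(st$match_direction, c(FALSE, FALSE, TRUE))
  # a 5.33-sigma excess sits below the study-wide line of a 343x343 design
  z <- standardize_and_test(5.33, 0, 1)
  expect_equal(z$p, 2 * pnorm(-5.33))
  expect_lt(z$p, reident_design(343, 343)$study_wide)
  expect_error(standardize_and_test(1, 0, 0), "variance")
})

test_that("LD pruning removes correlated sites and nothing else", {
  mk_panel <- function(g, p = NULL, pos = NULL) {
    N <- nrow(g)
    if (is.null(p)) p <- rowMeans(g) / 2
    if (is.null(pos)) pos <- seq_len(N) * 10L
    genotype_panel(data.frame(site = paste0("s", seq_len(N)), pos = pos,
                              ref = "A", alt = "C", p = p),
                   g)
  }
  set.seed(31)
  single <- mk_panel(matrix(rbinom(40, 2, 0.5), nrow = 1))
  expect_equal(ld_prune(single), "s1")

  # duplicated columns are perfectly correlated: exactly one survives
  row <- rbinom(60, 2, 0.5)
  dup <- mk_panel(rbind(row, row, rbinom(60, 2, 0.5)))
  kept <- ld_prune(dup)
  expect_equal(sum(kept %in% c("s1", "s2")), 1L)
  expect_true("s3" %in% kept)

  # brute-force verification on a random panel with planted correlation
  base <- matrix(rbinom(30 * 80, 2, 0.4), nrow = 30)
  base[7, ] <- base[3, ]
  base[15, ] <- pmin(2L, base[9, ] + rbinom(80, 1, 0.05))
  panel <- mk_panel(base)
  kept <- ld_prune(panel, window = 100, step = 30, r2_max = 0.1)
  g <- panel$genotypes[match(kept, panel$sites$site), ]
  cm <- suppressWarnings(cor(t(g)))^2
  diag(cm) <- 0
  cm[is.na(cm)] <- 0
  expect_lte(max(cm), 0.1)
})

test_that("pileups honor quality cutoffs and allele counting", {
  sites <- data.frame(site = "s1", pos = 100L, ref = "A", alt = "G")
  reads <- data.frame(
    read_id = sprintf("r%d", 1:5),
    start = c(91L, 95L, 99L, 100L, 60L),
    seq = c(strrep("A", 20), # ref at site
            paste0(strrep("C", 5), "G", strrep("C", 14)), # alt at site
            paste0("TG", strrep("T", 10)), # other allele: n only
            strrep("A", 10), # ref, but low mapq
            strrep("A", 20)), # does not overlap
    qual = strrep("I", 20),
    mapq = c(60L, 60L, 60L, 39L, 60L),
    stringsAsFactors = FALSE
  )
  pu <- pileup_from_reads(reads, sites)
  expect_equal(pu$n, 3L)
  expect_equal(pu$k, 1L)

  # base quality below 20 drops the base from the pileup
  lowq <- reads[1, ]
  lowq$qual <- strrep("#", 20) # Phred 2
  expect_equal(nrow(pileup_from_reads(lowq, sites)), 0L)

  # sites covered by no read are excluded entirely
  far <- data.frame(site = "s2", pos = 5000L, ref = "A", alt = "G")
  expect_equal(nrow(pileup_from_reads(reads, far)), 0L)
})

test_that("all-vs-all bookkeeping matches the design arithmetic", {
  d <- reident_design(343, 343)
  expect_equal(d$n_tests, 117649L)
  expect_equal(d$per_panel, 0.05 / 343)
  expect_equal(d$study_wide, 0.05 / 117649)
  d1 <- reident_design(1, 1)
  expect_equal(d1$n_tests, 1L)
  expect_equal(d1$study_wide, 0.05)
})

test_that("a leaking donor is recovered on the diagonal and only there", {
  seed <- 37
  base <- make_genome(15000, seed = seed, id = "base")
  panel <- simulate_genotype_panel(base, n_samples = 60, n_sites = 120,
                                   seed = seed)
  spec <- mixture_spec(n_reads = 200, frac_human = 1, error_rate = 0.001,
                       seed = seed)
  sets <- list()
  for (donor in 1:3) {
    dh <- donor_haplotypes(panel, base, donor = donor, seed = seed + donor)
    reads <- rbind(simulate_reads(dh[[1]], 100, spec, stream = donor * 2),
                   simulate_reads(dh[[2]], 100, spec,
                                  stream = donor * 2 + 1))
    reads$read_id <- sprintf("d%d_%04d", donor, seq_len(nrow(reads)))
    sets[[paste0("mg", donor)]] <- reads_placements(reads)
  }
  res <- all_vs_all(sets, panel)
  expect_true(all(res$evaluable))
  expect_true(all(res$bases_used > 200))
  for (m in 1:3) {
    expect_equal(unname(which.min(res$p[, m])), m)
    expect_lt(res$p[m, m], res$design$study_wide)
    expect_gt(res$z[m, m], 0)
  }
  # off-diagonal entries behave like background draws
  off <- res$p[cbind(c(2, 3, 1), 1:3)]
  expect_true(all(off > res$design$per_panel))
  expect_equal(dim(res$p), c(60L, 3L))
  expect_true(all(res$significant$sample == paste0("sample",
                                                   sprintf("%03d", 1:3))
                  [match(res$significant$read_set, c("mg1", "mg2", "mg3"))]))
})

test_that("panels round-trip through the TSV interface", {
  td <- withr::local_tempdir()
  base <- make_genome(3000, seed = 41)
  panel <- simulate_genotype_panel(base, n_samples = 5, n_sites = 8,
                                   seed = 42)
  tab <- cbind(panel$sites,
               as.data.frame(panel$genotypes |>
                               `colnames<-`(panel$samples)))
  path <- file.path(td, "panel.tsv")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_genotype_panel_tsv(path)
  expect_equal(back$genotypes, panel$genotypes, ignore_attr = TRUE)
  expect_equal(back$sites$p, panel$sites$p)
  expect_equal(back$samples, panel$samples)
})

test_that("genotype panels reject malformed input", {
  sites <- data.frame(site = "s1", pos = 1L, ref = "A", alt = "G", p = 0.5)
  expect_error(genotype_panel(sites, matrix(3L, 1, 2)), "0, 1, 2")
  expect_error(genotype_panel(sites, matrix(NA_integer_, 1, 2)), "complete")
  bad_p <- transform(sites, p = 1.5)
  expect_error(genotype_panel(bad_p, matrix(1L, 1, 2)), "\\[0, 1\\]")
  bad_allele <- transform(sites, alt = "A")
  expect_error(genotype_panel(bad_allele, matrix(1L, 1, 2)), "biallelic")
})

test_that("genotype panels load from VCF with multi-allelic exclusion", {
  skip_if_not_installed("vcfR")
  td <- withr::local_tempdir()
  vcf <- file.path(td, "panel.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "chr1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "chr1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t0|1\t0|0\t0|1",
    "chr1\t300\trs3\tG\tGA\t.\tPASS\t.\tGT\t0/0\t0/0\t0/1",
    "chr1\t400\trs4\tT\tA,C\t.\tPASS\t.\tGT\t0/0\t0/1\t0/2"
  ), vcf)
  expect_message(panel <- read_genotype_panel_vcf(vcf), "excluded")
  expect_equal(nrow(panel$sites), 2L)
  expect_equal(panel$sites$site, c("rs1", "rs2"))
  expect_equal(unname(panel$genotypes[1, ]), c(0L, 1L, 2L))
  expect_equal(unname(panel$genotypes[2, ]), c(1L, 0L, 1L))
  expect_equal(panel$sites$p, c(mean(c(0, 1, 2)) / 2, mean(c(1, 0, 1)) / 2))
  expect_equal(panel$samples, c("S1", "S2", "S3"))
})
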