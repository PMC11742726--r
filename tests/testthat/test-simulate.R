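test_that("genome generation is seeded, GC-controlled and validated", {
  g1 <- make_genome(1000, seed = 1)
  g2 <- make_genome(1000, seed = 1)
  expect_identical(g1$sequence, g2$sequence)
  expect_false(identical(g1$sequence, make_genome(1000, seed = 2)$sequence))

  gc1 <- make_genome(500, gc = 1, seed = 3)
  expect_true(grepl("^[GC]+$", gc1$sequence))

  big <- make_genome(1e5, gc = 0.41, seed = 4)
  obs <- sum(strsplit(big$sequence, "")[[1]] %in% c("G", "C"))
  sd3 <- 3 * sqrt(1e5 * 0.41 * 0.59)
  expect_lt(abs(obs - 1e5 * 0.41), sd3)

  expect_error(make_genome(100, gc = 1.2, seed = 1), "gc")
  expect_error(make_genome(0, seed = 1))
})

test_that("haplotypes carry reconstructable variant logs at the right rate", {
  base <- make_genome(1e5, seed = 5)
  none <- make_haplotypes(base, 3, snp_rate = 0, indel_rate = 0, seed = 6)
  for (h in none) expect_identical(h$sequence, base$sequence)

  haps <- make_haplotypes(base, 5, snp_rate = 0.001, indel_rate = 0,
                          seed = 7)
  sd3 <- 3 * sqrt(1e5 * 0.001 * 0.999)
  for (h in haps) {
    n_snp <- nrow(h$variant_log)
    expect_lt(abs(n_snp - 100), sd3)
    expect_identical(apply_variants(base$sequence, h$variant_log),
                     h$sequence)
    expect_equal(h$parent, base$id)
  }

  with_indels <- make_haplotypes(base, 2, snp_rate = 5e-4,
                                 indel_rate = 2e-4, seed = 8)
  for (h in with_indels) {
    expect_identical(apply_variants(base$sequence, h$variant_log),
                     h$sequence)
    expect_false(nchar(h$sequence) == 0)
  }
})

test_that("error-free reads are exact substrings of their genome", {
  g <- make_genome(8000, seed = 9)
  spec <- mixture_spec(n_reads = 30, error_rate = 0, seed = 10)
  reads <- simulate_reads(g, 30, spec)
  both <- paste(g$sequence, revcomp(g$sequence), sep = "#")
  for (i in seq_len(30)) {
    expect_true(grepl(reads$seq1[i], both, fixed = TRUE))
    expect_true(grepl(reads$seq2[i], both, fixed = TRUE))
  }
  expect_equal(nrow(simulate_reads(g, 0, spec)), 0L)
  short <- make_genome(200, seed = 11)
  expect_error(simulate_reads(short, 5, spec), "too short")
})

test_that("substitution errors appear at the configured rate", {
  g <- make_genome(8000, seed = 12)
  spec <- mixture_spec(n_reads = 400, error_rate = 0.01, seed = 13)
  reads <- simulate_reads(g, 400, spec)
  pl <- reads_placements(reads)
  mism <- 0L
  for (i in seq_len(nrow(pl))) {
    src <- substr(g$sequence, pl$start[i], pl$end[i])
    mism <- mism + sum(strsplit(pl$seq[i], "")[[1]] !=
                         strsplit(src, "")[[1]])
  }
  bases <- sum(nchar(pl$seq))
  sd3 <- 3 * sqrt(bases * 0.01 * 0.99)
  expect_lt(abs(mism - bases * 0.01), sd3)
})

test_that("placements locate every error-free read on its genome", {
  g <- make_genome(6000, seed = 14)
  spec <- mixture_spec(n_reads = 50, error_rate = 0, seed = 15)
  reads <- simulate_reads(g, 50, spec)
  pl <- reads_placements(reads)
  expect_equal(nrow(pl), 100L) # both mates
  for (i in seq_len(nrow(pl))) {
    expect_identical(pl$seq[i], substr(g$sequence, pl$start[i], pl$end[i]))
  }
})

test_that("mixtures are balanced, shuffled and reproducible", {
  base <- make_genome(5000, seed = 16)
  haps <- make_haplotypes(base, 3, seed = 17)
  mics <- lapply(1:3, function(i) {
    make_genome(5000, gc = 0.5, seed = 18 + i, id = paste0("m", i),
                kind = "microbial")
  })
  spec <- mixture_spec(n_reads = 1000, seed = 20)
  mix <- make_mixture(haps, mics, spec)
  expect_equal(sum(mix$truth$origin == "human"), 500L)
  expect_equal(sum(mix$truth$origin == "microbial"), 500L)
  expect_identical(make_mixture(haps, mics, spec)$pairs$read_id,
                   mix$pairs$read_id)

  allm <- make_mixture(haps, mics,
                       mixture_spec(n_reads = 100, frac_human = 0,
                                    seed = 21))
  expect_true(all(allm$truth$origin == "microbial"))
})

test_that("holdout_references excludes exactly the simulation genomes", {
  base <- make_genome(1000, seed = 22)
  haps <- make_haplotypes(base, 12, seed = 23)
  all_g <- c(list(base), haps)
  kept <- holdout_references(all_g, vapply(haps[1:10], `[[`, "", "id"))
  expect_equal(length(kept), 3L) # base + 2 held-in haplotypes
  expect_true(base$id %in% vapply(kept, `[[`, "", "id"))
  expect_identical(holdout_references(all_g, character()), all_g)
  expect_error(holdout_references(all_g,
                                  vapply(all_g, `[[`, "", "id")),
               "empty")
  expect_error(holdout_references(all_g, "nonexistent"), "not present")
})

test_that("benchmark counts follow set arithmetic and conserve labels", {
  truth <- data.frame(read_id = sprintf("r%02d", 1:20),
                      origin = rep(c("human", "microbial"), each = 10),
                      source_genome = "g")
  perfect <- benchmark_filtration(truth$read_id[11:20], truth)
  expect_equal(perfect$human_remaining, 0L)
  expect_equal(perfect$microbial_lost, 0L)
  passthrough <- benchmark_filtration(truth$read_id, truth)
  expect_equal(passthrough$human_remaining, 10L)
  expect_equal(passthrough$microbial_lost, 0L)
  some <- benchmark_filtration(truth$read_id[c(1:3, 11:14)], truth)
  expect_equal(some$human_remaining, 3L)
  expect_equal(some$microbial_lost, 6L)
  expect_equal(some$human_remaining + some$human_removed, some$total_human)
  expect_equal(some$microbial_remaining + some$microbial_lost,
               some$total_microbial)
  expect_error(benchmark_filtration("zz", truth), "not in truth")
})

test_that("coverage profile flags a sharp peak with low breadth", {
  whole <- coverage_profile(data.frame(start = 1L, end = 10000L), 10000L)
  expect_equal(whole$breadth, 1)
  expect_equal(whole$peak_ratio, 1)
  expect_false(whole$artifact)

  none <- coverage_profile(data.frame(start = integer(), end = integer()),
                           10000L)
  expect_equal(none$breadth, 0)
  expect_equal(none$mean_depth, 0)
  expect_true(is.na(none$artifact))

  stack <- coverage_profile(
    data.frame(start = rep(5001L, 1000), end = rep(5150L, 1000)), 1e6L)
  expect_equal(stack$breadth, 150 / 1e6)
  expect_gt(stack$peak_ratio, 10)
  expect_true(stack$artifact)

  expect_error(coverage_profile(data.frame(start = 0L, end = 10L), 100L),
               "invalid interval")
})

test_that("panel simulation respects HWE frequencies and donor haplotypes", {
  base <- make_genome(20000, seed = 24)
  panel <- simulate_genotype_panel(base, n_samples = 200, n_sites = 150,
                                   seed = 25)
  expect_equal(dim(panel$genotypes), c(150L, 200L))
  expect_true(all(panel$sites$ref ==
                    substring(base$sequence, panel$sites$pos,
                              panel$sites$pos)))
  # observed allele frequencies track the generating p
  obs <- rowMeans(panel$genotypes) / 2
  expect_lt(max(abs(obs - panel$sites$p)), 4 * sqrt(0.25 / (2 * 200)) + 0.05)

  dh <- donor_haplotypes(panel, base, donor = 1, seed = 26)
  g <- panel$genotypes[, 1]
  a1 <- substring(dh[[1]]$sequence, panel$sites$pos, panel$sites$pos)
  a2 <- substring(dh[[2]]$sequence, panel$sites$pos, panel$sites$pos)
  dose <- (a1 == panel$sites$alt) + (a2 == panel$sites$alt)
  expect_equal(as.integer(dose), as.integer(g))
})
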