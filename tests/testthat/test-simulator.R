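test_that("synthetic mitogenomes have the canonical layout and intact ORFs", {
  g <- fx_genome()
  expect_equal(nchar(g$sequence), 16500L)
  expect_true(g$circular)
  expect_equal(nrow(g$genes), 37L)
  expect_equal(sum(g$genes$gene_class == "CDS"), 13L)
  expect_equal(sum(g$genes$gene_class == "rRNA"), 2L)
  expect_equal(sum(g$genes$gene_class == "tRNA"), 22L)
  # genes non-overlapping
  ord <- order(g$genes$start)
  expect_true(all(g$genes$start[ord][-1] >= g$genes$end[ord][-37]))
  # every CDS translates without internal stops under the mitochondrial code
  cds <- g$genes[g$genes$gene_class == "CDS", ]
  for (i in seq_len(nrow(cds))) {
    s <- substr(g$sequence, cds$start[i] + 1L, cds$end[i])
    if (cds$strand[i] == "-") s <- revcomp(s)
    aa <- translate_mito(s)
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1L)))
  }
  # determinism
  expect_identical(build_mitogenome(42)$sequence, g$sequence)
  expect_identical(build_mitogenome(42)$genes, g$genes)
  expect_error(build_mitogenome(1, length = 11000), ">= 12000")
})

test_that("CDS use mitochondrial-specific codons that break the standard code", {
  # translate each CDS with the standard nuclear code: TGA (Trp in the
  # mitochondrial code) and AGA/AGG (mitochondrial stops) should betray at
  # least one gene for some seed
  std <- Biostrings::getGeneticCode("1")
  found_broken <- FALSE
  for (seed in 1:10) {
    g <- build_mitogenome(seed)
    cds <- g$genes[g$genes$gene_class == "CDS", ]
    for (i in seq_len(nrow(cds))) {
      s <- substr(g$sequence, cds$start[i] + 1L, cds$end[i])
      if (cds$strand[i] == "-") s <- revcomp(s)
      codons <- mitoskim:::split_codons(s)
      aa <- unname(std[codons])
      internal_stop <- any(aa[-length(aa)] == "*")
      bad_start <- aa[1] != "M"
      if (internal_stop || bad_start) found_broken <- TRUE
    }
    if (found_broken) break
  }
  expect_true(found_broken)
})

test_that("mutate_genome hits the requested divergence and keeps ORFs", {
  g <- fx_genome()
  expect_identical(mutate_genome(g, 0, seed = 1)$sequence, g$sequence)
  m <- mutate_genome(g, 0.02, seed = 5)
  # count raw mismatches (coordinates are preserved under substitution-only)
  a <- strsplit(g$sequence, "")[[1]]
  b <- strsplit(m$sequence, "")[[1]]
  ident <- 100 * mean(a == b)
  expect_lt(abs(ident - 98), 0.3)
  expect_length(mitoskim:::broken_cds_positions(m$sequence, m$genes), 0L)
  # two independent 2% processes compose to ~96% mutual identity
  m2 <- mutate_genome(g, 0.02, seed = 6)
  b2 <- strsplit(m2$sequence, "")[[1]]
  expect_lt(abs(100 * mean(b == b2) - 96), 0.6)
  expect_error(mutate_genome(g, 0.5, seed = 1), "divergence")
})

test_that("simulated runs respect yield, length and origin accounting", {
  run <- fx_skim_run(seed = 77, yield = 1e6, mt_fraction = 0.02)
  reads <- run$reads
  cfg_yield <- 1e6
  expect_gte(yield_bases(reads), cfg_yield)
  expect_lt(yield_bases(reads), cfg_yield + max(nchar(reads$sequence)))
  expect_equal(nrow(run$truth), nrow(reads))
  expect_true(all(run$truth$origin %in% c("mitochondrial", "nuclear")))
  # determinism: same config + seed give byte-identical output
  rerun <- fx_memo("skim-rerun", {
    cfg <- sim_config(seed = 77, target_yield = 1e6, mean_read_length = 2000,
                      mt_fraction = 0.02, per_base_error = 0.05)
    simulate_run(fx_genome(), fx_pool(), cfg)
  })
  expect_identical(rerun$reads$sequence, reads$sequence)
  expect_identical(rerun$reads$quality, reads$quality)
})

test_that("mitochondrial base fraction tracks the configured mt_fraction", {
  # short reads so the binomial count (n ~ 10,000, p = 0.004) has enough
  # power for a +/- 25% relative check on the base fraction
  cfg <- sim_config(seed = 7, target_yield = 5e6, mean_read_length = 500,
                    read_length_sigma = 0.3, mt_fraction = 0.004,
                    per_base_error = 0.02, min_read_length = 100)
  run <- simulate_run(fx_genome(), fx_pool(), cfg)
  mt <- run$truth$origin == "mitochondrial"
  frac <- sum(nchar(run$reads$sequence[mt])) / yield_bases(run$reads)
  expect_lt(abs(frac - 0.004) / 0.004, 0.25)
  # the read count itself sits inside a 99.9% binomial band
  n <- nrow(run$reads)
  ci <- stats::qbinom(c(5e-4, 1 - 5e-4), n, 0.004)
  expect_gte(sum(mt), ci[1])
  expect_lte(sum(mt), ci[2])
})

test_that("error-free reads are exact substrings of their source", {
  g <- fx_genome()
  cfg <- sim_config(seed = 13, target_yield = 2e5, mean_read_length = 1500,
                    mt_fraction = 0.5, per_base_error = 0)
  run <- simulate_run(g, fx_pool(), cfg)
  g2 <- paste0(g$sequence, g$sequence)
  pool <- fx_pool()
  for (i in seq_len(nrow(run$reads))) {
    tr <- run$truth[i, ]
    src <- if (tr$origin == "mitochondrial") g2 else pool[[tr$source_id]]
    expected <- substr(src, tr$start + 1L, tr$end)
    if (tr$strand == "-") expected <- revcomp(expected)
    expect_identical(run$reads$sequence[i], expected)
  }
})

test_that("a desk-scaled emulation reproduces the target mean read length", {
  # regime of a ~921 Mbp flongle run with 3.97 kbp mean reads, yield
  # scaled down 1/100
  cfg <- sim_config(seed = 21, target_yield = 9.21e6, mean_read_length = 3970,
                    mt_fraction = 9e-4, per_base_error = 0.05)
  run <- simulate_run(fx_genome(), fx_pool(), cfg)
  expect_lt(abs(mean_read_length(run$reads) - 3970) / 3970, 0.10)
})

test_that("observed per-base error rate matches the configured rate", {
  g <- fx_genome()
  cfg <- sim_config(seed = 15, target_yield = 3e5, mean_read_length = 2500,
                    mt_fraction = 0.999, per_base_error = 0.05)
  run <- simulate_run(g, fx_pool(), cfg)
  expect_gte(nrow(run$reads), 100)
  g2 <- paste0(g$sequence, g$sequence)
  bad <- 0; cols <- 0
  for (i in seq_len(min(nrow(run$reads), 120))) {
    tr <- run$truth[i, ]
    src <- substr(g2, tr$start + 1L, tr$end)
    if (tr$strand == "-") src <- revcomp(src)
    a <- mitoskim:::cpp_align(run$reads$sequence[i], src, 0, 150, 1, -4, 1, 2,
                              alignment = FALSE)
    bad <- bad + a$mismatches + a$gap_cols
    cols <- cols + a$cols
  }
  expect_lt(abs(bad / cols - 0.05) / 0.05, 0.10)
})

test_that("mitochondrial read starts are uniform on the circle", {
  g <- fx_genome()
  cfg <- sim_config(seed = 17, target_yield = 1.3e6, mean_read_length = 550,
                    read_length_sigma = 0.2, mt_fraction = 0.999,
                    per_base_error = 0, min_read_length = 100)
  run <- simulate_run(g, fx_pool(), cfg)
  starts <- run$truth$start[run$truth$origin == "mitochondrial"]
  expect_gte(length(starts), 2000)
  starts <- starts[seq_len(2000)]
  bins <- table(cut(starts, breaks = seq(0, 16500, length.out = 21),
                    include.lowest = TRUE))
  p <- stats::chisq.test(as.vector(bins))$p.value
  expect_gt(p, 0.01)
})

test_that("a run expected to contain no mitochondrial reads records a warning", {
  cfg <- sim_config(seed = 19, target_yield = 2e5, mean_read_length = 2000,
                    mt_fraction = 1e-4, per_base_error = 0.02)
  run <- simulate_run(fx_genome(), fx_pool(), cfg)
  expect_match(attr(run$reads, "warnings"), "fewer than one|< 1")
})

test_that("invalid simulation configurations are rejected", {
  expect_error(sim_config(error_split = c(sub = 0.5, ins = 0.2, del = 0.2)),
               "sum to 1")
  expect_error(sim_config(per_base_error = 0.7), "per_base_error")
  expect_error(sim_config(mt_fraction = 0), "mt_fraction")
  expect_error(simulate_run(fx_genome(), "ACGT", sim_config()), "10x")
})
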