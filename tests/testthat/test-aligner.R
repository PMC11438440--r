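test_that("seed finding is exhaustive and strand-symmetric", {
  s <- find_seeds("ACGTACGTACGTA", "ACGTACGTACGTA", 11)
  plus <- s[s$strand == "+", ]
  expect_equal(plus$qpos, 0:2)
  expect_equal(plus$spos, 0:2)
  # a query's reverse complement yields the same words on the minus strand
  rc <- revcomp("ACGTACGTACGTA")
  s2 <- find_seeds(rc, "ACGTACGTACGTA", 11)
  expect_equal(nrow(s2[s2$strand == "-", ]), 3L)
  # too-short sequences yield an empty list
  expect_equal(nrow(find_seeds("ACGT", "ACGTACGTACGT", 11)), 0L)
  # N never matches
  expect_equal(nrow(find_seeds("ACGTNACGTACGTA", strrep("ACGTN", 10), 5)), 0L)
})

test_that("random seed counts match the closed-form expectation", {
  withr::with_seed(99, {
    subject <- random_seq(16500)
    # 10,000 random 12-mers, joined with N spacers so no cross-boundary
    # words form; expected seeds per query over both strands:
    # 2 * (16500 - 10) * (1/4)^11 = 7.86e-3
    kmers <- vapply(1:10000, function(i) random_seq(12), "")
    query <- paste(kmers, collapse = "NNN")
    seeds <- find_seeds(query, subject, 11)
    lambda <- 10000 * 2 * (2 * (16500 - 10)) * 0.25^11
    # each 12-mer holds 2 candidate 11-mer starts; Poisson band +/- 5 sd
    expect_gt(nrow(seeds), lambda - 5 * sqrt(lambda))
    expect_lt(nrow(seeds), lambda + 5 * sqrt(lambda))
  })
})

test_that("seed extension reproduces forced scoring arithmetic", {
  withr::with_seed(3, {
    q <- random_seq(200)
    hit <- extend_seed(q, q, list(qpos = 0, spos = 0, strand = "+"))
    expect_equal(hit$score, 200)
    expect_equal(hit$pident, 100)
    expect_equal(hit$length, 200)

    # one mismatch in 100: score = 99 - 4 = 95, identity 99
    q2 <- random_seq(100)
    s2 <- q2
    mid <- substr(q2, 50, 50)
    substr(s2, 50, 50) <- setdiff(c("A", "C", "G", "T"), mid)[1]
    hit2 <- extend_seed(q2, s2, list(qpos = 0, spos = 0, strand = "+"))
    expect_equal(hit2$score, 95)
    expect_equal(hit2$pident, 99)
    expect_error(extend_seed(q2, s2, list(qpos = 0, spos = 0, strand = "+"),
                             band_width = 0), "band_width")
  })
})

test_that("full-band extension equals the brute-force affine local optimum", {
  withr::with_seed(11, {
    for (case in 1:60) {
      la <- sample(8:60, 1)
      lb <- sample(8:60, 1)
      a <- random_seq(la)
      b <- if (case %% 2 == 0) {
        paste0(substr(a, 1, min(la, lb)), random_seq(max(0, lb - la)))
      } else random_seq(lb)
      got <- mitoskim:::cpp_align(a, b, 0, la + lb, 1, -4, 1, 2)
      expect_equal(got$score, sw_oracle(a, b))
      # reported stats reconstruct the score exactly
      if (got$ok) {
        expect_equal(got$matches - 4 * got$mismatches -
                       (got$gap_opens + 2 * got$gap_cols), got$score)
      }
    }
  })
})

test_that("scores agree with an independent aligner on the same gap model", {
  withr::with_seed(12, {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -4)
    for (case in 1:15) {
      a <- random_seq(sample(30:60, 1))
      b <- paste0(substr(a, 5, 25), random_seq(20))
      ours <- mitoskim:::cpp_align(a, b, 0, 200, 1, -4, 1, 2)$score
      ref <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                           substitutionMatrix = mat,
                                           gapOpening = 1, gapExtension = 2,
                                           scoreOnly = TRUE)
      expect_equal(ours, max(ref, 0))
    }
  })
})

test_that("Karlin lambda solves the score-generating equation", {
  kp <- solve_karlin(scoring_scheme())
  expect_lt(abs(kp$lambda - karlin_lambda_oracle(1, -4)), 1e-6)
  # analytic case: +1/-1 uniform gives exp(lambda) = 3
  kp2 <- solve_karlin(scoring_scheme(penalty = -1))
  expect_equal(kp2$lambda, log(3), tolerance = 1e-9)
  # residual below 1e-9 by construction
  f <- 0.25 * exp(kp$lambda * 1) + 0.75 * exp(kp$lambda * -4) - 1
  expect_lt(abs(f), 1e-9)
  expect_error(solve_karlin(scoring_scheme(penalty = -1e-12)),
               "invalid scoring regime")
})

test_that("E-values follow E = K m n exp(-lambda S)", {
  kp <- solve_karlin(scoring_scheme())
  expect_equal(evalue(0, 100, 1000, kp), kp$K * 100 * 1000)
  expect_equal(evalue(50, 100, 2000, kp) / evalue(50, 100, 1000, kp), 2)
  expect_equal(evalue(95, 100, 1000, kp) / evalue(94, 100, 1000, kp),
               exp(-kp$lambda), tolerance = 1e-12)
})

test_that("search returns one best HSP per subject with identity filtering", {
  g <- fx_genome()
  read <- substr(g$sequence, 3001, 4000)
  rs <- read_set("r1", read, strrep("I", 1000))
  hits <- search_reads(rs, list(fx_genome()))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$pident, 100)
  expect_equal(hits$subject_id, g$record_id)
  expect_equal(hits$sstart, 3000)
  expect_error(search_reads(rs, list()), "empty database")
})

test_that("random reads produce no spurious hits at the 90% identity gate", {
  withr::with_seed(23, {
    panel <- fx_bundle()$panel
    reads <- read_set(paste0("rnd", 1:200),
                      vapply(1:200, function(i) random_seq(1000), ""),
                      rep(strrep("I", 1000), 200))
    hits <- search_reads(reads, panel, min_identity = 90, min_aligned = 100)
    expect_equal(nrow(hits), 0L)
    expect_length(attr(hits, "unassigned"), 200L)
  })
})

test_that("5%-error reads are recovered above the 90% cutoff", {
  reads <- fx_mito_reads(depth = 10)
  hits <- search_reads(reads, list(fx_genome()), min_identity = 90,
                       min_aligned = 100)
  recall <- length(unique(hits$query_id)) / nrow(reads)
  expect_gte(recall, 0.95)
})

test_that("search is strand-symmetric", {
  g <- fx_genome()
  withr::with_seed(31, {
    read <- substr(mutate_genome(g, 0.04, seed = 77)$sequence, 5001, 6500)
    fwd <- search_reads(read_set("r", read, strrep("I", nchar(read))), list(g))
    rev <- search_reads(read_set("r", revcomp(read), strrep("I", nchar(read))),
                        list(g))
    expect_equal(fwd$score, rev$score)
    expect_equal(fwd$pident, rev$pident)
    expect_equal(fwd$sstart, rev$sstart)
    expect_true(all(fwd$strand != rev$strand))
  })
})

test_that("e-value ordering matches score ordering at fixed lengths", {
  kp <- solve_karlin(scoring_scheme())
  scores <- c(300, 150, 120, 80, 40)
  ev <- evalue(scores, 1000, 1e6, kp)
  expect_equal(order(ev), order(-scores))
})

test_that("percent identity is bounded and exact only for gapless perfection", {
  reads <- fx_mito_reads(depth = 5)
  hits <- search_reads(reads, list(fx_genome()), min_identity = 50,
                       min_aligned = 50)
  expect_true(all(hits$pident <= 100))
  perfect <- hits$pident == 100
  expect_equal(perfect, hits$mismatch == 0 & hits$gap_cols == 0)
})
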