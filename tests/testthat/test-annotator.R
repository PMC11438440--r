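# helpers to build assemblies with known defects
perfect_assembly <- function(g = fx_genome()) {
  new_assembly(g$sequence, circular = TRUE, status = "assembled")
}

edit_codon <- function(sequence, gene, codon_index, to = "TAA") {
  # replace codon `codon_index` (1-based) of a + strand CDS
  at <- gene$start + 3L * (codon_index - 1L)
  paste0(substr(sequence, 1, at), to,
         substr(sequence, at + 4L, nchar(sequence)))
}

test_that("projection maps every gene of an identical assembly in place", {
  g <- fx_genome()
  proj <- project_annotation(perfect_assembly(), g)
  expect_true(all(proj$located))
  expect_equal(proj$start, g$genes$start)
  expect_equal(proj$end, g$genes$end)
})

test_that("a deletion spanning a tRNA leaves it unlocated and shifts the rest", {
  g <- fx_genome()
  # a 500-bp deletion starting just before the last tRNA and running into
  # the control region: exactly one gene falls inside it (the synthetic
  # layout leaves only a few spacer bases between internal genes)
  last_trna <- g$genes[g$genes$gene_class == "tRNA", ]
  last_trna <- last_trna[which.max(last_trna$start), ]
  from <- last_trna$start - 5L
  seqd <- paste0(substr(g$sequence, 1, from),
                 substr(g$sequence, from + 501L, nchar(g$sequence)))
  asm <- new_assembly(seqd, circular = TRUE, status = "assembled")
  proj <- project_annotation(asm, g)
  expect_false(proj$located[proj$gene_name == last_trna$gene_name])
  expect_equal(sum(proj$located), 36L)

  # an interior deletion covering one tRNA exactly: downstream genes shift
  tr <- g$genes[g$genes$gene_class == "tRNA", ][10, ]
  dlen <- (tr$end + 2L) - (tr$start - 2L)
  seqd2 <- paste0(substr(g$sequence, 1, tr$start - 2L),
                  substr(g$sequence, tr$start - 2L + dlen + 1L,
                         nchar(g$sequence)))
  asm2 <- new_assembly(seqd2, circular = TRUE, status = "assembled")
  proj2 <- project_annotation(asm2, g)
  expect_false(proj2$located[proj2$gene_name == tr$gene_name])
  expect_equal(sum(proj2$located), 36L)
  after <- proj2[proj2$located & proj2$ref_start > tr$end + 10L, ]
  expect_true(all(abs(after$start - (after$ref_start - dlen)) <= 2L))
})

test_that("2% substitution noise still locates all genes with small endpoint error", {
  g <- fx_genome()
  noisy <- mutate_genome(g, 0.02, seed = 91, record_id = "noisy")
  asm <- new_assembly(noisy$sequence, circular = TRUE, status = "assembled")
  proj <- project_annotation(asm, g)
  expect_true(all(proj$located))
  expect_true(all(abs(proj$start - proj$ref_start) <= 5L))
  expect_true(all(abs(proj$end - proj$ref_end) <= 5L))
})

test_that("overly divergent references are refused for projection", {
  g <- fx_genome()
  withr::with_seed(93, {
    stranger <- new_assembly(random_seq(16500), circular = TRUE,
                             status = "assembled")
    expect_error(assess_assembly(stranger, g, rotate = FALSE),
                 "cannot orient|too divergent")
  })
})

test_that("gene assessment classifies intact, stopped and frameshifted CDS", {
  g <- fx_genome()
  cds <- g$genes[g$genes$gene_name == "ND5", ]
  asm <- perfect_assembly()
  proj <- project_annotation(asm, g)
  nd5 <- proj[proj$gene_name == "ND5", ]
  expect_equal(assess_gene(asm, nd5)$status, "complete")

  # premature stop at codon 50
  stopped <- new_assembly(edit_codon(g$sequence, cds, 50L), circular = TRUE,
                          status = "assembled")
  proj2 <- project_annotation(stopped, g)
  expect_equal(assess_gene(stopped, proj2[proj2$gene_name == "ND5", ])$status,
               "stop_codon")

  # frameshifts (single-base deletion) are never complete
  withr::with_seed(95, {
    for (rep in 1:25) {
      at <- cds$start + 3L * 10L + sample(0:50, 1)
      fs_seq <- paste0(substr(g$sequence, 1, at),
                       substr(g$sequence, at + 2L, nchar(g$sequence)))
      fs <- new_assembly(fs_seq, circular = TRUE, status = "assembled")
      projf <- project_annotation(fs, g)
      status <- assess_gene(fs, projf[projf$gene_name == "ND5", ])$status
      expect_true(status %in% c("stop_codon", "incomplete"))
    }
  })
})

test_that("whole-assembly QC tallies the hit/error categories", {
  g <- fx_genome()
  q <- assess_assembly(perfect_assembly(), g, rotate = FALSE)
  expect_equal(q$summary$hit_count, 37L)
  expect_equal(q$summary$error_count, 0L)
  expect_equal(q$summary$complete_cds, 13L)

  # not_assembled inputs suppress gene categories
  q0 <- assess_assembly(new_assembly(NA_character_, status = "not_assembled"), g)
  expect_equal(q0$status, "not_assembled")
  expect_true(is.na(q0$summary$hit_count))
  expect_equal(nrow(q0$genes), 0L)
})

test_that("injected defects land in the right categories and partition the gene set", {
  g <- fx_genome()
  cds <- g$genes[g$genes$gene_class == "CDS", ]
  seqd <- g$sequence
  for (nm in c("ND1", "COII", "ND4")) {
    gene <- cds[cds$gene_name == nm, ]
    seqd <- edit_codon(seqd, gene, 40L)
  }
  # delete one tRNA entirely
  tr <- g$genes[g$genes$gene_class == "tRNA", ][5, ]
  seqd <- paste0(substr(seqd, 1, tr$start - 10L),
                 substr(seqd, tr$end + 11L, nchar(seqd)))
  asm <- new_assembly(seqd, circular = TRUE, status = "assembled")
  q <- assess_assembly(asm, g, rotate = FALSE)
  expect_equal(q$summary$stop_codon, 3L)
  expect_equal(q$summary$null, 1L)
  expect_equal(q$summary$hit_count, 33L)
  # category partition: statuses sum to the expected gene count
  expect_equal(nrow(q$genes), 37L)
  expect_equal(q$summary$hit_count + q$summary$error_count, 37L)
  # monotone degradation: more stops never increase the hit count
  seqd2 <- edit_codon(seqd, cds[cds$gene_name == "ND2", ], 30L)
  q2 <- assess_assembly(new_assembly(seqd2, circular = TRUE,
                                     status = "assembled"), g, rotate = FALSE)
  expect_lte(q2$summary$hit_count, q$summary$hit_count)
  # pure function: same assembly assessed twice is identical
  q3 <- assess_assembly(asm, g, rotate = FALSE)
  expect_identical(q$summary, q3$summary)
  expect_identical(q$genes, q3$genes)
})

test_that("markers are extracted only with intact reading frames", {
  g <- fx_genome()
  asm <- perfect_assembly()
  cytb_len <- with(g$genes[g$genes$gene_name == "CYTB", ], end - start)
  mk <- extract_marker(asm, g, "CYTB", rotate = FALSE)
  expect_true(mk$accepted)
  expect_equal(nchar(mk$sequence), cytb_len)
  coi <- extract_marker(asm, g, "COI", rotate = FALSE)
  expect_true(coi$accepted)

  # premature stop in CYTB -> rejection carrying the failing status
  cytb <- g$genes[g$genes$gene_name == "CYTB", ]
  broken <- new_assembly(edit_codon(g$sequence, cytb, 60L), circular = TRUE,
                         status = "assembled")
  mk2 <- extract_marker(broken, g, "CYTB", rotate = FALSE)
  expect_false(mk2$accepted)
  expect_equal(mk2$status, "stop_codon")

  # marker absent from the reference annotation is a parameter error
  bare <- g
  bare$genes <- g$genes[g$genes$gene_name != "CYTB", ]
  expect_error(extract_marker(asm, bare, "CYTB"), "absent")

  # not_assembled input is a rejection, not an error
  mk3 <- extract_marker(new_assembly(NA_character_, status = "not_assembled"),
                        g, "COI")
  expect_false(mk3$accepted)
})

test_that("noisy consensus assemblies keep genes assessable end to end", {
  g <- fx_genome()
  reads <- fx_mito_reads(depth = 30)
  asm <- assemble_reference_guided(reads, fx_close_ref())
  q <- assess_assembly(asm, fx_close_ref())
  expect_equal(q$status, "assembled")
  expect_gte(q$summary$hit_count, 33L)
})
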