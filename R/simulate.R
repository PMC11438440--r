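# Synthetic annotated mitogenomes and ONT-like genome-skim runs with known
# truth. The simulator emulates the statistical regime of low-output Flongle
# runs: log-normal read lengths, ~5% per-base error split over substitutions,
# insertions and deletions (R9-like), a small mitochondrial base fraction,
# and a per-read Q-score distribution tuned to a target Q>=7 pass fraction.

#' Simulation configuration
#'
#' @param seed integer seed; every stochastic stage derives from it.
#' @param target_yield total bases to simulate.
#' @param mean_read_length mean read length in bases.
#' @param read_length_sigma sigma of the log-normal length distribution
#'   (default 0.70, which puts the 99th percentile near 4x the mean).
#' @param per_base_error total per-base error rate in `[0, 0.5]` (default
#'   0.05, the R9-chemistry regime).
#' @param error_split proportions of substitution/insertion/deletion error;
#'   must sum to 1 (default 55/25/20, a typical R9 profile).
#' @param mt_fraction expected fraction of sequenced bases of mitochondrial
#'   origin (default 5e-4; real skims range roughly 1e-4 to 4e-3).
#' @param q_pass_fraction expected fraction of reads with mean Q >= 7
#'   (default 0.82).
#' @param min_read_length shortest read emitted.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, target_yield = 5e6,
                       mean_read_length = 3970, read_length_sigma = 0.70,
                       per_base_error = 0.05,
                       error_split = c(sub = 0.55, ins = 0.25, del = 0.20),
                       mt_fraction = 5e-4, q_pass_fraction = 0.82,
                       min_read_length = 200L) {
  if (abs(sum(error_split) - 1) > 1e-8) abort("error_split must sum to 1")
  if (per_base_error < 0 || per_base_error > 0.5) {
    abort("per_base_error must be in [0, 0.5]")
  }
  if (mt_fraction <= 0 || mt_fraction >= 1) abort("mt_fraction must be in (0, 1)")
  structure(list(seed = as.integer(seed), target_yield = target_yield,
                 mean_read_length = mean_read_length,
                 read_length_sigma = read_length_sigma,
                 per_base_error = per_base_error,
                 error_split = error_split, mt_fraction = mt_fraction,
                 q_pass_fraction = q_pass_fraction,
                 min_read_length = as.integer(min_read_length)),
            class = "sim_config")
}

random_dna <- function(n, gc = 0.40) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# one random ORF under the vertebrate mitochondrial code: valid start, no
# internal stop, terminal stop; internal codons include TGA (Trp in table 2)
random_orf <- function(n_codons) {
  all_codons <- as.vector(outer(as.vector(outer(DNA_BASES, DNA_BASES, paste0)),
                                DNA_BASES, paste0))
  internal <- setdiff(all_codons, MITO_STOP_CODONS)
  start <- sample(c("ATG", "ATA", "GTG"), 1, prob = c(0.5, 0.35, 0.15))
  body <- sample(internal, n_codons - 2L, replace = TRUE)
  stop <- sample(c("TAA", "TAG"), 1, prob = c(0.8, 0.2))
  paste(c(start, body, stop), collapse = "")
}

# canonical vertebrate gene complement: 13 CDS, 2 rRNA, 22 tRNA
mito_gene_layout <- function() {
  cds <- tibble(
    gene_name = c("ND1", "ND2", "COI", "COII", "ATP8", "ATP6", "COIII",
                  "ND3", "ND4L", "ND4", "ND5", "ND6", "CYTB"),
    gene_class = "CDS",
    length = c(957L, 1044L, 1545L, 684L, 168L, 681L, 784L, 348L, 297L,
               1380L, 1812L, 528L, 1140L),
    strand = c("+", "+", "+", "+", "+", "+", "+", "+", "+", "+", "+", "-", "+"))
  cds$length <- cds$length - cds$length %% 3L
  rrna <- tibble(gene_name = c("12S", "16S"), gene_class = "rRNA",
                 length = c(950L, 1560L), strand = "+")
  trna_aa <- c("Phe", "Val", "Leu", "Ile", "Gln", "Met", "Trp", "Ala", "Asn",
               "Cys", "Tyr", "Ser", "Asp", "Lys", "Gly", "Arg", "His", "Ser2",
               "Leu2", "Glu", "Thr", "Pro")
  trna <- tibble(gene_name = paste0("tRNA-", trna_aa), gene_class = "tRNA",
                 length = 70L,
                 strand = rep(c("+", "-"), length.out = 22L))
  # interleave tRNAs between the larger genes, roughly the vertebrate order
  big <- bind_rows(rrna[1, ], trna[3, ], rrna[2, ], cds[1, ], trna[4:6, ],
                   cds[2, ], trna[7:11, ], cds[3, ], trna[12:13, ],
                   cds[c(4:5, 6:7), ], trna[14:15, ], cds[8:10, ],
                   trna[16:18, ], cds[11:12, ], trna[19:20, ], cds[13, ],
                   trna[21:22, ])
  bind_rows(trna[1:2, ], big)
}

#' Build a synthetic annotated mitogenome
#'
#' Generates a circular record with a canonical vertebrate-like layout:
#' 13 protein-coding genes (each a valid open reading frame under the
#' vertebrate mitochondrial code), 2 rRNAs, 22 tRNAs and a control region
#' filling the remaining length. Genes do not overlap. Deterministic under
#' `seed`.
#'
#' @param seed integer seed.
#' @param length genome length in bases (>= 12000; default 16500).
#' @param lineage lineage passed to [reference_record()].
#' @param record_id record identifier.
#' @param gene_layout optional layout tibble (`gene_name`, `gene_class`,
#'   `length`, `strand`); defaults to the canonical 37-gene complement.
#' @return a circular, annotated `mito_reference`.
#' @export
build_mitogenome <- function(seed, length = 16500L,
                             lineage = c(species = "simulus exemplaris",
                                         genus = "Simulus",
                                         family = "Simulidae",
                                         order = "Simuliformes",
                                         class = "Mammalia",
                                         phylum = "Chordata"),
                             record_id = "synthmito-1",
                             gene_layout = NULL) {
  if (length < 12000L) abort("mitogenome length must be >= 12000")
  layout <- gene_layout %||% mito_gene_layout()
  withr::with_seed(as.integer(seed), {
    n_genes <- nrow(layout)
    spacer_len <- sample(2:20, n_genes, replace = TRUE)
    need <- sum(layout$length) + sum(spacer_len)
    if (need + 200L > length) abort("gene layout does not fit in requested length")
    pieces <- character(2L * n_genes + 1L)
    genes <- layout
    genes$start <- NA_integer_
    genes$end <- NA_integer_
    pos <- 0L
    for (i in seq_len(n_genes)) {
      sp <- random_dna(spacer_len[i])
      gseq <- if (layout$gene_class[i] == "CDS") {
        random_orf(layout$length[i] %/% 3L)
      } else random_dna(layout$length[i], gc = 0.42)
      if (layout$strand[i] == "-") gseq <- cpp_revcomp(gseq)
      pieces[2L * i - 1L] <- sp
      pieces[2L * i] <- gseq
      pos <- pos + spacer_len[i]
      genes$start[i] <- pos
      pos <- pos + nchar(gseq)
      genes$end[i] <- pos
    }
    pieces[2L * n_genes + 1L] <- random_dna(length - pos)  # control region
    seqn <- paste(pieces, collapse = "")
    reference_record(record_id, seqn, circular = TRUE, lineage = lineage,
                     genes = genes[, c("gene_name", "gene_class", "start",
                                       "end", "strand")])
  })
}

# 1-based genome positions of the codons that break a CDS reading frame
# (internal stop, invalid start, invalid terminal stop). Only the breaking
# codons are reported - reverting a whole gene would leave long genes
# systematically unmutated.
broken_cds_positions <- function(sequence, genes) {
  cds <- genes[genes$gene_class == "CDS", , drop = FALSE]
  bad <- integer()
  for (i in seq_len(nrow(cds))) {
    g <- substr(sequence, cds$start[i] + 1L, cds$end[i])
    if (cds$strand[i] == "-") g <- cpp_revcomp(g)
    codons <- split_codons(g)
    n <- length(codons)
    bad_codon <- codons %in% MITO_STOP_CODONS
    bad_codon[n] <- !(codons[n] %in% MITO_STOP_CODONS)
    if (!(codons[1] %in% MITO_START_CODONS)) bad_codon[1] <- TRUE
    idx <- which(bad_codon)
    if (length(idx) == 0L) next
    # map codon indices (gene orientation) to genome positions
    offs <- as.vector(vapply(idx, function(j) (3L * (j - 1L) + 1L):(3L * j),
                             integer(3)))
    pos <- if (cds$strand[i] == "+") cds$start[i] + offs
           else cds$end[i] - offs + 1L
    bad <- c(bad, pos)
  }
  bad
}

#' Mutate a genome to a given divergence
#'
#' Places substitutions uniformly at the requested rate while keeping every
#' annotated open reading frame intact: substitutions that would create a
#' premature stop or break a start/stop codon are redrawn at another
#' position, so the substitution count is preserved. Annotation carries over
#' unchanged. Small indels, restricted to intergenic sequence, are optional.
#'
#' @param genome a `mito_reference`.
#' @param divergence substitution fraction in `[0, 0.2]`.
#' @param seed integer seed.
#' @param lineage optional replacement lineage for the derived record.
#' @param record_id identifier of the derived record.
#' @param intergenic_indels number of 1-5 bp indels to place outside genes.
#' @return a new `mito_reference`.
#' @export
mutate_genome <- function(genome, divergence, seed, lineage = NULL,
                          record_id = paste0(genome$record_id, "-mut"),
                          intergenic_indels = 0L) {
  if (divergence < 0 || divergence > 0.2) abort("divergence must be in [0, 0.2]")
  withr::with_seed(as.integer(seed), {
    chars <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]
    len <- length(chars)
    n_sub <- round(divergence * len)
    if (n_sub > 0L) {
      pos <- sample.int(len, n_sub)
      sub_base <- function(b) sample(setdiff(DNA_BASES, b), 1L)
      chars[pos] <- vapply(chars[pos], sub_base, character(1))
      # redraw any substitution that breaks a CDS reading frame
      orig <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]
      for (iter in 1:12) {
        bad <- broken_cds_positions(paste(chars, collapse = ""), genome$genes)
        hit <- intersect(pos, bad)
        if (length(hit) == 0L) break
        chars[hit] <- orig[hit]
        pos <- setdiff(pos, hit)
        fresh <- sample(setdiff(seq_len(len), c(pos, bad)), length(hit))
        chars[fresh] <- vapply(chars[fresh], sub_base, character(1))
        pos <- c(pos, fresh)
      }
      # if redraws have not settled, revert the stragglers outright
      bad <- broken_cds_positions(paste(chars, collapse = ""), genome$genes)
      hit <- intersect(pos, bad)
      if (length(hit)) {
        chars[hit] <- orig[hit]
        pos <- setdiff(pos, hit)
      }
    }
    seqn <- paste(chars, collapse = "")
    genes <- genome$genes
    if (intergenic_indels > 0L) {
      in_gene <- rep(FALSE, len)
      for (i in seq_len(nrow(genes))) {
        in_gene[seq(genes$start[i] + 1L, min(genes$end[i], len))] <- TRUE
      }
      free <- which(!in_gene)
      spots <- sort(sample(free, min(intergenic_indels, length(free))))
      offset <- 0L
      for (p in spots) {
        k <- sample(1:5, 1L)
        at <- p + offset
        if (runif(1) < 0.5) {  # insertion after position at
          seqn <- paste0(substr(seqn, 1L, at), random_dna(k),
                         substr(seqn, at + 1L, nchar(seqn)))
          genes$start <- genes$start + ifelse(genes$start >= at, k, 0L)
          genes$end <- genes$end + ifelse(genes$end > at, k, 0L)
          offset <- offset + k
        } else {               # deletion of up to k bases after at
          k <- min(k, nchar(seqn) - at)
          seqn <- paste0(substr(seqn, 1L, at), substr(seqn, at + k + 1L, nchar(seqn)))
          genes$start <- genes$start - ifelse(genes$start >= at + k, k, 0L)
          genes$end <- genes$end - ifelse(genes$end > at + k, k, 0L)
          offset <- offset - k
        }
      }
    }
    reference_record(record_id, seqn, circular = genome$circular,
                     lineage = lineage %||% genome$lineage, genes = genes)
  })
}

#' Pairwise identity between two equal-role genomes
#'
#' Convenience wrapper: full banded alignment identity (percent).
#' @param a,b DNA strings or `mito_reference`s.
#' @return percent identity of the best local alignment.
#' @export
pairwise_identity <- function(a, b) {
  sa <- if (inherits(a, "mito_reference")) a$sequence else a
  sb <- if (inherits(b, "mito_reference")) b$sequence else b
  res <- cpp_align(sa, sb, 0, max(300L, abs(nchar(sa) - nchar(sb)) + 150L),
                   1, -4, 1, 2, alignment = FALSE)
  if (!res$ok) return(0)
  100 * res$matches / res$cols
}

# vectorized per-read error process: substitution / insertion / deletion
apply_read_errors <- function(seqs, per_base_error, split) {
  if (per_base_error <= 0) return(seqs)
  p_sub <- per_base_error * split[["sub"]]
  p_ins <- per_base_error * split[["ins"]]
  p_del <- per_base_error * split[["del"]]
  vapply(seqs, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    n <- length(chars)
    r <- runif(n)
    sub_i <- which(r < p_sub)
    del_i <- which(r >= p_sub & r < p_sub + p_del)
    ins_i <- which(r >= p_sub + p_del & r < p_sub + p_del + p_ins)
    if (length(sub_i)) {
      shift <- sample.int(3L, length(sub_i), replace = TRUE)
      code <- match(chars[sub_i], DNA_BASES)
      code[is.na(code)] <- 1L
      chars[sub_i] <- DNA_BASES[((code - 1L + shift) %% 4L) + 1L]
    }
    reps <- rep(1L, n)
    reps[del_i] <- 0L
    reps[ins_i] <- 2L
    out <- rep(chars, reps)
    if (length(ins_i)) {
      at <- cumsum(reps)[ins_i]  # the duplicated copy becomes the insert
      out[at] <- sample(DNA_BASES, length(ins_i), replace = TRUE)
    }
    paste(out, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate an ONT-like genome-skim run
#'
#' Draws reads until the cumulative yield reaches `config$target_yield`.
#' Each read's origin is mitochondrial with probability `mt_fraction`
#' (read lengths are origin-independent, so the expected mitochondrial base
#' fraction equals `mt_fraction`); start positions are uniform, wrapping
#' across the circular origin for mitochondrial reads; strands are uniform;
#' lengths are log-normal; errors are applied per base by the configured
#' substitution/insertion/deletion split; per-read qualities are drawn so
#' the expected Q>=7 pass fraction matches `q_pass_fraction`. Deterministic
#' under `config$seed`.
#'
#' @param mito a circular `mito_reference` (the sample's true mitogenome).
#' @param nuclear_pool character vector of nuclear background sequences.
#' @param config a [sim_config()].
#' @param run_id run identifier.
#' @return list with `reads` (a `mito_reads` tibble) and `truth` (tibble:
#'   `read_id, origin, source_id, start, end, strand`). A run expected to
#'   contain fewer than one mitochondrial read records a warning in
#'   `attr(reads, "warnings")`.
#' @export
simulate_run <- function(mito, nuclear_pool, config = sim_config(),
                         run_id = "simrun-1") {
  stopifnot(inherits(mito, "mito_reference"), isTRUE(mito$circular))
  pool_len <- nchar(nuclear_pool)
  if (sum(pool_len) < 10 * config$mean_read_length) {
    abort("nuclear_pool total length must be >= 10x mean read length")
  }
  warnings <- character()
  exp_mt_reads <- config$mt_fraction * config$target_yield / config$mean_read_length
  if (exp_mt_reads < 1) {
    warnings <- c(warnings, sprintf(
      "expected mitochondrial reads < 1 (%.2f); run may contain none", exp_mt_reads))
  }
  L <- nchar(mito$sequence)
  mito2 <- paste0(mito$sequence, mito$sequence)
  sigma <- config$read_length_sigma
  mu <- log(config$mean_read_length) - sigma^2 / 2
  mu_q <- 6.5 + 2.5 * qnorm(config$q_pass_fraction)

  withr::with_seed(config$seed, {
    n_est <- ceiling(config$target_yield / config$mean_read_length * 1.4) + 10L
    lens <- pmax(config$min_read_length, round(rlnorm(n_est, mu, sigma)))
    while (sum(lens) < config$target_yield) {
      lens <- c(lens, pmax(config$min_read_length, round(rlnorm(n_est, mu, sigma))))
    }
    n <- which(cumsum(as.numeric(lens)) >= config$target_yield)[1]
    lens <- lens[seq_len(n)]
    origin <- ifelse(runif(n) < config$mt_fraction, "mitochondrial", "nuclear")
    strand <- ifelse(runif(n) < 0.5, "+", "-")
    src_id <- character(n)
    start <- integer(n)
    seqs <- character(n)
    is_mt <- origin == "mitochondrial"
    # mitochondrial reads: uniform start on the circle, wrap via doubling
    if (any(is_mt)) {
      ml <- pmin(lens[is_mt], L)  # at most one full pass around the circle
      ms <- sample.int(L, sum(is_mt), replace = TRUE) - 1L
      seqs[is_mt] <- substring(mito2, ms + 1L, ms + ml)
      lens[is_mt] <- ml
      start[is_mt] <- ms
      src_id[is_mt] <- mito$record_id
    }
    if (any(!is_mt)) {
      idx <- sample.int(length(nuclear_pool), sum(!is_mt), replace = TRUE,
                        prob = pool_len)
      nl <- pmin(lens[!is_mt], pool_len[idx])
      ns <- floor(runif(sum(!is_mt)) * (pool_len[idx] - nl + 1L))
      seqs[!is_mt] <- substring(nuclear_pool[idx], ns + 1L, ns + nl)
      lens[!is_mt] <- nl
      start[!is_mt] <- ns
      src_id[!is_mt] <- if (!is.null(names(nuclear_pool))) {
        names(nuclear_pool)[idx]
      } else paste0("nuclear-", idx)
    }
    flip <- strand == "-"
    seqs[flip] <- vapply(seqs[flip], cpp_revcomp, character(1), USE.NAMES = FALSE)
    seqs <- apply_read_errors(seqs, config$per_base_error, config$error_split)
    q <- pmin(41L, pmax(1L, round(rnorm(n, mu_q, 2.5))))
    qual <- strrep(vapply(q + 33L, intToUtf8, character(1)), nchar(seqs))
    ids <- sprintf("%s_read%06d", run_id, seq_len(n))
    reads <- read_set(ids, seqs, qual, run_id = run_id)
    attr(reads, "warnings") <- warnings
    truth <- tibble(read_id = ids, origin = origin, source_id = src_id,
                    start = start, end = start + lens, strand = strand)
    list(reads = reads, truth = truth)
  })
}

#' Generate a nuclear background pool
#'
#' Random sequence at 40% GC, optionally carrying a NUMT: a copy of a
#' mitochondrial segment embedded in one pool sequence, to exercise false
#' mitochondrial recruitment.
#'
#' @param n number of pool sequences.
#' @param length length of each.
#' @param seed integer seed.
#' @param numt_from optional `mito_reference` to copy a NUMT segment from.
#' @param numt_length NUMT segment length.
#' @return named character vector of sequences.
#' @export
make_nuclear_pool <- function(n = 5L, length = 2e5, seed = 1L,
                              numt_from = NULL, numt_length = 4000L) {
  withr::with_seed(as.integer(seed), {
    pool <- vapply(seq_len(n), function(i) random_dna(length), character(1))
    names(pool) <- paste0("nuc-", seq_len(n))
    if (!is.null(numt_from)) {
      seg_start <- sample.int(nchar(numt_from$sequence) - numt_length, 1L)
      seg <- substr(numt_from$sequence, seg_start, seg_start + numt_length - 1L)
      at <- sample.int(length - numt_length, 1L)
      pool[1] <- paste0(substr(pool[1], 1L, at), seg,
                        substr(pool[1], at + numt_length + 1L, length))
      names(pool)[1] <- "nuc-1-numt"
    }
    pool
  })
}

#' Write the per-read truth table
#' @param truth truth tibble from [simulate_run()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  readr::write_tsv(truth, path, progress = FALSE)
  invisible(path)
}
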