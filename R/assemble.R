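# Mitogenome reconstruction from recruited or whole-run reads.
#
# Two strategies: reference-guided pileup consensus (reads aligned to the
# doubled circular reference, per-column weighted majority over
# substitutions and length-changing edits, reference retained at
# zero-coverage columns) and a minimal de novo overlap-layout-consensus
# assembler (k-mer-multiplicity read recruitment, greedy end extension,
# pileup consensus, end-overlap circularity detection). Polishing is
# iterative consensus re-estimation to a fixed point.

#' Construct an assembly object
#'
#' @param sequence contig sequence (`NA` when not assembled).
#' @param circular is the contig circular?
#' @param data_type provenance: `WGS`, `panel-filtered` or
#'   `reference-filtered`.
#' @param assembler provenance: `reference_guided` or `de_novo`.
#' @param polish_rounds consensus re-estimation rounds applied.
#' @param status `assembled` or `not_assembled`.
#' @param origin_offset rotation applied by [rotate_canonical()].
#' @param depth per-base read depth (integer vector) or `NULL`.
#' @param low_coverage logical vector flagging zero-coverage columns.
#' @return a `mito_assembly` object.
#' @export
new_assembly <- function(sequence, circular = FALSE, data_type = "WGS",
                         assembler = "reference_guided", polish_rounds = 0L,
                         status = c("assembled", "not_assembled"),
                         origin_offset = 0L, depth = NULL,
                         low_coverage = NULL) {
  status <- match.arg(status)
  data_type <- match.arg(data_type, c("WGS", "panel-filtered", "reference-filtered"))
  assembler <- match.arg(assembler, c("reference_guided", "de_novo"))
  structure(list(sequence = sequence, circular = isTRUE(circular),
                 origin_offset = as.integer(origin_offset),
                 provenance = list(data_type = data_type, assembler = assembler,
                                   polish_rounds = as.integer(polish_rounds)),
                 status = status, depth = depth, low_coverage = low_coverage),
            class = "mito_assembly")
}

#' @export
print.mito_assembly <- function(x, ...) {
  p <- x$provenance
  if (x$status == "not_assembled") {
    cat(sprintf("<mito_assembly> not assembled (%s x %s)\n", p$data_type,
                p$assembler))
  } else {
    cat(sprintf("<mito_assembly> %d bp%s, %s x %s, %d polish round(s), mean depth %.1fX\n",
                nchar(x$sequence), if (x$circular) " circular" else "",
                p$data_type, p$assembler, p$polish_rounds,
                if (is.null(x$depth)) NA_real_ else mean(x$depth)))
  }
  invisible(x)
}

#' @export
glance.mito_assembly <- function(x, ...) {
  tibble(status = x$status,
         length = if (x$status == "assembled") nchar(x$sequence) else NA_integer_,
         circular = x$circular,
         data_type = x$provenance$data_type,
         assembler = x$provenance$assembler,
         polish_rounds = x$provenance$polish_rounds,
         mean_depth = if (is.null(x$depth)) NA_real_ else mean(x$depth),
         origin_offset = x$origin_offset)
}

# shared pileup wrapper
pileup <- function(template, circular, reads, scheme = scoring_scheme(),
                   min_pident = 72, min_cols = 100L, band = 150L,
                   min_score = 30, consensus = TRUE) {
  seqs <- if (is.data.frame(reads)) reads$sequence else as.character(reads)
  cpp_pileup(template, circular, seqs, scheme$word_size, as.integer(band),
             scheme$min_cluster_seeds, scheme$reward, scheme$penalty,
             scheme$gap_open, scheme$gap_extend, min_score, min_pident,
             as.integer(min_cols), consensus)
}

#' Reference-guided assembly (pileup consensus)
#'
#' Aligns reads to the doubled circular reference and takes a per-column
#' consensus over the read pileup: weighted majority over substitutions,
#' deletions, and insertions supported by more than half of the covering
#' reads. Zero-coverage columns retain the reference base and are flagged
#' low-coverage (the reference-bias failure mode of guided assembly).
#' Succeeds whenever at least one read aligns.
#'
#' @param reads a `mito_reads` tibble.
#' @param reference a circular annotated `mito_reference` from the closest
#'   available relative.
#' @param data_type provenance label.
#' @param min_pident minimum read-to-reference identity for inclusion in the
#'   pileup (permissive, mapping-style).
#' @param min_cols minimum aligned columns per included read.
#' @param band alignment band half-width.
#' @param scheme a [scoring_scheme()].
#' @return a `mito_assembly`; `status = "not_assembled"` when zero reads
#'   align.
#' @export
assemble_reference_guided <- function(reads, reference, data_type = "WGS",
                                      min_pident = 72, min_cols = 100L,
                                      band = 150L, scheme = scoring_scheme()) {
  stopifnot(inherits(reference, "mito_reference"), isTRUE(reference$circular))
  pl <- if (nrow(reads) > 0) {
    pileup(reference$sequence, TRUE, reads, scheme, min_pident, min_cols, band)
  } else NULL
  if (is.null(pl) || sum(pl$aligned) == 0L) {
    return(new_assembly(NA_character_, circular = TRUE, data_type = data_type,
                        assembler = "reference_guided", status = "not_assembled"))
  }
  new_assembly(pl$consensus, circular = TRUE, data_type = data_type,
               assembler = "reference_guided", status = "assembled",
               depth = pl$depth, low_coverage = pl$low_coverage)
}

#' Minimal de novo overlap assembly
#'
#' Candidate mitochondrial reads are recruited by k-mer multiplicity (the
#' high-copy component of a skim), laid out by greedy end extension along
#' best overlaps, and polished by pileup consensus. Circularity is declared
#' when the contig ends overlap by at least `min_circular_overlap` at
#' `>= circular_identity` percent identity, and the duplication is trimmed.
#' The assembly is declared `not_assembled` when no contig reaches
#' `min_length_frac * expected_length` or the mean depth is below
#' `min_mean_depth` - a failure that is reported, never silent.
#'
#' @param reads a `mito_reads` tibble (whole-run or filtered).
#' @param data_type provenance label.
#' @param expected_length expected genome length (bases).
#' @param min_length_frac minimum contig length as a fraction of
#'   `expected_length`.
#' @param min_mean_depth minimum mean depth for a successful assembly.
#' @param kmer k-mer size for multiplicity recruitment.
#' @param min_kmer_mult minimum median k-mer multiplicity of a candidate
#'   read.
#' @param min_overlap minimum read-contig overlap for layout extension.
#' @param overlap_identity minimum percent identity of a layout overlap
#'   (two 5%-error reads align near 90%).
#' @param min_circular_overlap,circular_identity end-overlap thresholds for
#'   declaring circularity.
#' @param band alignment band half-width.
#' @param scheme a [scoring_scheme()].
#' @return a `mito_assembly`.
#' @export
assemble_de_novo <- function(reads, data_type = "WGS",
                             expected_length = 16500L, min_length_frac = 0.8,
                             min_mean_depth = 3, kmer = 16L,
                             min_kmer_mult = 3, min_overlap = 300L,
                             overlap_identity = 80, min_circular_overlap = 1000L,
                             circular_identity = 90, band = 150L,
                             scheme = scoring_scheme()) {
  failed <- function() new_assembly(NA_character_, data_type = data_type,
                                    assembler = "de_novo",
                                    status = "not_assembled")
  if (nrow(reads) == 0L) return(failed())
  scores <- cpp_kmer_read_scores(reads$sequence, as.integer(kmer))
  cand <- which(scores >= min_kmer_mult & nchar(reads$sequence) >= min_overlap)
  if (length(cand) < 2L) return(failed())
  seqs <- reads$sequence[cand]
  ord <- order(nchar(seqs), decreasing = TRUE)
  seqs <- seqs[ord]
  contig <- seqs[1]
  placed <- rep(FALSE, length(seqs))
  placed[1] <- TRUE
  max_len <- expected_length * 1.6 + 2 * mean(nchar(seqs))
  # greedy layout: sweep the unplaced reads, extending the contig in place;
  # a read overlapping a contig end contributes its overhang, a read fully
  # contained is retired. A few passes settle the layout.
  for (pass in 1:6) {
    changed <- FALSE
    for (ri in which(!placed)) {
      if (nchar(contig) > max_len) break
      res <- cpp_search(seqs[ri], contig, FALSE, scheme$word_size,
                        as.integer(band), scheme$min_cluster_seeds, 3L,
                        scheme$reward, scheme$penalty, scheme$gap_open,
                        scheme$gap_extend, 30)
      if (length(res$query) == 0L) next
      pid <- 100 * res$matches[1] / res$cols[1]
      if (pid < overlap_identity || res$cols[1] < min_overlap) next
      clen <- nchar(contig)
      qlen <- nchar(seqs[ri])
      oriented <- if (res$strand[1] == "-") cpp_revcomp(seqs[ri]) else seqs[ri]
      # oriented read coordinates (q coords are reported on the original read)
      oqs <- if (res$strand[1] == "-") qlen - res$qend[1] else res$qstart[1]
      oqe <- if (res$strand[1] == "-") qlen - res$qstart[1] else res$qend[1]
      right_ext <- if (res$send[1] >= clen - 20L) qlen - oqe else 0L
      left_ext <- if (res$sstart[1] <= 20L) oqs else 0L
      if (right_ext <= 20L && left_ext <= 20L) {
        placed[ri] <- TRUE  # contained
      } else if (right_ext >= left_ext) {
        contig <- paste0(contig, substr(oriented, oqe + 1L, nchar(oriented)))
        placed[ri] <- TRUE
        changed <- TRUE
      } else {
        contig <- paste0(substr(oriented, 1L, oqs), contig)
        placed[ri] <- TRUE
        changed <- TRUE
      }
    }
    if (!changed || nchar(contig) > max_len) break
  }
  # consensus over the layout
  cand_reads <- reads[cand, , drop = FALSE]
  for (round in 1:2) {
    pl <- pileup(contig, FALSE, cand_reads, scheme,
                 min_pident = overlap_identity, min_cols = min_overlap,
                 band = band)
    if (sum(pl$aligned) == 0L) return(failed())
    contig <- pl$consensus
  }
  # circularity: does the contig start re-occur near the end?
  circular <- FALSE
  if (nchar(contig) > expected_length * 0.9) {
    probe_len <- min(4000L, nchar(contig) %/% 3L)
    tail_from <- max(probe_len + 1L, nchar(contig) - expected_length %/% 2L -
                       2L * probe_len)
    tail_seq <- substr(contig, tail_from, nchar(contig))
    dup <- cpp_search(substr(contig, 1L, probe_len), tail_seq, FALSE,
                      scheme$word_size, as.integer(band),
                      scheme$min_cluster_seeds, 3L, scheme$reward,
                      scheme$penalty, scheme$gap_open, scheme$gap_extend, 30)
    if (length(dup$query) == 1L) {
      pid <- 100 * dup$matches / dup$cols
      if (dup$strand == "+" && pid >= circular_identity &&
          dup$cols >= min_circular_overlap) {
        cut <- (tail_from - 1L) + dup$sstart - dup$qstart
        if (cut > expected_length * min_length_frac) {
          contig <- substr(contig, 1L, cut)
          circular <- TRUE
        }
      }
    }
  }
  pl <- pileup(contig, circular, cand_reads, scheme,
               min_pident = overlap_identity, min_cols = min_overlap,
               band = band)
  if (sum(pl$aligned) == 0L) return(failed())
  contig <- pl$consensus
  depth <- pl$depth
  if (nchar(contig) < min_length_frac * expected_length ||
      mean(depth) < min_mean_depth) {
    return(failed())
  }
  new_assembly(contig, circular = circular, data_type = data_type,
               assembler = "de_novo", status = "assembled", depth = depth,
               low_coverage = pl$low_coverage)
}

#' Polish an assembly by consensus re-estimation
#'
#' Re-aligns the reads to the current contig and recomputes the pileup
#' consensus, iterating up to `rounds` times or until a fixed point (no base
#' changes). Deterministic.
#'
#' @param assembly an assembled `mito_assembly`.
#' @param reads the reads to polish with.
#' @param rounds maximum consensus rounds.
#' @param min_pident,min_cols,band pileup inclusion parameters.
#' @param scheme a [scoring_scheme()].
#' @return the polished `mito_assembly` with `polish_rounds` incremented by
#'   the number of rounds actually run.
#' @export
polish <- function(assembly, reads, rounds = 1L, min_pident = 72,
                   min_cols = 100L, band = 150L, scheme = scoring_scheme()) {
  if (assembly$status != "assembled") {
    abort("cannot polish a not_assembled assembly")
  }
  done <- 0L
  for (r in seq_len(rounds)) {
    pl <- pileup(assembly$sequence, assembly$circular, reads, scheme,
                 min_pident, min_cols, band)
    done <- done + 1L
    changed <- !identical(pl$consensus, assembly$sequence)
    assembly$sequence <- pl$consensus
    assembly$depth <- pl$depth
    assembly$low_coverage <- pl$low_coverage
    if (!changed) break
  }
  assembly$provenance$polish_rounds <- assembly$provenance$polish_rounds + done
  assembly
}

#' Rotate a circular assembly to the canonical origin
#'
#' Rotates (and reverse-complements if needed) the contig so that position 0
#' aligns to reference position 0 on the plus strand. The rotation applied
#' is recorded in `origin_offset`.
#'
#' @param assembly a circular, assembled `mito_assembly`.
#' @param reference the `mito_reference` defining the origin.
#' @param scheme a [scoring_scheme()].
#' @param band alignment band half-width.
#' @return the rotated `mito_assembly`.
#' @export
rotate_canonical <- function(assembly, reference, scheme = scoring_scheme(),
                             band = 150L) {
  stopifnot(inherits(assembly, "mito_assembly"))
  if (assembly$status != "assembled") abort("cannot orient: not assembled")
  if (!assembly$circular) abort("rotate_canonical needs a circular assembly")
  probe <- substr(reference$sequence, 1L, min(1500L, nchar(reference$sequence)))
  res <- cpp_search(probe, assembly$sequence, TRUE, scheme$word_size,
                    as.integer(band), scheme$min_cluster_seeds, 3L,
                    scheme$reward, scheme$penalty, scheme$gap_open,
                    scheme$gap_extend, 30)
  if (length(res$query) == 0L) abort("cannot orient: no alignment to reference")
  seqn <- assembly$sequence
  L <- nchar(seqn)
  if (res$strand[1] == "-") {
    seqn <- cpp_revcomp(seqn)
    # re-locate the probe on the flipped contig
    res <- cpp_search(probe, seqn, TRUE, scheme$word_size, as.integer(band),
                      scheme$min_cluster_seeds, 3L, scheme$reward,
                      scheme$penalty, scheme$gap_open, scheme$gap_extend, 30)
    if (length(res$query) == 0L || res$strand[1] == "-") {
      abort("cannot orient: no alignment to reference")
    }
  }
  offset <- (res$sstart[1] - res$qstart[1]) %% L
  if (offset > 0L) {
    seqn <- paste0(substr(seqn, offset + 1L, L), substr(seqn, 1L, offset))
  }
  assembly$sequence <- seqn
  assembly$origin_offset <- as.integer(offset)
  if (!is.null(assembly$depth) && offset > 0L) {
    idx <- c((offset + 1L):L, seq_len(offset))
    if (length(assembly$depth) == L) assembly$depth <- assembly$depth[idx]
    if (!is.null(assembly$low_coverage) && length(assembly$low_coverage) == L) {
      assembly$low_coverage <- assembly$low_coverage[idx]
    }
  }
  assembly
}

#' Per-base depth profile of an assembly
#'
#' @param assembly an assembled `mito_assembly`.
#' @param reads the reads to profile with.
#' @param min_pident,min_cols,band pileup inclusion parameters.
#' @param scheme a [scoring_scheme()].
#' @return a `depth_profile` tibble (`position` 0-based, `depth`), with
#'   `mean_depth` as an attribute.
#' @export
depth_profile <- function(assembly, reads, min_pident = 72, min_cols = 100L,
                          band = 150L, scheme = scoring_scheme()) {
  if (assembly$status != "assembled") abort("assembly is not assembled")
  pl <- if (nrow(reads) > 0) {
    pileup(assembly$sequence, assembly$circular, reads, scheme, min_pident,
           min_cols, band, consensus = FALSE)
  } else list(depth = rep(0L, nchar(assembly$sequence)))
  out <- tibble(position = seq_along(pl$depth) - 1L, depth = pl$depth)
  attr(out, "mean_depth") <- mean(pl$depth)
  class(out) <- c("depth_profile", class(out))
  out
}

#' Mean depth of a depth profile
#' @param profile a [depth_profile()] tibble.
#' @return mean reads covering a base (X units).
#' @export
mean_depth <- function(profile) attr(profile, "mean_depth") %||% mean(profile$depth)
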