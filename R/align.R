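# Seeded, gapped local alignment with blastn-style scoring and
# Karlin-Altschul E-values. The scoring defaults mirror the routine blastn
# parameter set for noisy-long-read searches: reward +1, penalty -4,
# gapopen 1, gapextend 2 (a length-L gap costs 1 + 2L), word size 11,
# one HSP per subject.

#' Alignment scoring scheme
#'
#' @param reward match score (> 0).
#' @param penalty mismatch score (< 0).
#' @param gap_open,gap_extend gap costs (>= 0); a gap of length L costs
#'   `gap_open + L * gap_extend`.
#' @param word_size exact-match seed length (>= 4).
#' @param max_hsps HSPs kept per query/subject pair (fixed best-HSP
#'   behaviour; 1).
#' @param max_target_seqs subjects reported per query in a scoped search.
#' @param band half-width of the banded extension around the seed diagonal.
#' @param min_cluster_seeds seeds that must co-occur on a diagonal band
#'   before extension is attempted.
#' @return a `scoring_scheme` list.
#' @export
scoring_scheme <- function(reward = 1, penalty = -4, gap_open = 1,
                           gap_extend = 2, word_size = 11L, max_hsps = 1L,
                           max_target_seqs = 1L, band = 50L,
                           min_cluster_seeds = 3L) {
  if (!(reward > 0 && penalty < 0)) abort("need reward > 0 > penalty")
  if (gap_open < 0 || gap_extend < 0) abort("gap costs must be >= 0")
  if (word_size < 4) abort("word_size must be >= 4")
  structure(list(reward = reward, penalty = penalty, gap_open = gap_open,
                 gap_extend = gap_extend, word_size = as.integer(word_size),
                 max_hsps = as.integer(max_hsps),
                 max_target_seqs = as.integer(max_target_seqs),
                 band = as.integer(band),
                 min_cluster_seeds = as.integer(min_cluster_seeds)),
            class = "scoring_scheme")
}

#' Exact-match seeds between two sequences
#'
#' Exhaustively enumerates `word_size`-mers shared between query and subject
#' on both strands; `N` never matches. For minus-strand seeds, `qpos` is the
#' 0-based start, on the original query, of the word whose reverse complement
#' matches the subject at `spos`.
#'
#' @param query,subject DNA strings.
#' @param word_size seed length.
#' @return tibble with `qpos`, `spos` (0-based) and `strand`.
#' @export
find_seeds <- function(query, subject, word_size = 11L) {
  as_tibble(cpp_find_seeds(query, subject, as.integer(word_size)))
}

hit_tibble <- function(query_id, subject_id, aln, strand,
                       qlen = NA_integer_, slen = NA_integer_) {
  cols <- aln$cols
  tibble(query_id = query_id, subject_id = subject_id,
         score = aln$score,
         evalue = NA_real_,
         pident = if (cols > 0) 100 * aln$matches / cols else NA_real_,
         length = cols, mismatch = aln$mismatches,
         gapopen = aln$gap_opens, gap_cols = aln$gap_cols,
         qstart = aln$qstart, qend = aln$qend,
         sstart = aln$sstart, send = aln$send,
         strand = strand, qlen = qlen, slen = slen)
}

#' Extend a seed into a gapped local alignment
#'
#' Banded affine-cost local alignment around the seed diagonal. The returned
#' hit is the maximal-scoring local alignment found in the band; with
#' `full_band = TRUE` the band covers the entire matrix and the result is the
#' exact local-alignment optimum.
#'
#' @param query,subject DNA strings.
#' @param seed one row of [find_seeds()] output (or a list with `qpos`,
#'   `spos`, `strand`).
#' @param scheme a [scoring_scheme()].
#' @param band_width band half-width (>= 1).
#' @param full_band if `TRUE`, use an unrestricted band.
#' @param score_floor hits scoring below this are not reported.
#' @return a one-row hits tibble, or `NULL` if nothing reaches `score_floor`.
#' @export
extend_seed <- function(query, subject, seed, scheme = scoring_scheme(),
                        band_width = scheme$band, full_band = FALSE,
                        score_floor = 20) {
  if (!full_band && band_width < 1) abort("band_width must be >= 1")
  qlen <- nchar(query)
  strand <- as.character(seed$strand)
  q <- if (strand == "-") cpp_revcomp(query) else query
  qpos <- if (strand == "-") qlen - scheme$word_size - seed$qpos else seed$qpos
  diag <- seed$spos - qpos
  band <- if (full_band) qlen + nchar(subject) else as.integer(band_width)
  a <- cpp_align(q, subject, diag, band, scheme$reward, scheme$penalty,
                 scheme$gap_open, scheme$gap_extend, alignment = FALSE)
  if (!a$ok || a$score < score_floor) return(NULL)
  if (strand == "-") {
    qs <- qlen - a$qend
    a$qend <- qlen - a$qstart
    a$qstart <- qs
  }
  hit_tibble("query", "subject", a, strand, qlen, nchar(subject))
}

#' Karlin-Altschul parameters for a scoring scheme
#'
#' `lambda` is the unique positive root of
#' `sum_ij p_i p_j exp(lambda * s_ij) = 1` under the background base
#' composition; it exists only when the expected per-column score is
#' negative. `K` defaults to the documented constant 0.46; the E-value is
#' used as a monotone ranking statistic, so its absolute calibration is not
#' attempted.
#'
#' @param scheme a [scoring_scheme()].
#' @param composition background base frequencies (A, C, G, T); must sum to 1.
#' @param K prefactor constant.
#' @return a `karlin_params` list with `lambda`, `K`, `composition`.
#' @export
solve_karlin <- function(scheme = scoring_scheme(),
                         composition = rep(0.25, 4), K = 0.46) {
  if (abs(sum(composition) - 1) > 1e-8) abort("composition must sum to 1")
  p_match <- sum(composition^2)
  exp_score <- p_match * scheme$reward + (1 - p_match) * scheme$penalty
  if (exp_score >= 0) abort("invalid scoring regime: expected score must be negative")
  f <- function(lambda) {
    p_match * exp(lambda * scheme$reward) +
      (1 - p_match) * exp(lambda * scheme$penalty) - 1
  }
  # the root is below lambda_max where the match term alone reaches 1
  upper <- log(1 / p_match) / scheme$reward + 1
  root <- uniroot(f, c(1e-9, upper), tol = 1e-12)$root
  stopifnot(abs(f(root)) < 1e-9)
  structure(list(lambda = root, K = K, composition = composition),
            class = "karlin_params")
}

#' Karlin-Altschul E-value
#'
#' `E = K * m * n * exp(-lambda * S)`: the expected number of local
#' alignments scoring at least `S` between random sequences of the compared
#' lengths.
#'
#' @param score alignment score (>= 0).
#' @param m query length.
#' @param n database (subject) length.
#' @param params a [solve_karlin()] result.
#' @return the expectation (numeric, > 0).
#' @export
evalue <- function(score, m, n, params) {
  stopifnot(all(score >= 0), all(m >= 1), all(n >= 1))
  params$K * m * n * exp(-params$lambda * score)
}

# normalize database-ish inputs for the C++ search
db_parts <- function(database) {
  seqs <- as_sequence_vector(database)
  if (length(seqs) == 0L) abort("empty database")
  list(ids = names(seqs), seqs = unname(seqs),
       circular = unname(as_circular_flags(database, length(seqs))))
}

#' Search reads against a reference database
#'
#' Seeded, banded local alignment of every read against every database
#' record (both strands; circular records are searched across the origin).
#' At most one HSP is kept per read/subject pair; hits are filtered to
#' `pident >= min_identity` and `length >= min_aligned` aligned columns.
#' Reads with no surviving hit are reported in `attr(, "unassigned")`.
#'
#' @param reads a `mito_reads` tibble (or named character vector of
#'   sequences).
#' @param database a `mito_refdb`, list of [reference_record()]s, or named
#'   character vector.
#' @param scheme a [scoring_scheme()].
#' @param min_identity minimum percent identity (default 90, the cutoff
#'   derived from 95% homology minus ~5% ONT error).
#' @param min_aligned minimum aligned columns (default 100; without a length
#'   floor, seed-sized matches would pass the identity gate).
#' @param karlin Karlin-Altschul parameters; computed from `scheme` if
#'   `NULL`.
#' @param min_score extension report floor in score units.
#' @return hits tibble (one row per read x subject), ordered by read input
#'   order then ascending E-value.
#' @export
search_reads <- function(reads, database, scheme = scoring_scheme(),
                         min_identity = 90, min_aligned = 100L,
                         karlin = NULL, min_score = 30) {
  db <- db_parts(database)
  qseq <- if (is.data.frame(reads)) reads$sequence else unname(as.character(reads))
  qids <- if (is.data.frame(reads)) reads$read_id else
    (names(reads) %||% paste0("read-", seq_along(qseq)))
  if (length(qseq) == 0L) {
    out <- tibble(query_id = character(), subject_id = character(),
                  score = numeric(), evalue = numeric(), pident = numeric(),
                  length = integer(), mismatch = integer(),
                  gapopen = integer(), gap_cols = integer(),
                  qstart = integer(), qend = integer(),
                  sstart = integer(), send = integer(), strand = character(),
                  qlen = integer(), slen = integer())
    attr(out, "unassigned") <- character()
    attr(out, "database_length") <- sum(as.numeric(nchar(db$seqs)))
    return(out)
  }
  karlin <- karlin %||% solve_karlin(scheme)
  res <- cpp_search(qseq, db$seqs, db$circular,
                    scheme$word_size, scheme$band, scheme$min_cluster_seeds,
                    3L, scheme$reward, scheme$penalty, scheme$gap_open,
                    scheme$gap_extend, min_score)
  hits <- tibble(query_id = qids[res$query],
                 subject_id = db$ids[res$subject],
                 score = res$score,
                 evalue = NA_real_,
                 pident = ifelse(res$cols > 0, 100 * res$matches / res$cols, NA_real_),
                 length = res$cols, mismatch = res$mismatches,
                 gapopen = res$gap_opens, gap_cols = res$gap_cols,
                 qstart = res$qstart, qend = res$qend,
                 sstart = res$sstart, send = res$send,
                 strand = res$strand,
                 qlen = nchar(qseq)[res$query],
                 slen = nchar(db$seqs)[res$subject])
  n_db <- sum(as.numeric(nchar(db$seqs)))
  hits$evalue <- evalue(hits$score, hits$qlen, n_db, karlin)
  hits <- hits[hits$pident >= min_identity & hits$length >= min_aligned, ,
               drop = FALSE]
  hits <- hits[order(match(hits$query_id, qids), hits$evalue, -hits$pident,
                     hits$subject_id), , drop = FALSE]
  attr(hits, "unassigned") <- setdiff(qids, hits$query_id)
  attr(hits, "database_length") <- n_db
  hits
}

#' Export hits as a BLAST outfmt-6 style TSV
#'
#' Column order mirrors tabular blastn output: qseqid, sseqid, pident,
#' length, mismatch, gapopen, qstart, qend, sstart, send, evalue, score.
#' Coordinates are written 1-based inclusive as in BLAST tabular output.
#'
#' @param hits a hits tibble from [search_reads()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_hits_tsv <- function(hits, path) {
  out <- tibble(qseqid = hits$query_id, sseqid = hits$subject_id,
                pident = round(hits$pident, 3), length = hits$length,
                mismatch = hits$mismatch, gapopen = hits$gapopen,
                qstart = hits$qstart + 1L, qend = hits$qend,
                sstart = hits$sstart + 1L, send = hits$send,
                evalue = hits$evalue, score = hits$score)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
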