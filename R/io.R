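# Core record types and readers/writers for the standard formats the
# pipeline touches: FASTQ reads (Phred+33), FASTA references, gene
# annotations (GFF3 or 6-column TSV) and the taxonomy lineage table.
#
# Coordinates are 0-based half-open on the + strand of the stored sequence
# everywhere internally; GFF3 I/O converts from 1-based inclusive.

LINEAGE_RANKS <- c("species", "genus", "family", "order", "class", "phylum")

#' Construct a read set
#'
#' A read set is a tibble with one row per read (`read_id`, `sequence`,
#' `quality`) plus run metadata. Qualities are Phred+33 strings of the same
#' length as the sequence.
#'
#' @param read_id,sequence,quality parallel character vectors.
#' @param run_id run identifier.
#' @param q_filtered `NULL`, or the Q-score threshold already applied.
#' @return a `mito_reads` tibble.
#' @export
read_set <- function(read_id = character(), sequence = character(),
                     quality = character(), run_id = NA_character_,
                     q_filtered = NULL) {
  stopifnot(length(read_id) == length(sequence),
            length(sequence) == length(quality))
  if (length(sequence)) {
    bad <- nchar(sequence) != nchar(quality)
    if (any(bad)) {
      abort(paste0("sequence/quality length mismatch for read(s): ",
                   paste(head(read_id[bad], 5), collapse = ", ")))
    }
    if (any(nchar(sequence) < 1L)) abort("reads must have length >= 1")
  }
  out <- tibble(read_id = as.character(read_id),
                sequence = toupper(as.character(sequence)),
                quality = as.character(quality))
  attr(out, "run_id") <- run_id
  attr(out, "q_filtered") <- q_filtered
  class(out) <- c("mito_reads", class(out))
  out
}

keep_reads_attrs <- function(new, old) {
  attr(new, "run_id") <- attr(old, "run_id")
  attr(new, "q_filtered") <- attr(old, "q_filtered")
  if (!inherits(new, "mito_reads")) class(new) <- c("mito_reads", class(new))
  new
}

#' Total bases in a read set
#' @param reads a `mito_reads` tibble.
#' @return total sequenced bases.
#' @export
yield_bases <- function(reads) {
  if (nrow(reads) == 0L) return(0)
  sum(as.numeric(nchar(reads$sequence)))
}

#' Mean read length of a read set
#' @inheritParams yield_bases
#' @return mean read length in bases (`NaN` for an empty set).
#' @export
mean_read_length <- function(reads) yield_bases(reads) / nrow(reads)

#' @export
glance.mito_reads <- function(x, ...) {
  qf <- attr(x, "q_filtered")
  tibble(run_id = attr(x, "run_id") %||% NA_character_,
         n_reads = nrow(x),
         yield_bases = yield_bases(x),
         mean_read_length = if (nrow(x)) mean_read_length(x) else NA_real_,
         q_filtered = !is.null(qf),
         q_threshold = if (is.null(qf)) NA_real_ else as.numeric(qf))
}

#' @export
print.mito_reads <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<mito_reads> run %s: %d reads, %.0f bases%s\n",
              g$run_id, g$n_reads, g$yield_bases,
              if (g$q_filtered) sprintf(", Q >= %g filtered", g$q_threshold) else ""))
  NextMethod()
}

#' Read a FASTQ file
#'
#' Accepts plain or gzip-compressed four-line FASTQ with Phred+33 qualities
#' (other encodings are rejected). An empty file yields an empty read set.
#'
#' @param path path to a FASTQ file.
#' @param run_id run identifier recorded on the read set (defaults to the
#'   file name).
#' @return a `mito_reads` tibble.
#' @export
read_fastq <- function(path, run_id = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[seq_len(max(which(lines != ""), 0L))]
  if (length(lines) == 0L) {
    return(read_set(run_id = run_id %||% basename(path)))
  }
  if (length(lines) %% 4L != 0L) {
    abort(paste0("malformed FASTQ (", path, "): ", length(lines),
                 " lines is not a multiple of 4; multi-line records are not supported"))
  }
  hdr <- lines[seq(1L, length(lines), 4L)]
  seq <- lines[seq(2L, length(lines), 4L)]
  plus <- lines[seq(3L, length(lines), 4L)]
  qual <- lines[seq(4L, length(lines), 4L)]
  if (any(substr(hdr, 1L, 1L) != "@") || any(substr(plus, 1L, 1L) != "+")) {
    bad <- which(substr(hdr, 1L, 1L) != "@" | substr(plus, 1L, 1L) != "+")[1]
    abort(paste0("malformed FASTQ record #", bad, " in ", path))
  }
  ids <- sub("\\s.*$", "", substring(hdr, 2L))
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad)) {
    abort(paste0("FASTQ parse error in ", path,
                 ": sequence/quality length mismatch for record(s): ",
                 paste(head(ids[bad], 5), collapse = ", ")))
  }
  qmin <- min(vapply(qual, function(q) min(utf8ToInt(q)), 1L))
  qmax <- max(vapply(qual, function(q) max(utf8ToInt(q)), 1L))
  if (qmin < 33L || qmax > 126L) {
    abort(paste0("quality characters outside the Phred+33 range in ", path,
                 "; only Phred+33 is supported"))
  }
  read_set(ids, seq, qual, run_id = run_id %||% basename(path))
}

#' Write a FASTQ file
#' @param reads a `mito_reads` tibble.
#' @param path output path (gzip if it ends in `.gz`).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (nrow(reads)) {
    writeLines(paste0("@", reads$read_id, "\n", reads$sequence, "\n+\n",
                      reads$quality), con, sep = "\n")
  }
  invisible(path)
}

#' Decode a Phred+33 quality string
#' @param quality character vector of quality strings.
#' @return list of integer vectors of per-base Phred scores.
#' @export
phred_decode <- function(quality) {
  lapply(quality, function(q) utf8ToInt(q) - 33L)
}

#' Mean Q-score of a read
#'
#' Aggregates per-base qualities the way ONT tooling does: the mean of the
#' per-base error probabilities `10^(-q/10)` converted back to the Phred
#' scale, `-10 log10(mean error)`.
#'
#' @param x a `mito_reads` tibble or a character vector of Phred+33 quality
#'   strings.
#' @return numeric vector of per-read mean Q-scores.
#' @export
mean_read_qscore <- function(x) {
  qual <- if (is.data.frame(x)) x$quality else as.character(x)
  if (length(qual) && any(nchar(qual) == 0L)) abort("reads must have length >= 1")
  cpp_mean_qscore(qual)
}

#' Filter reads by mean Q-score
#'
#' Retains exactly the reads whose mean Q-score (see [mean_read_qscore()]) is
#' greater than or equal to `min_q`; the boundary is inclusive. Input order is
#' preserved and the threshold is recorded on the result.
#'
#' @param reads a `mito_reads` tibble.
#' @param min_q minimum mean Q-score (default 7, the routine ONT cutoff).
#' @return the filtered `mito_reads` tibble.
#' @export
filter_by_qscore <- function(reads, min_q = 7) {
  # 1e-9 guard: the error-probability/Phred round trip can land a read of
  # constant quality q at q - 4e-16, which must not fail the inclusive cutoff
  keep <- if (nrow(reads)) mean_read_qscore(reads) >= min_q - 1e-9 else logical()
  out <- reads[keep, , drop = FALSE]
  out <- keep_reads_attrs(out, reads)
  attr(out, "q_filtered") <- min_q
  out
}

# ---------------------------------------------------------------------------
# References, annotations, taxonomy
# ---------------------------------------------------------------------------

#' Construct an annotated reference record
#'
#' @param record_id identifier.
#' @param sequence DNA string.
#' @param circular is the molecule circular?
#' @param lineage named character vector with at least `species` and `genus`;
#'   ranks from `species, genus, family, order, class, phylum`.
#' @param genes `NULL` or a tibble with columns `gene_name`, `gene_class`
#'   (`CDS`, `rRNA` or `tRNA`), `start`, `end` (0-based half-open), `strand`.
#' @return a `mito_reference` object.
#' @export
reference_record <- function(record_id, sequence, circular = FALSE,
                             lineage = c(species = NA_character_,
                                         genus = NA_character_),
                             genes = NULL) {
  sequence <- toupper(sequence)
  lin <- setNames(rep(NA_character_, length(LINEAGE_RANKS)), LINEAGE_RANKS)
  lin[names(lineage)] <- as.character(lineage)
  if (is.na(lin["species"]) || is.na(lin["genus"]) ||
      !nzchar(lin["species"]) || !nzchar(lin["genus"])) {
    abort(paste0("reference ", record_id, ": lineage must define species and genus"))
  }
  len <- nchar(sequence)
  if (!is.null(genes) && nrow(genes)) {
    genes <- as_tibble(genes)
    stopifnot(all(c("gene_name", "gene_class", "start", "end", "strand") %in%
                    names(genes)))
    if (!all(genes$gene_class %in% c("CDS", "rRNA", "tRNA"))) {
      abort("gene_class must be one of CDS, rRNA, tRNA")
    }
    over <- genes$end > len | genes$start < 0L
    if (any(over) && !circular) {
      abort(paste0("reference ", record_id, ": gene interval outside [0, ",
                   len, ") on a non-circular record: ",
                   paste(genes$gene_name[over], collapse = ", ")))
    }
    if (any(genes$end > 2L * len)) {
      abort(paste0("reference ", record_id, ": gene wraps more than once"))
    }
    if (any(genes$start >= genes$end)) {
      abort(paste0("reference ", record_id, ": empty gene interval"))
    }
  }
  structure(list(record_id = record_id, sequence = sequence,
                 circular = isTRUE(circular), lineage = lin,
                 genes = genes %||% tibble(gene_name = character(),
                                           gene_class = character(),
                                           start = integer(), end = integer(),
                                           strand = character())),
            class = "mito_reference")
}

#' @export
print.mito_reference <- function(x, ...) {
  cat(sprintf("<mito_reference> %s (%s %s): %d bp%s, %d genes\n",
              x$record_id, x$lineage["genus"], x$lineage["species"],
              nchar(x$sequence), if (x$circular) ", circular" else "",
              nrow(x$genes)))
  invisible(x)
}

#' Look up a lineage rank for a record
#'
#' @param taxonomy taxonomy tibble (`record_id` + lineage ranks).
#' @param record_id record to resolve.
#' @param rank one of `species, genus, family, order, class, phylum`.
#' @return the taxon name; undefined lookups are an error, never empty text.
#' @export
lineage_rank <- function(taxonomy, record_id, rank) {
  rank <- match.arg(rank, LINEAGE_RANKS)
  row <- taxonomy[taxonomy$record_id == record_id, , drop = FALSE]
  if (nrow(row) == 0L) abort(paste0("record not in taxonomy: ", record_id))
  val <- row[[rank]][1]
  if (is.na(val) || !nzchar(val)) {
    abort(paste0("rank '", rank, "' undefined for record ", record_id))
  }
  val
}

read_annotation_tsv <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("record_id", "gene_name", "gene_class", "start", "end", "strand")
  if (!all(need %in% names(ann))) {
    abort(paste0("annotation TSV must have columns: ", paste(need, collapse = ", ")))
  }
  ann
}

read_annotation_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("reading GFF3 requires the rtracklayer package; use the annotation TSV instead")
  }
  gr <- as.data.frame(rtracklayer::import(path, format = "gff3"))
  gr <- gr[gr$type %in% c("CDS", "rRNA", "tRNA"), , drop = FALSE]
  nm <- if (!is.null(gr$gene)) as.character(gr$gene) else as.character(gr$ID)
  tibble(record_id = as.character(gr$seqnames),
         gene_name = nm,
         gene_class = as.character(gr$type),
         start = gr$start - 1L,  # GFF3 1-based inclusive -> 0-based half-open
         end = gr$end,
         strand = as.character(gr$strand))
}

#' Load annotated references with taxonomy
#'
#' Reads a reference FASTA, a gene annotation (GFF3, or a 6-column TSV with
#' `record_id, gene_name, gene_class, start, end, strand` in 0-based
#' half-open coordinates) and a taxonomy TSV with header
#' `record_id, species, genus, family, order, class, phylum`. The taxonomy
#' table may carry an optional logical `circular` column; otherwise all
#' records take the `circular` argument.
#'
#' @param fasta path to the reference FASTA.
#' @param annotation path to the annotation (GFF3 or TSV), or `NULL`.
#' @param taxonomy path to the taxonomy TSV.
#' @param circular default circular flag for records without metadata.
#' @return a `mito_refdb`: list with `records` (named list of
#'   [reference_record()]s) and `taxonomy` (tibble).
#' @export
load_references <- function(fasta, annotation = NULL, taxonomy, circular = TRUE) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate record ids in ", fasta, ": ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  tax <- readr::read_tsv(taxonomy, show_col_types = FALSE, progress = FALSE)
  if (!all(c("record_id", LINEAGE_RANKS) %in% names(tax))) {
    abort("taxonomy TSV must have columns record_id, species, genus, family, order, class, phylum")
  }
  missing <- setdiff(ids, tax$record_id)
  if (length(missing)) {
    abort(paste0("records missing from taxonomy: ", paste(missing, collapse = ", ")))
  }
  ann <- NULL
  if (!is.null(annotation)) {
    ann <- if (grepl("\\.gff3?$", annotation)) read_annotation_gff3(annotation)
           else read_annotation_tsv(annotation)
  }
  records <- lapply(seq_along(ids), function(i) {
    id <- ids[i]
    trow <- tax[tax$record_id == id, , drop = FALSE][1, ]
    circ <- if ("circular" %in% names(tax)) isTRUE(as.logical(trow$circular)) else circular
    genes <- if (!is.null(ann)) {
      g <- ann[ann$record_id == id, c("gene_name", "gene_class", "start", "end", "strand")]
      if (nrow(g)) as_tibble(g) else NULL
    }
    reference_record(id, as.character(seqs[[i]]), circular = circ,
                     lineage = unlist(trow[LINEAGE_RANKS]), genes = genes)
  })
  names(records) <- ids
  new_refdb(records, tax[, c("record_id", LINEAGE_RANKS)])
}

new_refdb <- function(records, taxonomy) {
  structure(list(records = records, taxonomy = as_tibble(taxonomy)),
            class = "mito_refdb")
}

#' Build a reference database from records
#'
#' @param records list of [reference_record()]s.
#' @return a `mito_refdb` whose taxonomy table is assembled from the records'
#'   lineages.
#' @export
reference_db <- function(records) {
  names(records) <- vapply(records, `[[`, "", "record_id")
  tax <- bind_rows(lapply(records, function(r) {
    as_tibble(as.list(c(record_id = r$record_id, r$lineage)))
  }))
  new_refdb(records, tax)
}

#' @export
print.mito_refdb <- function(x, ...) {
  cat(sprintf("<mito_refdb> %d records, %d lineages\n",
              length(x$records), nrow(x$taxonomy)))
  invisible(x)
}

#' Write reference sequences as FASTA
#' @param x a `mito_refdb`, a list of references, or a named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  seqs <- as_sequence_vector(x)
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read plain FASTA sequences
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- as.character(seqs)
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Write a gene annotation TSV
#' @param refdb a `mito_refdb` or list of references.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation_tsv <- function(refdb, path) {
  records <- if (inherits(refdb, "mito_refdb")) refdb$records else refdb
  ann <- bind_rows(lapply(records, function(r) {
    if (nrow(r$genes) == 0L) return(NULL)
    mutate(r$genes, record_id = r$record_id, .before = 1L)
  }))
  readr::write_tsv(ann, path, progress = FALSE)
  invisible(path)
}

#' Write a taxonomy TSV
#' @param refdb a `mito_refdb`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy_tsv <- function(refdb, path) {
  readr::write_tsv(refdb$taxonomy, path, progress = FALSE)
  invisible(path)
}

# normalize the many sequence-holder shapes to a named character vector
as_sequence_vector <- function(x) {
  if (inherits(x, "mito_refdb")) x <- x$records
  if (inherits(x, "mito_reference")) x <- list(x)
  if (is.list(x)) {
    out <- vapply(x, function(r) {
      if (inherits(r, "mito_reference")) r$sequence else as.character(r)
    }, character(1))
    nm <- if (!is.null(names(x)) && all(nzchar(names(x)))) names(x) else
      vapply(x, function(r) if (inherits(r, "mito_reference")) r$record_id else NA_character_,
             character(1))
    names(out) <- nm
    return(out)
  }
  out <- as.character(x)
  names(out) <- names(x)
  out
}

as_circular_flags <- function(x, n) {
  if (inherits(x, "mito_refdb")) {
    vapply(x$records, function(r) isTRUE(r$circular), logical(1))
  } else if (is.list(x)) {
    vapply(x, function(r) inherits(r, "mito_reference") && isTRUE(r$circular),
           logical(1))
  } else rep(FALSE, n)
}
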