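# Mitochondrial read recruitment from whole-genome shotgun data, by two
# routes: a blastn-style search against a panel of model-organism
# mitogenomes (strict 90% identity), or permissive mapping against the
# closest available reference mitogenome.

#' Derive the recruitment identity cutoff
#'
#' The strict identity cutoff is the nucleotide homology threshold minus the
#' expected sequencing error rate: with 95% homology safeguarding and ~5%
#' ONT (R9) error, the cutoff is 90%. With R10-class chemistry (~1% error)
#' the same rule yields 98-99%.
#'
#' @param homology_threshold percent identity safeguarding homology.
#' @param error_rate expected per-base sequencing error, in percent.
#' @return the identity cutoff in percent.
#' @export
derive_identity_cutoff <- function(homology_threshold = 95, error_rate = 5) {
  if (!(error_rate >= 0 && error_rate < homology_threshold &&
        homology_threshold <= 100)) {
    abort("need 0 <= error_rate < homology_threshold <= 100")
  }
  homology_threshold - error_rate
}

filter_report <- function(route, input, recruited, min_identity) {
  in_bases <- yield_bases(input)
  rec_bases <- yield_bases(recruited)
  tibble(route = route,
         input_reads = nrow(input), input_bases = in_bases,
         recruited_reads = nrow(recruited), recruited_bases = rec_bases,
         mt_fraction_percent = if (in_bases > 0) 100 * rec_bases / in_bases else 0,
         mt_read_fraction_percent = if (nrow(input) > 0)
           100 * nrow(recruited) / nrow(input) else 0,
         min_identity = min_identity)
}

#' Recruit mitochondrial reads with a model-organism panel
#'
#' A read is recruited iff it has at least one hit against any panel member
#' at `>= min_identity` percent identity over `>= min_aligned` columns
#' (the strict blastn-style route).
#'
#' @param reads a `mito_reads` tibble.
#' @param panel mitogenome panel: a `mito_refdb`, list of references, or
#'   named character vector (typically ~10 diverged mitogenomes).
#' @param min_identity identity cutoff (default 90; see
#'   [derive_identity_cutoff()]).
#' @param min_aligned minimum aligned columns.
#' @param scheme a [scoring_scheme()].
#' @return list with `reads` (recruited subset, input order preserved) and
#'   `report` (one-row tibble).
#' @export
filter_panel <- function(reads, panel, min_identity = 90, min_aligned = 100L,
                         scheme = scoring_scheme()) {
  if (nrow(reads) == 0L) {
    out <- keep_reads_attrs(reads[0, ], reads)
    return(list(reads = out, report = filter_report("panel", reads, out, min_identity)))
  }
  hits <- search_reads(reads, panel, scheme = scheme,
                       min_identity = min_identity, min_aligned = min_aligned)
  keep <- reads$read_id %in% hits$query_id
  out <- keep_reads_attrs(reads[keep, , drop = FALSE], reads)
  list(reads = out, report = filter_report("panel", reads, out, min_identity))
}

#' Recruit mitochondrial reads against a close reference
#'
#' The mapping-style route: recruits reads with any alignment to the closest
#' available reference mitogenome at a permissive identity floor (mapping
#' tolerates higher divergence than the strict 90% panel route).
#'
#' @param reads a `mito_reads` tibble.
#' @param close_reference a `mito_reference`.
#' @param min_identity identity floor (default 80).
#' @param min_aligned minimum aligned columns.
#' @param scheme a [scoring_scheme()].
#' @return list with `reads` and `report` as in [filter_panel()].
#' @export
filter_reference <- function(reads, close_reference, min_identity = 80,
                             min_aligned = 100L, scheme = scoring_scheme()) {
  stopifnot(inherits(close_reference, "mito_reference"))
  if (nrow(reads) == 0L) {
    out <- keep_reads_attrs(reads[0, ], reads)
    return(list(reads = out,
                report = filter_report("reference", reads, out, min_identity)))
  }
  hits <- search_reads(reads, list(close_reference), scheme = scheme,
                       min_identity = min_identity, min_aligned = min_aligned)
  keep <- reads$read_id %in% hits$query_id
  out <- keep_reads_attrs(reads[keep, , drop = FALSE], reads)
  list(reads = out, report = filter_report("reference", reads, out, min_identity))
}
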