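# Species identification from raw recruited reads: taxonomically scoped
# database search, explicit hit ranking (e-value ascending, then percent
# identity descending), top-hit identification, and per-read genus/species
# agreement percentages for evaluation against a known truth.

parse_scope <- function(scope) {
  scope <- as.character(scope)
  if (tolower(scope) %in% c("metazoa", "full")) {
    return(list(rank = NA_character_, taxon = NA_character_, label = "Metazoa"))
  }
  parts <- strsplit(scope, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !parts[1] %in% c("order", "family")) {
    abort(paste0("scope must be 'Metazoa', 'order:<name>' or 'family:<name>', got: ",
                 scope))
  }
  list(rank = parts[1], taxon = parts[2], label = scope)
}

#' Restrict a reference database to a taxonomic scope
#'
#' A scope is `"Metazoa"` (the full database), `"order:<name>"` or
#' `"family:<name>"`. Order/family scopes contain exactly the records whose
#' lineage matches the scope taxon; member order is deterministic (record id
#' order).
#'
#' @param database a `mito_refdb`.
#' @param scope scope string.
#' @return a `mito_refdb` restricted to the scope, with a `scope` attribute.
#' @export
scope_database <- function(database, scope = "Metazoa") {
  stopifnot(inherits(database, "mito_refdb"))
  sc <- parse_scope(scope)
  if (is.na(sc$rank)) {
    out <- database
  } else {
    tax <- database$taxonomy
    if (!sc$taxon %in% tax[[sc$rank]]) {
      abort(paste0("unknown ", sc$rank, " in taxonomy: ", sc$taxon))
    }
    ids <- sort(tax$record_id[tax[[sc$rank]] == sc$taxon])
    out <- new_refdb(database$records[ids],
                     tax[match(ids, tax$record_id), , drop = FALSE])
  }
  attr(out, "scope") <- sc$label
  out
}

#' Rank hits by the identification rule
#'
#' Total order: e-value ascending, then percent identity descending, then
#' score descending, then subject id lexicographic. The result is invariant
#' to the input permutation.
#'
#' @param hits a hits tibble (from [search_reads()]).
#' @return the hits reordered; empty input is returned unchanged.
#' @export
rank_hits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  hits[order(hits$evalue, -hits$pident, -hits$score, hits$subject_id,
             hits$query_id), , drop = FALSE]
}

#' Identify a sample from recruited reads
#'
#' Searches every read against the scoped database (best HSP per
#' read/subject), keeps each read's best hit, pools the per-read best hits,
#' ranks the pool with [rank_hits()], and takes the lineage of the
#' first-ranked hit's subject as the identification.
#'
#' @param reads a `mito_reads` tibble (typically panel-filtered).
#' @param scoped_db a [scope_database()] result (or any `mito_refdb`).
#' @param scheme a [scoring_scheme()].
#' @param min_identity,min_aligned hit filters (defaults 90 / 100).
#' @return an `identification` object: `scope`, `top` (one-row tibble:
#'   subject, species, genus, evalue, pident), `ranked_hits`,
#'   `per_read_best`, `n_reads_with_hits`, `n_unique_subjects`,
#'   `no_identification` flag.
#' @export
identify_species <- function(reads, scoped_db, scheme = scoring_scheme(),
                             min_identity = 90, min_aligned = 100L) {
  stopifnot(inherits(scoped_db, "mito_refdb"))
  if (length(scoped_db$records) == 0L) abort("empty scoped database")
  hits <- search_reads(reads, scoped_db, scheme = scheme,
                       min_identity = min_identity, min_aligned = min_aligned)
  scope <- attr(scoped_db, "scope") %||% "Metazoa"
  if (nrow(hits) == 0L) {
    return(structure(list(scope = scope, top = NULL, ranked_hits = hits,
                          per_read_best = hits, n_reads_with_hits = 0L,
                          n_unique_subjects = 0L, no_identification = TRUE),
                     class = "identification"))
  }
  # each read's own best hit, by the same ordering rule
  ranked <- rank_hits(hits)
  per_read_best <- ranked[!duplicated(ranked$query_id), , drop = FALSE]
  pool <- rank_hits(per_read_best)
  tax <- scoped_db$taxonomy
  top_row <- pool[1, ]
  top <- tibble(subject_id = top_row$subject_id,
                species = lineage_rank(tax, top_row$subject_id, "species"),
                genus = lineage_rank(tax, top_row$subject_id, "genus"),
                evalue = top_row$evalue, pident = top_row$pident,
                score = top_row$score)
  structure(list(scope = scope, top = top, ranked_hits = pool,
                 per_read_best = per_read_best,
                 n_reads_with_hits = length(unique(hits$query_id)),
                 n_unique_subjects = length(unique(hits$subject_id)),
                 no_identification = FALSE),
            class = "identification")
}

#' @export
print.identification <- function(x, ...) {
  if (x$no_identification) {
    cat(sprintf("<identification> scope %s: no identification (0 hits)\n", x$scope))
  } else {
    cat(sprintf("<identification> scope %s: %s (%s), identity %.2f%%, %d reads with hits\n",
                x$scope, x$top$species, x$top$genus, x$top$pident,
                x$n_reads_with_hits))
  }
  invisible(x)
}

#' @export
tidy.identification <- function(x, ...) x$ranked_hits

#' @export
glance.identification <- function(x, ...) {
  tibble(scope = x$scope,
         top_species = if (x$no_identification) NA_character_ else x$top$species,
         top_genus = if (x$no_identification) NA_character_ else x$top$genus,
         top_pident = if (x$no_identification) NA_real_ else x$top$pident,
         n_reads_with_hits = x$n_reads_with_hits,
         n_unique_subjects = x$n_unique_subjects,
         no_identification = x$no_identification)
}

#' Per-read genus/species agreement with a known truth
#'
#' Denominators are reads with at least one surviving hit; numerators are
#' reads whose own top-ranked hit matches the true genus (resp. species).
#' With zero reads with hits both percentages are undefined and reported as
#' `NA`, never as 0.
#'
#' @param identification an [identify_species()] result (its
#'   `per_read_best` table), or a per-read best-hit tibble.
#' @param taxonomy taxonomy tibble resolving subject ids.
#' @param truth named character vector with `species` and `genus` of the
#'   true sample lineage.
#' @return one-row tibble: `n_reads_with_hits`,
#'   `percent_reads_correct_genus`, `percent_reads_correct_species`
#'   (2 decimals).
#' @export
read_agreement <- function(identification, taxonomy, truth) {
  best <- if (inherits(identification, "identification")) {
    identification$per_read_best
  } else identification
  if (is.null(best) || nrow(best) == 0L) {
    return(tibble(n_reads_with_hits = 0L,
                  percent_reads_correct_genus = NA_real_,
                  percent_reads_correct_species = NA_real_))
  }
  sp <- vapply(best$subject_id, function(id) lineage_rank(taxonomy, id, "species"), "")
  ge <- vapply(best$subject_id, function(id) lineage_rank(taxonomy, id, "genus"), "")
  tibble(n_reads_with_hits = nrow(best),
         percent_reads_correct_genus =
           round(100 * mean(ge == truth[["genus"]]), 2),
         percent_reads_correct_species =
           round(100 * mean(sp == truth[["species"]]), 2))
}

#' Identify a sample under several taxonomic scopes
#'
#' Runs [identify_species()] once per scope (e.g. the full Metazoa database,
#' the sample's order, the sample's family) and logs wall-clock time per
#' scope.
#'
#' @param reads a `mito_reads` tibble.
#' @param database the full `mito_refdb`.
#' @param scopes character vector of scope strings.
#' @param scheme a [scoring_scheme()].
#' @param min_identity,min_aligned hit filters.
#' @return list with `results` (one `identification` per scope) and `timing`
#'   (tibble: scope, seconds).
#' @export
multiscope_identify <- function(reads, database,
                                scopes = c("Metazoa"),
                                scheme = scoring_scheme(),
                                min_identity = 90, min_aligned = 100L) {
  results <- list()
  timing <- tibble(scope = character(), seconds = numeric())
  for (scope in scopes) {
    db <- scope_database(database, scope)
    t0 <- proc.time()[["elapsed"]]
    results[[scope]] <- identify_species(reads, db, scheme = scheme,
                                         min_identity = min_identity,
                                         min_aligned = min_aligned)
    timing <- bind_rows(timing, tibble(scope = scope,
                                       seconds = proc.time()[["elapsed"]] - t0))
  }
  list(results = results, timing = timing)
}
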