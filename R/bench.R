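# The full evaluation design: six reconstruction routines (three data types
# x two assemblers), each with and without a polishing round, across
# samples; plus per-sample multi-scope identification and aggregate quality
# and recovery tables.

DATA_TYPES <- c("WGS", "panel-filtered", "reference-filtered")
ASSEMBLERS <- c("de_novo", "reference_guided")

#' Enumerate the reconstruction routines
#'
#' The cross product of data types (`WGS`, `panel-filtered`,
#' `reference-filtered`) and assemblers (`de_novo`, `reference_guided`):
#' exactly 6 routines; with both polish states, 12 cells per sample.
#'
#' @param polish_states if `TRUE`, expand each routine into polished and
#'   unpolished cells.
#' @return a tibble of routines (and `polished` when expanded).
#' @export
enumerate_routines <- function(polish_states = FALSE) {
  out <- tidyr::expand_grid(data_type = DATA_TYPES, assembler = ASSEMBLERS)
  if (polish_states) {
    out <- tidyr::expand_grid(out, polished = c(FALSE, TRUE))
  }
  out
}

#' Enumerate the full benchmark grid
#'
#' One cell per sample x routine x polish state; 21 samples give the full
#' 252-cell design.
#'
#' @param sample_ids character vector of sample identifiers.
#' @return tibble: `run_id`, `data_type`, `assembler`, `polished`.
#' @export
benchmark_grid <- function(sample_ids) {
  tidyr::expand_grid(run_id = sample_ids, enumerate_routines(polish_states = TRUE))
}

assemble_cell <- function(reads, assembler, data_type, reference,
                          expected_length, scheme) {
  if (assembler == "reference_guided") {
    assemble_reference_guided(reads, reference, data_type = data_type,
                              scheme = scheme)
  } else {
    assemble_de_novo(reads, data_type = data_type,
                     expected_length = expected_length, scheme = scheme)
  }
}

#' Run the benchmark grid over samples
#'
#' For each sample, recruits reads by both filtering routes, assembles every
#' (data type x assembler) routine with and without a polishing round,
#' scores every assembly against the sample's close reference, and
#' identifies the sample from its panel-filtered reads under the requested
#' scopes. A cell that fails to assemble is recorded as `not_assembled`;
#' a sample with no recruited reads yields explicit "no identification"
#' rows. Never aborts on an empty cell.
#'
#' @param samples list of samples; each a list with `run_id`, `reads`
#'   (a `mito_reads` tibble), `reference` (close `mito_reference`), `truth`
#'   (named character: species, genus), and optionally `scopes`.
#' @param panel mitogenome filter panel (`mito_refdb` or list of references).
#' @param database identification `mito_refdb`.
#' @param scopes default scope strings for identification.
#' @param qc a [qc_config()].
#' @param scheme a [scoring_scheme()].
#' @param polish_rounds rounds applied in the polished state.
#' @return a `benchmark_result`: list with `cells` (per-cell quality tibble),
#'   `identifications` (per sample x scope), `filter_reports`.
#' @export
run_benchmark <- function(samples, panel, database,
                          scopes = c("Metazoa"), qc = qc_config(),
                          scheme = scoring_scheme(), polish_rounds = 1L) {
  cells <- list()
  idents <- list()
  freports <- list()
  for (s in samples) {
    run_id <- s$run_id
    yield <- yield_bases(s$reads)
    fp <- filter_panel(s$reads, panel, scheme = scheme)
    fr <- filter_reference(s$reads, s$reference, scheme = scheme)
    freports[[run_id]] <- bind_rows(fp$report, fr$report) |>
      mutate(run_id = run_id, .before = 1L)
    read_sets <- list("WGS" = s$reads, "panel-filtered" = fp$reads,
                      "reference-filtered" = fr$reads)
    expected_length <- nchar(s$reference$sequence)
    for (data_type in DATA_TYPES) {
      for (assembler in ASSEMBLERS) {
        base <- tryCatch(
          assemble_cell(read_sets[[data_type]], assembler, data_type,
                        s$reference, expected_length, scheme),
          error = function(e) NULL)
        if (is.null(base)) {
          base <- new_assembly(NA_character_, data_type = data_type,
                               assembler = assembler, status = "not_assembled")
        }
        for (polished in c(FALSE, TRUE)) {
          asm <- base
          if (polished && asm$status == "assembled") {
            asm <- polish(asm, read_sets[[data_type]], rounds = polish_rounds,
                          scheme = scheme)
          }
          q <- tryCatch(assess_assembly(asm, s$reference, qc),
                        error = function(e) NULL)
          summary <- if (is.null(q)) {
            quality_summary(NULL, "not_assembled") |>
              mutate(status = "configuration-error")
          } else q$summary
          cells[[length(cells) + 1L]] <- bind_cols(
            tibble(run_id = run_id, data_type = data_type,
                   assembler = assembler, polished = polished,
                   yield_bases = yield,
                   mean_depth = if (is.null(asm$depth)) NA_real_
                                else mean(asm$depth)),
            summary)
        }
      }
    }
    scopes_s <- s$scopes %||% scopes
    ms <- multiscope_identify(fp$reads, database, scopes = scopes_s,
                              scheme = scheme)
    for (scope in names(ms$results)) {
      id <- ms$results[[scope]]
      agree <- read_agreement(id, database$taxonomy, s$truth)
      idents[[length(idents) + 1L]] <- bind_cols(
        tibble(run_id = run_id), glance(id), agree[, -1L],
        tibble(true_species = s$truth[["species"]],
               true_genus = s$truth[["genus"]]))
    }
  }
  structure(list(cells = bind_rows(cells),
                 identifications = bind_rows(idents),
                 filter_reports = bind_rows(freports)),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark_result> %d cells over %d samples; %d identification rows\n",
              nrow(x$cells), length(unique(x$cells$run_id)),
              nrow(x$identifications)))
  invisible(x)
}

#' Aggregate assembly quality tables
#'
#' Builds the percent-assembled grid (assembler x yield class x data type),
#' the mean hit/error grid (assembler x data type), and the per-category
#' composition table, from the raw benchmark cells.
#'
#' @param result a [run_benchmark()] result, or its `cells` tibble.
#' @param yield_boundary yield splitting the low/high classes, in bases.
#'   The full-scale boundary is 550 Mbp; desk-scale fixtures use a
#'   proportionally scaled boundary (coverage scales with yield).
#' @return list of tibbles: `percent_assembled`, `mean_quality`,
#'   `category_composition`.
#' @export
aggregate_quality <- function(result, yield_boundary = 550e6) {
  cells <- if (inherits(result, "benchmark_result")) result$cells else result
  if (nrow(cells) == 0L) abort("no benchmark cells to aggregate")
  cells <- mutate(cells,
                  yield_class = ifelse(.data$yield_bases >= yield_boundary,
                                       "high", "low"))
  percent_assembled <- cells |>
    group_by(.data$assembler, .data$yield_class, .data$data_type) |>
    summarise(n_cells = dplyr::n(),
              percent_assembled = 100 * mean(.data$status == "assembled"),
              .groups = "drop")
  mean_quality <- cells |>
    filter(.data$status == "assembled") |>
    group_by(.data$assembler, .data$data_type) |>
    summarise(n_assembled = dplyr::n(),
              mean_hits = mean(.data$hit_count),
              mean_errors = mean(.data$error_count),
              mean_depth = mean(.data$mean_depth, na.rm = TRUE),
              .groups = "drop")
  category_composition <- cells |>
    mutate(complete = dplyr::coalesce(.data$complete_cds, 0L) +
             dplyr::coalesce(.data$complete_rna, 0L)) |>
    tidyr::pivot_longer(c("complete", "stop_codon", "incomplete", "null"),
                        names_to = "category", values_to = "count") |>
    mutate(count = ifelse(.data$status == "assembled", .data$count, NA_integer_)) |>
    group_by(.data$assembler, .data$data_type, .data$polished, .data$category) |>
    summarise(total = sum(.data$count, na.rm = TRUE),
              n_not_assembled = sum(.data$status != "assembled"),
              .groups = "drop")
  list(percent_assembled = percent_assembled,
       mean_quality = mean_quality,
       category_composition = category_composition)
}

#' Identification recovery summary
#'
#' Per-scope fraction of samples whose top identification matches the true
#' genus and species.
#'
#' @param result a [run_benchmark()] result, or its `identifications`
#'   tibble.
#' @return tibble: scope, n_samples, percent_correct_genus,
#'   percent_correct_species, n_no_identification.
#' @export
recovery_report <- function(result) {
  ids <- if (inherits(result, "benchmark_result")) result$identifications else result
  if (nrow(ids) == 0L) abort("no identification rows")
  ids |>
    group_by(.data$scope) |>
    summarise(n_samples = dplyr::n(),
              percent_correct_genus =
                100 * mean(.data$top_genus == .data$true_genus, na.rm = TRUE),
              percent_correct_species =
                100 * mean(.data$top_species == .data$true_species, na.rm = TRUE),
              n_no_identification = sum(.data$no_identification),
              .groups = "drop")
}

#' Write benchmark outputs as TSVs
#' @param result a [run_benchmark()] result.
#' @param dir output directory (created if needed).
#' @param yield_boundary passed to [aggregate_quality()].
#' @return `dir`, invisibly.
#' @export
write_benchmark_tsvs <- function(result, dir, yield_boundary = 550e6) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(result$cells, file.path(dir, "cells.tsv"), progress = FALSE)
  agg <- aggregate_quality(result, yield_boundary)
  readr::write_tsv(agg$percent_assembled, file.path(dir, "percent_assembled.tsv"),
                   progress = FALSE)
  readr::write_tsv(agg$mean_quality, file.path(dir, "mean_quality.tsv"),
                   progress = FALSE)
  readr::write_tsv(agg$category_composition,
                   file.path(dir, "category_composition.tsv"), progress = FALSE)
  readr::write_tsv(result$identifications, file.path(dir, "identifications.tsv"),
                   progress = FALSE)
  invisible(dir)
}
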