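# ggplot2 views of the main result types.

#' @export
autoplot.depth_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$depth)) +
    ggplot2::geom_area(fill = "grey70") +
    ggplot2::geom_hline(yintercept = mean_depth(object), linetype = 2,
                        colour = "firebrick") +
    ggplot2::labs(x = "position (bp)", y = "read depth (X)",
                  title = sprintf("mean depth %.1fX", mean_depth(object))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.assembly_quality <- function(object, ...) {
  if (object$status == "not_assembled") {
    abort("nothing to plot: assembly is not assembled")
  }
  counts <- object$genes |>
    count(.data$status) |>
    mutate(status = factor(.data$status,
                           levels = c("complete", "stop_codon", "incomplete",
                                      "null")))
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$status, y = .data$n,
                                       fill = .data$status)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "genes",
                  title = "gene-level assembly quality") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.identification <- function(object, ...) {
  if (object$no_identification) {
    abort("nothing to plot: no identification")
  }
  top <- utils::head(object$ranked_hits, 20L)
  top$label <- paste0(top$subject_id, " (", round(top$pident, 1), "%)")
  ggplot2::ggplot(top, ggplot2::aes(x = -log10(.data$evalue),
                                    y = stats::reorder(.data$label, -.data$evalue))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "-log10 e-value", y = NULL,
                  title = paste0("top hits, scope ", object$scope)) +
    ggplot2::theme_minimal()
}

#' Category-composition plot across benchmark cells
#'
#' Stacked per-category gene counts per routine, split by polish state -
#' the benchmark's quality-composition view.
#'
#' @param result a [run_benchmark()] result.
#' @return a ggplot object.
#' @export
plot_quality_composition <- function(result) {
  cells <- result$cells
  long <- cells |>
    filter(.data$status == "assembled") |>
    mutate(complete = .data$complete_cds + .data$complete_rna,
           routine = paste(.data$data_type, .data$assembler, sep = " + ")) |>
    tidyr::pivot_longer(c("complete", "stop_codon", "incomplete", "null"),
                        names_to = "category", values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$routine, y = .data$count,
                                     fill = .data$category)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::facet_wrap(~.data$polished,
                        labeller = ggplot2::labeller(
                          .cols = function(v) paste0("polished: ", v))) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "gene count") +
    ggplot2::theme_minimal()
}
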