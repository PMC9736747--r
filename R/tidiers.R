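#' Tidy a patient graph into a factor-level summary
#'
#' One row per factor-value node with its connection counts and CDR (where
#' defined; degree-0 nodes get `NA`).
#'
#' @param x A `patient_graph`.
#' @param ... Unused.
#' @return A tibble with factor identity, `tpc`, `bpc`, `cdr`.
#' @method tidy patient_graph
#' @export
tidy.patient_graph <- function(x, ...) {
  counts <- count_connections(x)
  counts$cdr <- ifelse(
    counts$tpc + counts$bpc >= 1L,
    (counts$tpc - counts$bpc) / (counts$tpc + counts$bpc),
    NA_real_
  )
  counts
}

#' Summarise a patient graph in one row
#'
#' @param x A `patient_graph`.
#' @param ... Unused.
#' @return A one-row tibble: node, cohort and edge counts.
#' @method glance patient_graph
#' @export
glance.patient_graph <- function(x, ...) {
  tibble(
    n_patients = nrow(x$patients),
    n_target = sum(x$patients$label == 1L),
    n_background = sum(x$patients$label == 0L),
    n_factor_nodes = nrow(x$factors),
    n_edges = nrow(x$edges)
  )
}

#' @method tidy cdr_distribution
#' @export
tidy.cdr_distribution <- function(x, ...) {
  as_tibble(x)
}

#' Summarise a health-factor distribution in one row
#'
#' @param x A `cdr_distribution`.
#' @param ... Unused.
#' @return A one-row tibble: entry count, CDR range, number of CDR-1
#'   factors and the filter settings used.
#' @method glance cdr_distribution
#' @export
glance.cdr_distribution <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble(
    n_factors = nrow(x),
    cdr_max = if (nrow(x)) max(x$cdr) else NA_real_,
    cdr_min = if (nrow(x)) min(x$cdr) else NA_real_,
    n_cdr_one = sum(x$bpc == 0L),
    cdr_cutoff = cfg$cdr_cutoff,
    min_target_connections = cfg$min_target_connections
  )
}

#' Plot the health-factor distribution curve
#'
#' CDR versus rank for the retained factors, the standard way to eyeball
#' the strength spectrum: a plateau at 1 (factors exclusive to the target
#' cohort) followed by a decay toward the cutoff.
#'
#' @param object A `cdr_distribution`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cdr_distribution
#' @export
autoplot.cdr_distribution <- function(object, ...) {
  cfg <- attr(object, "config")
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(x = .data$rank, y = .data$cdr)
  ) +
    ggplot2::geom_step(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$category), size = 1.8) +
    ggplot2::geom_hline(
      yintercept = cfg$cdr_cutoff, linetype = "dashed", colour = "red3"
    ) +
    ggplot2::scale_y_continuous(limits = c(min(cfg$cdr_cutoff, 0), 1)) +
    ggplot2::labs(
      x = "Factor rank (CDR descending)",
      y = "Connection delta ratio",
      colour = "Category",
      title = "Health-factor distribution",
      subtitle = paste0(
        nrow(object), " factors with CDR > ", cfg$cdr_cutoff,
        " and TPC ≥ ", cfg$min_target_connections
      )
    ) +
    ggplot2::theme_minimal()
}

#' @export
plot.cdr_distribution <- function(x, ...) print(autoplot(x, ...))
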