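#' Plot a PAV matrix as a presence/absence heat map
#'
#' Rows (orthogroups) are sorted by occurrence, columns grouped by
#' subpopulation — the classic pan-genome landscape view.
#'
#' @param pav A [pav_matrix()].
#' @param max_orthogroups Downsample rows beyond this count for display.
#' @return A ggplot object.
#' @export
plot_pav_matrix <- function(pav, max_orthogroups = 2000) {
  stopifnot(inherits(pav, "pav_matrix"))
  M <- pav$presence
  if (nrow(M) > max_orthogroups) {
    M <- M[sort(sample.int(nrow(M), max_orthogroups)), , drop = FALSE]
  }
  og_order <- rownames(M)[order(-rowSums(M))]
  acc_order <- colnames(M)[order(pav$subpop[colnames(M)])]
  long <- tidy.pav_matrix(list(presence = M) |>
                            structure(class = "pav_matrix"))
  long$orthogroup_id <- factor(long$orthogroup_id, levels = og_order)
  long$accession_id <- factor(long$accession_id, levels = acc_order)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$accession_id,
                                     y = .data$orthogroup_id,
                                     fill = .data$present)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#b2182b",
                                          `FALSE` = "#2166ac"),
                               name = "present") +
    ggplot2::labs(x = "accession", y = "orthogroup") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' @export
autoplot.pan_rarefaction <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$n_accessions, y = .data$mean_count,
                               colour = .data$count_kind,
                               fill = .data$count_kind)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$min_count,
                                      ymax = .data$max_count),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "accessions sampled", y = "orthogroups",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sv_windows <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = (.data$start + .data$end) / 2,
                               y = .data$n_breakpoints)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "SV breakpoints / window") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sv_hotspots <- function(object, ...) {
  p <- autoplot.sv_windows(object$windows)
  if (nrow(object$regions) > 0) {
    p <- p + ggplot2::geom_rect(
      data = object$regions,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "#b2182b", alpha = 0.25)
  }
  p
}

#' @export
autoplot.divergence_windows <- function(object, ...) {
  stat <- attr(object, "statistic") %||% intersect(c("fst", "dxy"),
                                                   names(object))[1]
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = (.data$start + .data$end) / 2,
                               y = .data[[stat]])) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = toupper(stat)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.eqtl_result <- function(object, alpha = 0.05, ...) {
  d <- tidy(object)
  d$index <- seq_len(nrow(d))
  mapping <- if ("class" %in% names(d)) {
    ggplot2::aes(x = .data$index, y = -log10(.data$p_value),
                 colour = .data$class)
  } else {
    ggplot2::aes(x = .data$index, y = -log10(.data$p_value))
  }
  ggplot2::ggplot(d, mapping) +
    ggplot2::geom_point(size = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::labs(x = "SV-gene pair (ranked)", y = "-log10 p") +
    ggplot2::theme_minimal()
}
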