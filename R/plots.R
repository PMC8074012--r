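#' Plot induction/repression kinetics per contrast
#'
#' Bar chart of the number of genes called induced (up) and repressed
#' (down, negative axis) at each timepoint, faceted by contrast — the
#' classic transcription-wave view.
#'
#' @param tallies Output of [direction_tallies()] or an `mghi_result`.
#' @return A ggplot object.
#' @export
plot_kinetics <- function(tallies) {
  if (inherits(tallies, "mghi_result")) tallies <- tallies$tallies
  assert_cols(tallies, c("contrast", "timepoint", "direction", "n_called"),
              "tallies")
  df <- tallies %>%
    filter(.data$direction %in% c("induced", "repressed")) %>%
    mutate(n_signed = if_else(.data$direction == "induced",
                              .data$n_called, -.data$n_called),
           timepoint = factor(.data$timepoint,
                              levels = unique(.data$timepoint)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$timepoint, y = .data$n_signed,
                                   fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::facet_wrap(~contrast, scales = "free_x") +
    ggplot2::scale_fill_manual(values = c(induced = "#c23b22",
                                          repressed = "#2e6f40")) +
    ggplot2::labs(x = "timepoint", y = "genes called (repressed < 0)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot directional list sizes
#'
#' @param result An `mghi_result` or a named list of [gene_list()]s.
#' @param which Which lists to show (default the final categories).
#' @return A ggplot object.
#' @export
plot_list_sizes <- function(result,
                            which = c("A", "A1", "B1", "B2", "B3", "B", "C")) {
  lists <- if (inherits(result, "mghi_result")) result$lists else result
  lists <- lists[intersect(which, names(lists))]
  df <- purrr::imap(lists, function(l, nm) {
    as_tibble(l) %>% count(.data$direction) %>% mutate(list = nm)
  }) %>%
    bind_rows() %>%
    mutate(list = factor(.data$list, levels = names(lists)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$list, y = .data$n,
                                   fill = .data$direction)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_manual(values = c(induced = "#c23b22",
                                          repressed = "#2e6f40")) +
    ggplot2::labs(x = NULL, y = "entries", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an enrichment table
#'
#' Dot plot of the top sets by EASE p-value: fold enrichment against
#' -log10(p), sized by overlap count, filled by filter status.
#'
#' @param enrichment Output of [enrich()].
#' @param top Number of sets shown.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment, top = 20) {
  assert_cols(enrichment, c("set_name", "k", "p_ease", "fe", "passes_filter"),
              "enrichment")
  df <- enrichment %>%
    arrange(.data$p_ease) %>%
    slice_head(n = top) %>%
    mutate(set_name = factor(.data$set_name, levels = rev(.data$set_name)))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(pmax(.data$p_ease, 1e-300)),
                                   y = .data$set_name,
                                   size = .data$k,
                                   color = .data$passes_filter)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "-log10 EASE p", y = NULL, size = "overlap",
                  color = "passes filter") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mghi_result <- function(object, type = c("kinetics", "lists"), ...) {
  type <- match.arg(type)
  switch(type,
         kinetics = plot_kinetics(object),
         lists = plot_list_sizes(object))
}
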