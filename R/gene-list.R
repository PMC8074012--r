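#' Directional gene lists
#'
#' A directional gene list is the currency of the interaction set algebra:
#' a named set of (gene, direction) entries, where direction is `"induced"`
#' or `"repressed"`, with logical flags `biphasic` (opposite directions at
#' successive timepoints) and `splice_conflict` (opposite directions from
#' separate probes at one timepoint). A gene may carry both directions only
#' when one of the flags is set. Entries keep a `provenance` string naming
#' the intermediate list(s) they came from.
#'
#' @param entries Tibble (or data frame) with at least `gene` and
#'   `direction`; missing flag columns are filled with `FALSE`, missing
#'   provenance with the list name.
#' @param name Label of the list (e.g. `"A"`, `"B1"`).
#'
#' @return A tibble of class `gene_list` with attribute `list_name`.
#' @export
gene_list <- function(entries = NULL, name = "list") {
  if (is.null(entries) || nrow(as_tibble(entries)) == 0) {
    entries <- tibble(gene = character(), direction = character(),
                      biphasic = logical(), splice_conflict = logical(),
                      provenance = character())
  }
  entries <- as_tibble(entries)
  assert_cols(entries, c("gene", "direction"), "entries")
  bad_dir <- setdiff(unique(entries$direction), c("induced", "repressed"))
  if (length(bad_dir) > 0) {
    abort(sprintf("invalid direction value(s): %s",
                  paste(bad_dir, collapse = ", ")))
  }
  if (!"biphasic" %in% names(entries)) entries$biphasic <- FALSE
  if (!"splice_conflict" %in% names(entries)) entries$splice_conflict <- FALSE
  if (!"provenance" %in% names(entries)) entries$provenance <- name
  entries <- entries %>%
    select("gene", "direction", "biphasic", "splice_conflict", "provenance") %>%
    group_by(.data$gene, .data$direction) %>%
    summarise(biphasic = any(.data$biphasic),
              splice_conflict = any(.data$splice_conflict),
              provenance = paste(sort(unique(unlist(
                strsplit(.data$provenance, "+", fixed = TRUE)))),
                collapse = "+"),
              .groups = "drop") %>%
    arrange(.data$gene, .data$direction)
  structure(entries,
            class = c("gene_list", class(tibble())),
            list_name = name)
}

#' @export
print.gene_list <- function(x, ...) {
  cat(sprintf("<gene_list \"%s\"> %d entries (%d genes; %d induced, %d repressed)\n",
              list_name(x), nrow(x), n_distinct(x$gene),
              sum(x$direction == "induced"), sum(x$direction == "repressed")))
  NextMethod()
}

#' Name of a directional gene list
#' @param x A `gene_list`.
#' @return Character scalar.
#' @export
list_name <- function(x) attr(x, "list_name") %||% "list"

#' Genes of a directional list, ignoring direction
#' @param x A `gene_list` (or tibble with a `gene` column).
#' @return Character vector of distinct genes.
#' @export
list_genes <- function(x) unique(x$gene)

#' Directional overlap of two gene lists
#'
#' The primitive of the interaction set algebra. In mode `"same"` the result
#' holds (gene, direction) pairs carried with equal direction by both lists;
#' in mode `"opposite"`, genes carried with unequal directions, reported
#' under the direction of `x` (`keep = "x"`, default) or of `y`; in mode
#' `"any"`, the gene-level intersection (entries of `x` whose gene occurs in
#' `y`, whatever the direction).
#'
#' @param x,y `gene_list` objects.
#' @param mode `"same"`, `"opposite"` or `"any"`.
#' @param keep For `"opposite"`: report the direction of `"x"` or `"y"`.
#' @param name Name of the resulting list.
#'
#' @return A `gene_list`.
#' @export
directional_overlap <- function(x, y, mode = c("same", "opposite", "any"),
                                keep = c("x", "y"), name = NULL) {
  mode <- match.arg(mode)
  keep <- match.arg(keep)
  name <- name %||% sprintf("%s_%s_%s", list_name(x), mode, list_name(y))
  out <- switch(
    mode,
    same = as_tibble(x) %>%
      inner_join(as_tibble(y) %>%
                   select("gene", "direction", biphasic_y = "biphasic",
                          splice_y = "splice_conflict", prov_y = "provenance"),
                 by = c("gene", "direction")),
    opposite = {
      yy <- as_tibble(y) %>%
        mutate(direction = flip_direction(.data$direction)) %>%
        select("gene", "direction", biphasic_y = "biphasic",
               splice_y = "splice_conflict", prov_y = "provenance")
      joined <- as_tibble(x) %>% inner_join(yy, by = c("gene", "direction"))
      if (keep == "y") {
        joined <- joined %>% mutate(direction = flip_direction(.data$direction))
      }
      joined
    },
    any = as_tibble(x) %>%
      semi_join(as_tibble(y), by = "gene") %>%
      mutate(biphasic_y = FALSE, splice_y = FALSE,
             prov_y = .data$provenance))
  out <- out %>%
    mutate(biphasic = .data$biphasic | .data$biphasic_y,
           splice_conflict = .data$splice_conflict | .data$splice_y,
           provenance = paste(.data$provenance, .data$prov_y, sep = "+")) %>%
    select("gene", "direction", "biphasic", "splice_conflict", "provenance")
  gene_list(out, name = name)
}

#' Subtract one gene list from another
#'
#' Entry-wise subtraction removes matching (gene, direction) pairs;
#' gene-level subtraction removes every entry of a gene present in the
#' subtrahend, whatever its direction (used when directions are not
#' commensurate between the two lists).
#'
#' @param x,y `gene_list` objects.
#' @param by `"entry"` or `"gene"`.
#' @param name Name of the resulting list.
#' @return A `gene_list`.
#' @export
gene_list_diff <- function(x, y, by = c("entry", "gene"), name = NULL) {
  by <- match.arg(by)
  name <- name %||% list_name(x)
  keys <- if (by == "entry") c("gene", "direction") else "gene"
  gene_list(as_tibble(x) %>% anti_join(as_tibble(y), by = keys), name = name)
}

# union of gene lists, merging provenance and flags on duplicate entries
gene_list_union <- function(..., name = "union") {
  pieces <- purrr::map(list(...), as_tibble)
  gene_list(bind_rows(pieces), name = name)
}

#' @export
tidy.gene_list <- function(x, ...) {
  as_tibble(x) %>% mutate(list = list_name(x), .before = 1)
}

#' @export
glance.gene_list <- function(x, ...) {
  dual <- as_tibble(x) %>% count(.data$gene) %>% filter(.data$n > 1) %>% nrow()
  tibble(list = list_name(x),
         n_entries = nrow(x),
         n_genes = n_distinct(x$gene),
         n_induced = sum(x$direction == "induced"),
         n_repressed = sum(x$direction == "repressed"),
         n_dual = dual)
}
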