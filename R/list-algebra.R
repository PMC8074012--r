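#' Interaction set algebra for treatment-by-insult designs
#'
#' The algebra combines four merged directional lists — the two-color
#' treatment contrast (Mg vs Ctrl, "list 1"), the two-color combined
#' contrast (MgHI vs HI, "list 2"), the two-color insult contrast (HI vs
#' Ctrl, "list 3") and the one-color combined-vs-control comparison (MgHI vs
#' Ctrl, "list 7") — into the final categories:
#'
#' * List A: every treatment effect (list 1 merged over its timepoints).
#' * List A1 ("list 4"): treatment effects observed in the same direction
#'   with and without the insult — the insult-independent part of A.
#' * List B1 ("5 + 6 + 7 - 4 - 11"): de novo effects revealed only in the
#'   pretreated-insult context.
#' * List B2 ("8 + 9 - 4"): insult effects reversed by pretreatment
#'   (reported under the direction of the treatment modulation, i.e.
#'   opposite to the insult direction).
#' * List B3 ("10 - 4"): insult effects amplified by pretreatment.
#' * List B: concatenation of B1, B2, B3.
#' * List C ("11" without amplification): insult effects insensitive to the
#'   pretreatment.
#'
#' Intermediate lists: 5 = genes of list 2 absent from list 3 (gene-level);
#' 6 = opposite-direction overlap of lists 1 and 2; 8 = opposite-direction
#' overlap of lists 3 and 2; 9 = list-3 genes whose one-color comparison is
#' equivalent (see [equivalence_genes()]); 10 = same-direction overlap of
#' lists 3 and 7 with a same-sign call in list 2 (the only contrast that
#' directly tests the amplification); 11 = same-direction overlap of lists
#' 3 and 7.
#'
#' @name list_algebra
NULL

#' Build List A from the merged treatment contrast
#'
#' @param exp1_merged Merged [gene_list()] of the treatment (Mg vs Ctrl)
#'   contrast, from [merge_timepoints()].
#' @return A `gene_list` named `"A"`; dual-direction (biphasic or
#'   splice-conflict) genes are retained under both directions.
#' @export
build_list_a <- function(exp1_merged) {
  out <- gene_list(as_tibble(exp1_merged), name = "A")
  for (a in c("kinetics", "per_timepoint", "peak_timepoint", "n_at_peak")) {
    attr(out, a) <- attr(exp1_merged, a)
  }
  out
}

#' Build List A1: treatment effects unchanged by the insult
#'
#' Same-direction overlap of the treatment contrast (list 1) and the
#' combined-vs-insult contrast (list 2).
#'
#' @param l1,l2 Merged `gene_list`s of the Mg-vs-Ctrl and MgHI-vs-HI
#'   contrasts.
#' @return A `gene_list` named `"A1"`.
#' @export
build_list_a1 <- function(l1, l2) {
  directional_overlap(l1, l2, "same", name = "A1")
}

#' Build List B1: de novo effects in the pretreated-insult context
#'
#' Union of: genes affected in the combined contrast but not by the insult
#' alone (gene-level difference, list 5); genes with opposite directions in
#' the treatment and combined contrasts (list 6, reported under the
#' combined-contrast direction); and one-color combined-vs-control calls
#' (list 7). Entries of A1 are removed gene-level, entries of list 11
#' (insult effects confirmed in one-color) entry-level.
#'
#' @param l2,l3,l1,l7 Merged `gene_list`s (combined, insult, treatment,
#'   one-color).
#' @param a1 List A1 from [build_list_a1()].
#' @param l11 Same-direction overlap of `l3` and `l7` (built internally by
#'   [interaction_lists()]; see [build_list_c()]).
#' @return A `gene_list` named `"B1"` with provenance per entry.
#' @export
build_list_b1 <- function(l2, l3, l1, l7, a1, l11) {
  l5 <- gene_list_diff(l2, l3, by = "gene", name = "combined_only")
  l6 <- directional_overlap(l1, l2, "opposite", keep = "y",
                            name = "treatment_reversed_in_combined")
  b1 <- gene_list_union(l5, l6, as_tibble(l7), name = "B1")
  b1 <- gene_list_diff(b1, a1, by = "gene", name = "B1")
  gene_list_diff(b1, l11, by = "entry", name = "B1")
}

#' Build List B2: insult effects reversed by pretreatment
#'
#' Union of the opposite-direction overlap of the insult and combined
#' contrasts (list 8) and of insult-contrast genes whose one-color
#' combined-vs-control comparison shows equivalence (list 9), minus A1
#' (gene-level). Entries are reported under the direction of the treatment
#' modulation, i.e. opposite to the insult direction.
#'
#' @param l2,l3 Merged `gene_list`s of the combined and insult contrasts.
#' @param equiv_genes Character vector of one-color-equivalent genes from
#'   [equivalence_genes()].
#' @param a1 List A1.
#' @return A `gene_list` named `"B2"`.
#' @export
build_list_b2 <- function(l2, l3, equiv_genes, a1) {
  l8 <- directional_overlap(l3, l2, "opposite", keep = "y",
                            name = "insult_reversed")
  l9 <- gene_list(as_tibble(l3) %>%
                    filter(.data$gene %in% equiv_genes) %>%
                    mutate(direction = flip_direction(.data$direction),
                           provenance = "insult_nullified"),
                  name = "insult_nullified")
  b2 <- gene_list_union(l8, l9, name = "B2")
  gene_list_diff(b2, a1, by = "gene", name = "B2")
}

#' Build List B3: insult effects amplified by pretreatment
#'
#' Same-direction overlap of the insult contrast and the one-color
#' comparison in which the combined contrast is also called with the same
#' sign as the insult (list 10), minus A1 (gene-level). The combined
#' contrast is the only one that directly tests combined-vs-insult, so its
#' same-sign call is the amplification criterion.
#'
#' @param l3,l7,l2 Merged `gene_list`s (insult, one-color, combined).
#' @param a1 List A1.
#' @return A `gene_list` named `"B3"`.
#' @export
build_list_b3 <- function(l3, l7, l2, a1) {
  l11 <- directional_overlap(l3, l7, "same", name = "insult_confirmed")
  l10 <- directional_overlap(l11, l2, "same", name = "insult_amplified")
  b3 <- gene_list(as_tibble(l10) %>% mutate(provenance = "insult_amplified"),
                  name = "B3")
  gene_list_diff(b3, a1, by = "gene", name = "B3")
}

#' Build List C: insult effects insensitive to pretreatment
#'
#' Same-direction overlap of the insult contrast and the one-color
#' comparison (list 11) for entries not satisfying the amplification
#' criterion (no same-sign call in the combined contrast) — the complement
#' of List B3 within list 11.
#'
#' @param l3,l7,l2 Merged `gene_list`s (insult, one-color, combined).
#' @return A `gene_list` named `"C"`.
#' @export
build_list_c <- function(l3, l7, l2) {
  l11 <- directional_overlap(l3, l7, "same", name = "insult_confirmed")
  l10 <- directional_overlap(l11, l2, "same", name = "insult_amplified")
  gene_list(as_tibble(gene_list_diff(l11, l10, by = "entry")) %>%
              mutate(provenance = "insult_insensitive"),
            name = "C")
}

#' Assemble List B from its three sub-lists
#'
#' Concatenates B1, B2 and B3. The sub-lists are disjoint by construction;
#' any (gene, direction) entry appearing in more than one sub-list is a
#' construction error and raises an assertion failure naming the genes.
#'
#' @param b1,b2,b3 The sub-lists.
#' @return A `gene_list` named `"B"` whose provenance records the sub-list.
#' @export
build_list_b <- function(b1, b2, b3) {
  pieces <- list(B1 = b1, B2 = b2, B3 = b3)
  tagged <- purrr::imap(pieces, function(l, nm) {
    as_tibble(l) %>% mutate(sublist = nm)
  })
  all <- bind_rows(tagged)
  dup <- all %>%
    distinct(.data$gene, .data$direction, .data$sublist) %>%
    count(.data$gene, .data$direction) %>%
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf(
      "sub-lists of B overlap (construction error) for gene(s): %s",
      paste(utils::head(unique(dup$gene), 10), collapse = ", ")))
  }
  gene_list(all %>% mutate(provenance = .data$sublist) %>% select(-"sublist"),
            name = "B")
}

#' Classify every gene into its interaction category
#'
#' Assigns each (gene, direction) entry exactly one category: `de_novo`
#' (B1), `reversed` (B2), `amplified` (B3), `insensitive` (C), `shared`
#' (A1) or `mg_only` (A outside A1); genes in no list are `unaffected`.
#' The B/C categories are checked for pairwise disjointness first. The
#' provenance column records every list that contains the entry.
#'
#' @param lists Named list with elements `A`, `A1`, `B1`, `B2`, `B3`, `C`
#'   (each a [gene_list()]).
#' @param genes Optional character vector of all analysed genes; those in
#'   no list are reported as `unaffected` with direction `"none"`.
#' @return Tibble: `gene`, `direction`, `category`, `provenance`, flags.
#' @export
classify_genes <- function(lists, genes = NULL) {
  needed <- c("A", "A1", "B1", "B2", "B3", "C")
  if (!all(needed %in% names(lists))) {
    abort(sprintf("`lists` must contain elements: %s",
                  paste(needed, collapse = ", ")))
  }
  entries <- purrr::imap(lists[needed], function(l, nm) {
    as_tibble(l) %>% mutate(member_of = nm)
  }) %>% bind_rows()

  exclusive <- entries %>%
    filter(.data$member_of %in% c("B1", "B2", "B3", "C")) %>%
    distinct(.data$gene, .data$direction, .data$member_of) %>%
    count(.data$gene, .data$direction) %>%
    filter(.data$n > 1)
  if (nrow(exclusive) > 0) {
    abort(sprintf("contradictory B/C membership for gene(s): %s",
                  paste(utils::head(unique(exclusive$gene), 10),
                        collapse = ", ")))
  }

  precedence <- c(B1 = "de_novo", B2 = "reversed", B3 = "amplified",
                  C = "insensitive", A1 = "shared", A = "mg_only")
  classified <- entries %>%
    mutate(rank = match(.data$member_of, names(precedence))) %>%
    group_by(.data$gene, .data$direction) %>%
    summarise(category = precedence[[names(precedence)[min(.data$rank)]]],
              provenance = paste(sort(unique(.data$member_of)),
                                 collapse = "+"),
              biphasic = any(.data$biphasic),
              splice_conflict = any(.data$splice_conflict),
              .groups = "drop")

  if (!is.null(genes)) {
    missing <- setdiff(genes, classified$gene)
    classified <- bind_rows(
      classified,
      tibble(gene = missing, direction = "none", category = "unaffected",
             provenance = "", biphasic = FALSE, splice_conflict = FALSE))
  }
  classified %>% arrange(.data$gene, .data$direction)
}

#' Overlap counts between gene lists
#'
#' Gene-level sizes and all pairwise and triple intersections of the
#' supplied lists (a Venn tally).
#'
#' @param lists Named list of [gene_list()] objects (2 or more).
#' @return Tibble with `lists` (names joined by `&`) and `n_genes`.
#' @export
venn_counts <- function(lists) {
  if (is.null(names(lists)) || any(names(lists) == "")) {
    abort("`lists` must be a fully named list")
  }
  sets <- purrr::map(lists, list_genes)
  nm <- names(sets)
  rows <- list()
  for (k in seq_len(min(3, length(sets)))) {
    combos <- utils::combn(nm, k, simplify = FALSE)
    for (cb in combos) {
      rows[[length(rows) + 1]] <- tibble(
        lists = paste(cb, collapse = "&"),
        n_genes = length(purrr::reduce(sets[cb], intersect)))
    }
  }
  bind_rows(rows)
}

#' Induction/repression tallies per contrast and timepoint
#'
#' @param calls Called statistics (gene- or probe-level) with `contrast`,
#'   `timepoint`, `direction`, `called`.
#' @return Tibble of counts per contrast x timepoint x direction.
#' @export
direction_tallies <- function(calls) {
  assert_cols(calls, c("contrast", "timepoint", "direction", "called"),
              "calls")
  calls %>%
    filter(.data$called) %>%
    count(.data$contrast, .data$timepoint, .data$direction,
          name = "n_called")
}

#' Run the whole set algebra from the four merged lists
#'
#' Builds A, A1, B1-B3, B and C. The reversal (B2) and amplification (B3)
#' lists rest on direct two-color evidence in the combined contrast; the de
#' novo list B1 partly rests on the weaker one-color route. Under noise a
#' gene can occasionally satisfy both a B2/B3 criterion and a B1 route, so
#' B1 is subordinated: entries claimed by B2 or B3 are removed from B1
#' before concatenation, which makes the sub-lists disjoint by construction
#' and lets [build_list_b()] assert that property.
#'
#' @param l1,l2,l3,l7 Merged `gene_list`s of the treatment, combined,
#'   insult and one-color contrasts.
#' @param equiv_genes Genes passing the one-color equivalence band.
#' @return Named list of `gene_list`s: `L1`, `L2`, `L3`, `L7`, `A`, `A1`,
#'   `B1`, `B2`, `B3`, `B`, `C`.
#' @export
interaction_lists <- function(l1, l2, l3, l7, equiv_genes) {
  a <- build_list_a(l1)
  a1 <- build_list_a1(l1, l2)
  l11 <- directional_overlap(l3, l7, "same", name = "insult_confirmed")
  b1 <- build_list_b1(l2, l3, l1, l7, a1, l11)
  b2 <- build_list_b2(l2, l3, equiv_genes, a1)
  b3 <- build_list_b3(l3, l7, l2, a1)
  b1 <- gene_list_diff(gene_list_diff(b1, b2, by = "entry"), b3,
                       by = "entry", name = "B1")
  c_list <- build_list_c(l3, l7, l2)
  b <- build_list_b(b1, b2, b3)
  list(L1 = l1, L2 = l2, L3 = l3, L7 = l7,
       A = a, A1 = a1, B1 = b1, B2 = b2, B3 = b3, B = b, C = c_list)
}
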