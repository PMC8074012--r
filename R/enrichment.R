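#' Right-tailed Fisher exact (hypergeometric tail) test
#'
#' Probability of observing `k` or more query genes in a set of size `K`
#' when `n` genes are drawn from a universe of `N`.
#'
#' @param k Overlap count(s).
#' @param n Query-list size(s).
#' @param K Set size(s).
#' @param N Universe size(s).
#' @return Vector of right-tail p-values, `P(X >= k)`.
#' @export
fisher_exact <- function(k, n, K, N) {
  check_counts(k, n, K, N)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' EASE score: jackknifed Fisher exact test
#'
#' The Fisher right tail recomputed after removing one gene from the
#' overlap (k - 1 successes), a conservative penalty that deflates
#' one-gene coincidences; overlaps of 0 or 1 score p = 1.
#'
#' @inheritParams fisher_exact
#' @return Vector of EASE p-values; always >= the Fisher p for k >= 1.
#' @export
ease_score <- function(k, n, K, N) {
  check_counts(k, n, K, N)
  len <- max(length(k), length(n), length(K), length(N))
  k <- rep_len(k, len)
  n <- rep_len(n, len)
  K <- rep_len(K, len)
  N <- rep_len(N, len)
  out <- rep(1, len)
  idx <- k >= 2
  if (any(idx)) {
    out[idx] <- stats::phyper(k[idx] - 2, K[idx], N[idx] - K[idx], n[idx],
                              lower.tail = FALSE)
  }
  out
}

#' Fold enrichment
#'
#' `FE = (k/n) / (K/N)`: the overlap rate in the query relative to the
#' background rate of the set.
#'
#' @inheritParams fisher_exact
#' @return Nonnegative fold enrichment values.
#' @export
fold_enrichment <- function(k, n, K, N) {
  check_counts(k, n, K, N)
  if (any(n == 0 | K == 0 | N == 0)) {
    abort("`n`, `K` and `N` must be positive")
  }
  (k / n) / (K / N)
}

check_counts <- function(k, n, K, N) {
  args <- cbind(k, n, K, N)
  if (anyNA(args) || any(args < 0)) abort("counts must be nonnegative")
  if (any(k > pmin(n, K)) || any(n > N) || any(K > N)) {
    abort("inconsistent counts: need k <= min(n, K), n <= N, K <= N")
  }
  invisible(NULL)
}

#' Harmonize a gene-set collection against a universe
#'
#' @param sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param universe Character vector of background genes.
#' @return List with harmonized `sets` (each intersected with the universe,
#'   empty sets dropped with a warning) and the `universe`.
#' @export
gene_set_collection <- function(sets, universe) {
  if (is.null(names(sets)) || any(names(sets) == "")) {
    abort("`sets` must be a fully named list")
  }
  universe <- unique(universe)
  sets <- purrr::map(sets, ~ intersect(unique(.x), universe))
  empty <- purrr::map_int(sets, length) == 0
  if (any(empty)) {
    warn(sprintf("dropping %d empty set(s) after harmonization: %s",
                 sum(empty),
                 paste(utils::head(names(sets)[empty], 5), collapse = ", ")))
    sets <- sets[!empty]
  }
  list(sets = sets, universe = universe)
}

#' Over-representation of gene sets in a query list
#'
#' Direction-blind over-representation analysis with the classical DAVID
#' statistics per set: overlap `k`, Fisher right-tail p, EASE p, fold
#' enrichment, Bonferroni (over the collection) and BH FDR. Two filter
#' profiles are provided: `"keyword"` (k >= `min_count` and Bonferroni p <
#' 1e-4, or EASE p < 1e-4 with FE > 2) and `"pathway"` (k >= `min_count`,
#' Bonferroni p < 0.05, FDR < 10%); `"none"` keeps everything.
#'
#' The universe defaults to all genes that survived QC in the calling
#' pipeline; stand-alone calls must pass it explicitly.
#'
#' @param query A [gene_list()] or character vector of genes.
#' @param sets Named list of gene sets.
#' @param universe Background gene vector.
#' @param profile Filter profile, see above.
#' @param min_count Minimum overlap count for the filters.
#' @return Tibble with one row per set: `set_name`, `k`, `n`, `K`, `N`,
#'   `p_fisher`, `p_ease`, `fe`, `p_bonferroni`, `fdr`, `passes_filter`.
#' @export
enrich <- function(query, sets, universe,
                   profile = c("keyword", "pathway", "none"),
                   min_count = 10) {
  profile <- match.arg(profile)
  genes <- if (inherits(query, "gene_list") || is.data.frame(query)) {
    list_genes(query)
  } else {
    unique(as.character(query))
  }
  coll <- gene_set_collection(sets, universe)
  q <- intersect(genes, coll$universe)
  if (length(q) == 0) abort("query and universe share no genes")

  N <- length(coll$universe)
  n <- length(q)
  K <- unname(purrr::map_int(coll$sets, length))
  k <- unname(purrr::map_int(coll$sets, ~ length(intersect(.x, q))))
  m <- length(coll$sets)

  out <- tibble(set_name = names(coll$sets), k = k, n = n, K = K, N = N) %>%
    mutate(p_fisher = fisher_exact(.data$k, .data$n, .data$K, .data$N),
           p_ease = ease_score(.data$k, .data$n, .data$K, .data$N),
           fe = fold_enrichment(.data$k, .data$n, .data$K, .data$N),
           p_bonferroni = pmin(1, .data$p_fisher * m),
           fdr = bh_adjust(.data$p_fisher))
  out %>%
    mutate(passes_filter = switch(
      profile,
      keyword = .data$k >= min_count &
        (.data$p_bonferroni < 1e-4 |
           (.data$p_ease < 1e-4 & .data$fe > 2)),
      pathway = .data$k >= min_count & .data$p_bonferroni < 0.05 &
        .data$fdr < 0.10,
      none = rep(TRUE, n()))) %>%
    arrange(.data$p_fisher)
}

#' Regulator activation z-score on a signed network
#'
#' For each regulator, its known targets present in the directional query
#' are scored for sign consistency with a hypothesized activation: an edge
#' is consistent when edge sign times observed target direction (+1 induced,
#' -1 repressed) is positive. The unweighted activation z-score is
#' `(n_consistent - n_inconsistent) / sqrt(n_consistent + n_inconsistent)`;
#' z > 2 predicts activation, z < -2 inhibition (strict inequalities),
#' anything else is undetermined. A Fisher right-tail p on the target-set
#' overlap accompanies the z.
#'
#' Genes carried under both directions (biphasic / splice conflicts) are
#' ambiguous and excluded from the consistency count.
#'
#' @param query A [gene_list()] (directions are used).
#' @param network Tibble with `regulator`, `target`, `sign` (+1/-1), unique
#'   per (regulator, target).
#' @param universe Background genes for the overlap test.
#' @return Tibble per regulator: `n_targets`, `n_consistent`,
#'   `n_inconsistent`, `z`, `p_overlap`, `predicted_state`. Regulators with
#'   no overlapping directional target are omitted.
#' @export
regulator_zscore <- function(query, network, universe) {
  assert_cols(network, c("regulator", "target", "sign"), "network")
  if (any(duplicated(network[c("regulator", "target")]))) {
    abort("network edges must be unique per (regulator, target)")
  }
  if (!all(network$sign %in% c(-1, 1))) {
    abort("edge `sign` must be +1 or -1")
  }
  universe <- unique(universe)
  dirs <- as_tibble(query) %>%
    distinct(.data$gene, .data$direction) %>%
    group_by(.data$gene) %>%
    filter(n() == 1) %>%  # drop dual-direction genes
    ungroup() %>%
    mutate(dir_sign = if_else(.data$direction == "induced", 1, -1))
  q_genes <- unique(as_tibble(query)$gene)

  network %>%
    filter(.data$target %in% universe) %>%
    left_join(dirs, by = c(target = "gene")) %>%
    group_by(.data$regulator) %>%
    summarise(
      n_targets_universe = n(),
      n_overlap = sum(.data$target %in% q_genes),
      n_consistent = sum(.data$sign * .data$dir_sign > 0, na.rm = TRUE),
      n_inconsistent = sum(.data$sign * .data$dir_sign < 0, na.rm = TRUE),
      .groups = "drop") %>%
    filter(.data$n_consistent + .data$n_inconsistent > 0) %>%
    mutate(
      n_targets = .data$n_consistent + .data$n_inconsistent,
      z = (.data$n_consistent - .data$n_inconsistent) / sqrt(.data$n_targets),
      p_overlap = fisher_exact(
        pmin(.data$n_overlap, length(intersect(q_genes, universe))),
        length(intersect(q_genes, universe)),
        .data$n_targets_universe, length(universe)),
      predicted_state = case_when(.data$z > 2 ~ "activated",
                                  .data$z < -2 ~ "inhibited",
                                  .default = "undetermined")) %>%
    select("regulator", "n_targets", "n_consistent", "n_inconsistent",
           "z", "p_overlap", "predicted_state") %>%
    arrange(desc(abs(.data$z)))
}

#' Concordance of treatment effects with ontogenetic trajectories
#'
#' Labels each directional query gene `anticipating` when its effect
#' direction matches the gene's spontaneous developmental direction
#' (induced & increasing, or repressed & decreasing) and `antagonistic`
#' otherwise. Genes absent from the developmental table are skipped and
#' counted.
#'
#' @param query A [gene_list()].
#' @param dev_table Tibble with `gene` and `developmental_direction`
#'   (`"increasing"`/`"decreasing"`).
#' @return Tibble per (gene, direction): `developmental_direction`,
#'   `concordance`; summary counts are attached as attribute `"summary"`
#'   and the skipped-gene count as `"n_skipped"`.
#' @export
ontogeny_concordance <- function(query, dev_table) {
  assert_cols(dev_table, c("gene", "developmental_direction"), "dev_table")
  bad <- setdiff(unique(dev_table$developmental_direction),
                 c("increasing", "decreasing"))
  if (length(bad) > 0) {
    abort(sprintf("invalid developmental direction(s): %s",
                  paste(bad, collapse = ", ")))
  }
  q <- as_tibble(query) %>% distinct(.data$gene, .data$direction)
  joined <- q %>% inner_join(dev_table %>% distinct(.data$gene, .data$developmental_direction),
                             by = "gene")
  n_skipped <- length(setdiff(q$gene, dev_table$gene))
  out <- joined %>%
    mutate(concordance = if_else(
      (.data$direction == "induced" &
         .data$developmental_direction == "increasing") |
        (.data$direction == "repressed" &
           .data$developmental_direction == "decreasing"),
      "anticipating", "antagonistic"))
  attr(out, "summary") <- out %>%
    count(.data$developmental_direction, .data$concordance, name = "n_genes")
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Read gene sets from a GMT file
#'
#' @param path Path to a tab-separated GMT file (set name, description,
#'   member genes).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!requireNamespace("fgsea", quietly = TRUE)) {
    abort("reading GMT files requires the fgsea package")
  }
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- purrr::imap_chr(sets, function(g, nm) {
    paste(c(nm, "na", g), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}
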