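#' Run the full analysis pipeline
#'
#' Orchestrates QC, differential statistics, timepoint merging, the
#' interaction set algebra and summary reporting on a simulated or loaded
#' dataset: probe filtering (uniformity everywhere; detection above
#' background for one-color data), exclusion of non-gene probes,
#' per-timepoint probe statistics with BH correction, the fold-change/p
#' calling rule, per-gene probe resolution with splice-conflict flagging,
#' merging over timepoints, and the directional set algebra yielding Lists
#' A, A1, B1-B3, B and C plus the per-gene classification.
#'
#' @param data An `mghi_sim` object ([simulate_experiment()]) or a directory
#'   path readable by [read_sim_data()].
#' @param fc_threshold,p_threshold,rule,p_col Calling rule, see
#'   [call_differential()].
#' @param detection_factor,min_detected Detection filter, see
#'   [filter_probes()].
#' @param equiv_p,equiv_log2 One-color equivalence band, see
#'   [equivalence_genes()].
#' @param var_equal Pooled-variance one-color t (default) or Welch.
#'
#' @return An object of class `mghi_result`: list with `stats` (probe
#'   level), `gene_stats` (resolved), `lists` (all directional lists),
#'   `classification`, `venn`, `tallies`, `amplitudes`, `summary` and
#'   `manifest`.
#' @export
run_pipeline <- function(data,
                         fc_threshold = 2, p_threshold = 0.05,
                         rule = c("union", "intersection", "p_only"),
                         p_col = "p_bh",
                         detection_factor = 2, min_detected = 2,
                         equiv_p = 0.05, equiv_log2 = log2(1.5),
                         var_equal = TRUE) {
  rule <- match.arg(rule)
  if (is.character(data)) data <- read_sim_data(data)
  if (!inherits(data, "mghi_sim")) {
    abort("`data` must be an mghi_sim object or a data directory")
  }
  t0 <- Sys.time()

  ## ---- QC ----
  tc <- filter_probes(data$two_color)
  oc <- filter_probes(data$one_color, detection_factor = detection_factor,
                      min_detected = min_detected)
  qc_log <- list(two_color = qc_report(tc), one_color = qc_report(oc))
  tc <- exclude_nongene_probes(tc, data$probes)
  oc <- exclude_nongene_probes(oc, data$probes)
  genes_tested <- unique(c(tc$gene_symbol, oc$gene_symbol))

  ## ---- probe statistics and calls ----
  stats_tc <- two_color_stats(tc) %>%
    call_differential(fc_threshold = fc_threshold, p_threshold = p_threshold,
                      rule = rule, p_col = p_col)
  stats_oc <- one_color_stats(oc, var_equal = var_equal) %>%
    call_differential(fc_threshold = fc_threshold, p_threshold = p_threshold,
                      rule = rule, p_col = p_col)

  ## ---- gene-level resolution and merging ----
  gene_tc <- resolve_multiprobe(stats_tc)
  gene_oc <- resolve_multiprobe(stats_oc)
  merged <- purrr::map(
    c(mg = "mg", mghi_hi = "mghi_hi", hi = "hi"),
    ~ merge_timepoints(gene_tc %>% filter(.data$contrast == .x), name = .x))
  l7 <- merge_timepoints(gene_oc, name = "mghi_ctrl")
  equiv <- equivalence_genes(gene_oc, p_gt = equiv_p,
                             max_abs_log2 = equiv_log2)

  ## ---- set algebra ----
  lists <- interaction_lists(merged$mg, merged$mghi_hi, merged$hi, l7,
                             equiv_genes = equiv)
  classification <- classify_genes(lists[c("A", "A1", "B1", "B2", "B3", "C")],
                                   genes = genes_tested)
  venn <- venn_counts(lists[c("L1", "L2", "L3", "L7")])
  tallies <- direction_tallies(bind_rows(
    gene_tc %>% select("contrast", "timepoint", "direction", "called"),
    gene_oc %>% select("contrast", "timepoint", "direction", "called")))

  # one |FC| per gene and direction: its largest called amplitude
  amplitudes <- gene_tc %>%
    filter(.data$called, .data$contrast == "mg") %>%
    group_by(.data$gene_symbol, .data$direction) %>%
    dplyr::slice_max(abs(.data$fc), n = 1, with_ties = FALSE) %>%
    ungroup() %>%
    select("direction", "fc") %>%
    amplitude_summary()

  result <- structure(
    list(stats = bind_rows(stats_tc, stats_oc),
         gene_stats = bind_rows(gene_tc, gene_oc),
         lists = lists,
         classification = classification,
         venn = venn,
         tallies = tallies,
         amplitudes = amplitudes,
         qc = qc_log,
         genes_tested = genes_tested,
         manifest = list(
           parameters = list(fc_threshold = fc_threshold,
                             p_threshold = p_threshold, rule = rule,
                             p_col = p_col,
                             detection_factor = detection_factor,
                             min_detected = min_detected,
                             equiv_p = equiv_p, equiv_log2 = equiv_log2,
                             var_equal = var_equal),
           input_checksum = rlang::hash(data[c("two_color", "one_color",
                                               "design", "probes")]),
           config = data$config,
           n_genes_tested = length(genes_tested),
           list_sizes = purrr::map_int(lists, ~ n_distinct(.x$gene)),
           version = as.character(utils::packageVersion("dirlists")),
           elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))),
    class = "mghi_result")
  result$summary <- report_summary(lists)
  result
}

#' Summary tallies of the directional lists
#'
#' Per-list induction/repression/dual counts with the inclusion-exclusion
#' identity `distinct = induced + repressed - dual`, where dual is the
#' number of genes carrying both directions. When the List-A kinetics are
#' available, the percentage of List-A genes called at the peak timepoint
#' is attached, as is the retention of insult effects
#' (`|C| / |list 3|`, gene-level), both rounded half-up to one decimal.
#'
#' @param lists Named list of [gene_list()] objects (tibbles with `gene`
#'   and `direction` columns are accepted).
#' @return Tibble with one row per list: `list`, `n_induced`,
#'   `n_repressed`, `n_dual`, `n_distinct_genes`. Extras are attached as
#'   attributes `peak` and `c_retention`.
#' @export
report_summary <- function(lists) {
  rows <- purrr::imap(lists, function(l, nm) {
    tb <- as_tibble(l)
    dual <- tb %>% distinct(.data$gene, .data$direction) %>%
      count(.data$gene) %>% filter(.data$n > 1) %>% nrow()
    tibble(list = nm,
           n_induced = sum(tb$direction == "induced"),
           n_repressed = sum(tb$direction == "repressed"),
           n_dual = dual,
           n_distinct_genes = sum(tb$direction == "induced") +
             sum(tb$direction == "repressed") - dual)
  })
  out <- bind_rows(rows)

  if ("A" %in% names(lists)) {
    a <- lists$A
    kin <- attr(a, "kinetics")
    peak_tp <- attr(a, "peak_timepoint")
    if (!is.null(kin) && !is.null(peak_tp) && !is.na(peak_tp) &&
        nrow(kin) > 0) {
      n_at_peak <- sum(purrr::map_lgl(
        strsplit(kin$timepoints, ","), ~ peak_tp %in% .x))
      n_total <- n_distinct(a$gene)
      attr(out, "peak") <- tibble(
        list = "A", peak_timepoint = peak_tp, n_at_peak = n_at_peak,
        pct_at_peak = round_half_up(100 * n_at_peak / n_total, 1))
    }
  }
  if (all(c("C", "L3") %in% names(lists))) {
    n3 <- n_distinct(as_tibble(lists$L3)$gene)
    nc <- n_distinct(as_tibble(lists$C)$gene)
    if (n3 > 0) {
      attr(out, "c_retention") <- tibble(
        n_c = nc, n_insult = n3,
        pct_retained = round_half_up(100 * nc / n3, 1))
    }
  }
  out
}

#' @export
print.mghi_result <- function(x, ...) {
  cat("<mghi_result>\n")
  cat(sprintf("  %d genes tested; elapsed %.1fs\n",
              x$manifest$n_genes_tested, x$manifest$elapsed_s))
  print(x$summary, n = 15)
  invisible(x)
}

#' @export
tidy.mghi_result <- function(x, ...) {
  x$classification
}

#' @export
glance.mghi_result <- function(x, ...) {
  sizes <- x$manifest$list_sizes
  tibble(n_genes_tested = x$manifest$n_genes_tested,
         n_list_a = sizes[["A"]], n_list_a1 = sizes[["A1"]],
         n_list_b1 = sizes[["B1"]], n_list_b2 = sizes[["B2"]],
         n_list_b3 = sizes[["B3"]], n_list_b = sizes[["B"]],
         n_list_c = sizes[["C"]],
         n_unaffected = sum(x$classification$category == "unaffected"))
}
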