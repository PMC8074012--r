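#' One-sample t test against zero
#'
#' Classical one-sample t statistic for a vector of log2 ratios, with df =
#' n - 1 and a two-sided p-value. Degenerate zero-variance inputs do not
#' crash batch runs: a constant zero vector gives p = 1, a constant nonzero
#' vector gives p = 0 with the `degenerate` flag set.
#'
#' @param x Numeric vector of at least 2 finite values.
#' @return One-row tibble: `estimate`, `t_stat`, `df`, `p_value`,
#'   `degenerate`.
#' @export
#' @examples
#' one_sample_t(c(1.0, 1.2, 0.8))
one_sample_t <- function(x) {
  if (length(x) < 2 || !all(is.finite(x))) {
    abort("`x` must hold at least 2 finite values")
  }
  res <- t_from_moments(mean(x), stats::sd(x), length(x))
  tibble(estimate = mean(x), t_stat = res$t, df = length(x) - 1,
         p_value = res$p, degenerate = res$degenerate)
}

# vectorized one-sample t from per-group moments
t_from_moments <- function(m, s, n) {
  se <- s / sqrt(n)
  t <- ifelse(se > 0, m / se, ifelse(m == 0, 0, Inf * sign(m)))
  p <- ifelse(se > 0, 2 * stats::pt(-abs(t), df = n - 1),
              ifelse(m == 0, 1, 0))
  list(t = t, p = p, degenerate = se == 0 & m != 0)
}

#' Two-group t test on log2 intensities
#'
#' Pooled-variance two-sample t test by default (`var_equal = TRUE`), Welch
#' otherwise. The estimate is the difference of group means on the log2
#' scale (`a` minus `b`). Zero pooled variance follows the same degenerate
#' conventions as [one_sample_t()].
#'
#' @param a,b Numeric vectors with at least 2 finite values each.
#' @param var_equal Pool the variances?
#' @return One-row tibble: `estimate`, `t_stat`, `df`, `p_value`,
#'   `degenerate`.
#' @export
two_group_t <- function(a, b, var_equal = TRUE) {
  if (length(a) < 2 || length(b) < 2 || !all(is.finite(c(a, b)))) {
    abort("each group must hold at least 2 finite values")
  }
  res <- t2_from_moments(mean(a), stats::var(a), length(a),
                         mean(b), stats::var(b), length(b),
                         var_equal = var_equal)
  tibble(estimate = mean(a) - mean(b), t_stat = res$t, df = res$df,
         p_value = res$p, degenerate = res$degenerate)
}

# vectorized two-sample t from per-group moments
t2_from_moments <- function(ma, va, na, mb, vb, nb, var_equal = TRUE) {
  d <- ma - mb
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    df[!is.finite(df)] <- na + nb - 2
  }
  t <- ifelse(se > 0, d / se, ifelse(d == 0, 0, Inf * sign(d)))
  p <- ifelse(se > 0, 2 * stats::pt(-abs(t), df = df),
              ifelse(d == 0, 1, 0))
  list(t = t, p = p, df = df, degenerate = se == 0 & d != 0)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values (monotone in rank, capped at 1), in the input
#'   order.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1)) {
    abort("`p_values` must all lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Per-timepoint probe statistics from two-color log2 ratios
#'
#' For every probe x contrast x timepoint: mean log2 ratio over replicate
#' arrays, one-sample t against 0, raw and BH-adjusted p (BH applied across
#' probes within each contrast x timepoint, matching per-timepoint list
#' extraction) and the signed linear fold change.
#'
#' @param spots Long two-color spot table (`probe_id`, `contrast`,
#'   `timepoint`, `log2_ratio`, optionally `gene_symbol`).
#' @return Tibble of probe-level statistics.
#' @export
two_color_stats <- function(spots) {
  assert_cols(spots, c("probe_id", "contrast", "timepoint", "log2_ratio"),
              "spots")
  carry <- intersect("gene_symbol", names(spots))
  out <- spots %>%
    group_by(across(all_of(c("probe_id", carry, "contrast", "timepoint")))) %>%
    summarise(n = n(), mean_log2_ratio = mean(.data$log2_ratio),
              sd_log2_ratio = stats::sd(.data$log2_ratio), .groups = "drop") %>%
    filter(.data$n >= 2)
  res <- t_from_moments(out$mean_log2_ratio, out$sd_log2_ratio, out$n)
  out %>%
    mutate(t_stat = res$t, p_raw = res$p, degenerate = res$degenerate,
           fc = signed_fc(.data$mean_log2_ratio)) %>%
    group_by(.data$contrast, .data$timepoint) %>%
    mutate(p_bh = bh_adjust(.data$p_raw)) %>%
    ungroup()
}

#' Per-timepoint probe statistics from one-color intensities
#'
#' Compares the combined-condition group (default `MgHI`) to the reference
#' group (default `Ctrl`, pooling control channels from every experiment
#' providing them) at each timepoint shared by both groups, using a
#' two-group t test on log2 intensities. The estimate (`mean_log2_ratio`)
#' is the difference of group means on the log2 scale, so the same fold
#' change / p calling rule applies as for two-color data.
#'
#' @param spots Long one-color spot table (`probe_id`, `condition`,
#'   `timepoint`, `signal`, optionally `gene_symbol`).
#' @param group_a,group_b Condition labels compared (`a` minus `b`).
#' @param contrast Label given to the resulting contrast.
#' @param var_equal Pooled-variance t (default) or Welch.
#' @return Tibble of probe-level statistics (probes need >= 2 samples in
#'   each group at a timepoint to be tested there).
#' @export
one_color_stats <- function(spots, group_a = "MgHI", group_b = "Ctrl",
                            contrast = "mghi_ctrl", var_equal = TRUE) {
  assert_cols(spots, c("probe_id", "condition", "timepoint", "signal"),
              "spots")
  carry <- intersect("gene_symbol", names(spots))
  tps <- intersect(unique(spots$timepoint[spots$condition == group_a]),
                   unique(spots$timepoint[spots$condition == group_b]))
  moments <- spots %>%
    filter(.data$condition %in% c(group_a, group_b),
           .data$timepoint %in% tps) %>%
    mutate(grp = if_else(.data$condition == group_a, "a", "b"),
           value = log2(.data$signal)) %>%
    group_by(across(all_of(c("probe_id", carry, "timepoint", "grp")))) %>%
    summarise(n = n(), m = mean(.data$value), v = stats::var(.data$value),
              .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "grp", values_from = c("n", "m", "v")) %>%
    filter(!is.na(.data$n_a) & !is.na(.data$n_b),
           .data$n_a >= 2, .data$n_b >= 2)
  res <- t2_from_moments(moments$m_a, moments$v_a, moments$n_a,
                         moments$m_b, moments$v_b, moments$n_b,
                         var_equal = var_equal)
  moments %>%
    mutate(contrast = contrast,
           n = .data$n_a + .data$n_b,
           mean_log2_ratio = .data$m_a - .data$m_b,
           t_stat = res$t, p_raw = res$p, degenerate = res$degenerate,
           fc = signed_fc(.data$mean_log2_ratio)) %>%
    group_by(.data$timepoint) %>%
    mutate(p_bh = bh_adjust(.data$p_raw)) %>%
    ungroup() %>%
    select(all_of(c("probe_id", carry)), "contrast", "timepoint", "n",
           "mean_log2_ratio", "t_stat", "p_raw", "p_bh", "degenerate", "fc")
}

#' Apply the fold-change / p-value selection rule
#'
#' Default rule `"union"` calls an entity when |FC| >= `fc_threshold` or the
#' (BH-adjusted) p-value is <= `p_threshold`; `"intersection"` requires
#' both; `"p_only"` ignores the fold change. Direction is the sign of the
#' mean log2 ratio for called entities, `"none"` otherwise; an exactly zero
#' mean is never called.
#'
#' @param stats Statistics tibble with `mean_log2_ratio` and the p column.
#' @param fc_threshold Linear fold-change threshold.
#' @param p_threshold p-value threshold.
#' @param rule `"union"`, `"intersection"` or `"p_only"`.
#' @param p_col Which p-value column the rule thresholds (default BH).
#' @return `stats` with `called` and `direction` columns.
#' @export
call_differential <- function(stats, fc_threshold = 2, p_threshold = 0.05,
                              rule = c("union", "intersection", "p_only"),
                              p_col = "p_bh") {
  rule <- match.arg(rule)
  assert_cols(stats, c("mean_log2_ratio", p_col), "stats")
  assert_scalar_number(fc_threshold, "fc_threshold", min = 1e-12)
  assert_scalar_number(p_threshold, "p_threshold", min = 0, max = 1)
  fc_ok <- abs(stats$mean_log2_ratio) >= log2(fc_threshold)
  p_ok <- stats[[p_col]] <= p_threshold
  called <- switch(rule,
                   union = fc_ok | p_ok,
                   intersection = fc_ok & p_ok,
                   p_only = p_ok)
  called <- called & stats$mean_log2_ratio != 0
  stats %>%
    mutate(called = called,
           direction = case_when(
             !called ~ "none",
             .data$mean_log2_ratio > 0 ~ "induced",
             .default = "repressed"))
}

#' Merge per-timepoint calls into a directional gene list
#'
#' A gene enters the merged list when called at one or more timepoints of a
#' contrast, in either direction. Genes called in opposite directions at
#' different timepoints are flagged biphasic; splice conflicts (from
#' [resolve_multiprobe()]) are carried through. Both kinds keep both
#' direction entries. The per-gene kinetics profile and the peak timepoint
#' (the one with most called genes) are attached as attributes.
#'
#' @param gene_stats Gene-level called statistics for a single contrast
#'   (columns `gene_symbol`, `timepoint`, `direction`, `called`, optionally
#'   `splice_conflict`).
#' @param name Name for the resulting list (default: the contrast label).
#' @return A [gene_list()] with attributes `kinetics` (tibble gene x
#'   timepoint directions, `biphasic` flag), `peak_timepoint` and
#'   `n_at_peak`; see [kinetics()].
#' @export
merge_timepoints <- function(gene_stats, name = NULL) {
  assert_cols(gene_stats, c("gene_symbol", "timepoint", "direction", "called"),
              "gene_stats")
  if ("contrast" %in% names(gene_stats)) {
    ctr <- unique(gene_stats$contrast)
    if (length(ctr) > 1) {
      abort("`gene_stats` holds several contrasts; merge one at a time")
    }
    name <- name %||% ctr
  }
  name <- name %||% "merged"
  if (!"splice_conflict" %in% names(gene_stats)) {
    gene_stats$splice_conflict <- FALSE
  }
  calls <- gene_stats %>% filter(.data$called)

  kin <- calls %>%
    group_by(.data$gene_symbol) %>%
    summarise(
      n_timepoints = n_distinct(.data$timepoint),
      timepoints = paste(unique(.data$timepoint), collapse = ","),
      biphasic = n_distinct(.data$direction) > 1 &&
        n_distinct(.data$timepoint) > 1,
      splice_conflict = any(.data$splice_conflict),
      .groups = "drop") %>%
    rename(gene = "gene_symbol")

  per_tp <- calls %>% count(.data$timepoint, name = "n_called")
  peak <- if (nrow(per_tp) > 0) {
    per_tp %>% arrange(desc(.data$n_called), .data$timepoint) %>% slice_head(n = 1)
  } else {
    tibble(timepoint = NA_character_, n_called = 0L)
  }

  entries <- calls %>%
    distinct(gene = .data$gene_symbol, .data$direction) %>%
    left_join(kin, by = "gene")
  out <- gene_list(entries, name = name)
  attr(out, "kinetics") <- kin
  attr(out, "per_timepoint") <- per_tp
  attr(out, "peak_timepoint") <- peak$timepoint[1]
  attr(out, "n_at_peak") <- peak$n_called[1]
  out
}

#' Kinetics profile attached to a merged gene list
#' @param x Result of [merge_timepoints()].
#' @return Tibble with per-gene called timepoints and flags.
#' @export
kinetics <- function(x) attr(x, "kinetics") %||% tibble()

#' Amplitude summary of a directional gene list
#'
#' Median and quartiles (linear interpolation, R type 7) of the linear fold
#' changes per direction, signed as printed (repressions negative), plus a
#' two-sided Wilcoxon rank-sum p comparing the |FC| distributions between
#' the induced and repressed entries.
#'
#' @param fc_table Tibble with `direction` (`induced`/`repressed`) and `fc`
#'   (signed linear fold change) per gene.
#' @return Tibble with one row per direction: `n`, `median_fc`, `q1`, `q3`,
#'   `ranksum_p`.
#' @export
amplitude_summary <- function(fc_table) {
  assert_cols(fc_table, c("direction", "fc"), "fc_table")
  fc_table <- fc_table %>% filter(.data$direction %in% c("induced", "repressed"))
  present <- unique(fc_table$direction)
  if (length(present) < 2) {
    warn(sprintf("direction(s) missing from input: %s",
                 paste(setdiff(c("induced", "repressed"), present),
                       collapse = ", ")))
  }
  p <- if (length(present) == 2) {
    suppressWarnings(stats::wilcox.test(
      abs(fc_table$fc[fc_table$direction == "induced"]),
      abs(fc_table$fc[fc_table$direction == "repressed"]))$p.value)
  } else {
    NA_real_
  }
  fc_table %>%
    group_by(.data$direction) %>%
    summarise(n = n(),
              median_fc = stats::median(.data$fc),
              q1 = stats::quantile(.data$fc, 0.25, names = FALSE),
              q3 = stats::quantile(.data$fc, 0.75, names = FALSE),
              .groups = "drop") %>%
    mutate(ranksum_p = p)
}

#' One-color equivalence calls (no difference between groups)
#'
#' Operationalizes "no difference in the one-color comparison" as an
#' equivalence band rather than mere absence of significance: the raw p must
#' exceed `p_gt` and the absolute mean log2 difference must stay below
#' `max_abs_log2`, at every timepoint. Genes lacking a usable one-color
#' measurement at one of the tested timepoints are never declared
#' equivalent: absence of data is not evidence of absence of difference.
#'
#' @param stats One-color gene-level statistics (from [one_color_stats()]
#'   after [resolve_multiprobe()]), with `gene_symbol`, `timepoint`,
#'   `mean_log2_ratio`, `p_raw`.
#' @param p_gt Raw p-value that must be exceeded.
#' @param max_abs_log2 Upper bound on the absolute mean log2 difference
#'   (default `log2(1.5)`).
#' @return Character vector of genes satisfying the band everywhere.
#' @export
equivalence_genes <- function(stats, p_gt = 0.05, max_abs_log2 = log2(1.5)) {
  assert_cols(stats, c("gene_symbol", "timepoint", "mean_log2_ratio", "p_raw"),
              "stats")
  n_tp <- n_distinct(stats$timepoint)
  stats %>%
    group_by(.data$gene_symbol) %>%
    summarise(equiv = n_distinct(.data$timepoint) == .env$n_tp &&
                all(.data$p_raw > .env$p_gt &
                      abs(.data$mean_log2_ratio) < .env$max_abs_log2),
              .groups = "drop") %>%
    filter(.data$equiv) %>%
    pull("gene_symbol")
}
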