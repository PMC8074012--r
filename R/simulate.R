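#' Simulate a treatment-by-insult microarray study with planted truth
#'
#' Generates probe-level two-color log2 ratios for the three contrasts
#' (Mg-vs-Ctrl at the experiment-1 timepoints; MgHI-vs-HI and HI-vs-Ctrl at
#' the experiment-2/3 timepoints) and one-color channel intensities for the
#' Ctrl, Mg, HI and MgHI groups, together with the design table, the probe
#' annotation and a truth table recording every gene's planted class and
#' expected downstream category.
#'
#' Measurements are drawn at the normalized log2 scale: each spot is the
#' planted effect plus i.i.d. normal noise of sd `noise_sd_log2`. One-color
#' intensities are a per-probe baseline (log2-uniform between 10.5 and 14.5,
#' comfortably above the detection floor so that detection failures are
#' governed by the injected artifact fraction alone, and shared across all
#' groups so pooling control channels across experiments is well-defined)
#' plus the group effect plus noise; backgrounds are
#' `background_level` with mild log-normal jitter. Ratio and intensity noise
#' are independent draws.
#'
#' @param config A [sim_config()] object.
#' @param artifacts If `TRUE` (default), [inject_artifacts()] is applied.
#'
#' @return An object of class `mghi_sim`: a list with tibbles `two_color`
#'   (spot-level log2 ratios), `one_color` (spot-level linear signal and
#'   background), `design`, `probes` (annotation), `truth`, `truth_effects`
#'   (gene x contrast x timepoint planted log2 effects), `artifacts` (flag
#'   record) and the `config`.
#' @export
#' @examples
#' sim <- simulate_experiment(sim_config(seed = 1, n_genes = 50))
#' sim$truth
simulate_experiment <- function(config, artifacts = TRUE) {
  if (!inherits(config, "sim_config")) {
    abort("`config` must be created with sim_config()")
  }
  withr::local_seed(config$seed)
  e <- config$effect_size_log2
  k1 <- length(config$timepoints_exp1)

  ## ---- gene table with planted classes and signs ----
  class_vec <- allocate_classes(config$n_genes, config$class_proportions,
                                config$deterministic_allocation)
  genes <- tibble(
    gene = sprintf("G%05d", seq_len(config$n_genes)),
    planted_class = class_vec) %>%
    group_by(.data$planted_class) %>%
    mutate(sign = ifelse(row_number() %% 2 == 1, 1, -1)) %>%
    ungroup()

  ## ---- probes ----
  n_choices <- as.integer(names(config$probes_per_gene))
  n_probes <- sample(n_choices, config$n_genes, replace = TRUE,
                     prob = config$probes_per_gene)
  n_probes[genes$planted_class == "splice_discordant"] <- 2L
  probe_gene <- rep(genes$gene, times = n_probes)
  probes <- tibble(gene_symbol = probe_gene, status = "gene") %>%
    group_by(.data$gene_symbol) %>%
    mutate(probe_rank = row_number()) %>%
    ungroup()
  n_gene_probes <- nrow(probes)
  n_rik <- round(config$frac_riken * n_gene_probes)
  n_ctl <- round(config$frac_control * n_gene_probes)
  extra <- bind_rows(
    tibble(gene_symbol = sprintf("Rik%04d", seq_len(n_rik)),
           status = "riken", probe_rank = 1L),
    tibble(gene_symbol = rep(NA_character_, n_ctl),
           status = "control", probe_rank = 1L))
  probes <- bind_rows(probes, extra) %>%
    mutate(probe_id = sprintf("P%06d", row_number())) %>%
    select("probe_id", "gene_symbol", "status", "probe_rank")

  ## ---- planted gene-level effects ----
  truth_effects <- gene_truth_effects(genes, config)

  ## ---- probe-level effects (splice-discordant genes diverge by probe) ----
  probe_effects <- probes %>%
    filter(.data$status == "gene") %>%
    inner_join(genes, by = c(gene_symbol = "gene")) %>%
    inner_join(truth_effects, by = c(gene_symbol = "gene"),
               relationship = "many-to-many") %>%
    mutate(effect = .data$true_log2_effect)
  peak_tp <- config$timepoints_exp1[ceiling((k1 + 1) / 2)]
  is_splice <- probe_effects$planted_class == "splice_discordant" &
    probe_effects$contrast == "mg" & probe_effects$timepoint == peak_tp
  probe_effects$effect[is_splice] <-
    with(probe_effects[is_splice, ],
         ifelse(probe_rank == 1, sign * e, -sign * e))
  probe_effects <- probe_effects %>%
    select("probe_id", "contrast", "timepoint", "effect")

  ## ---- two-color spot tables ----
  contrast_tp <- bind_rows(
    tibble(contrast = "mg", timepoint = config$timepoints_exp1),
    tibble(contrast = "mghi_hi", timepoint = config$timepoints_exp23),
    tibble(contrast = "hi", timepoint = config$timepoints_exp23))
  two_color <- tidyr::crossing(
    probes %>% select("probe_id"),
    contrast_tp,
    replicate = seq_len(config$n_replicates)) %>%
    left_join(probe_effects, by = c("probe_id", "contrast", "timepoint")) %>%
    mutate(effect = tidyr::replace_na(.data$effect, 0),
           sample_id = sprintf("%s_%s_r%d", .data$contrast, .data$timepoint,
                               .data$replicate)) %>%
    arrange(.data$contrast, .data$timepoint, .data$replicate, .data$probe_id)
  two_color$log2_ratio <- two_color$effect +
    stats::rnorm(nrow(two_color), 0, config$noise_sd_log2)
  two_color <- two_color %>%
    mutate(uniform = TRUE) %>%
    select("probe_id", "contrast", "timepoint", "replicate", "sample_id",
           "log2_ratio", "uniform")

  ## ---- one-color spot tables ----
  baseline <- tibble(probe_id = probes$probe_id,
                     base_log2 = stats::runif(nrow(probes), 10.5, 14.5))
  oc_samples <- bind_rows(
    tidyr::crossing(experiment = "exp1", timepoint = config$timepoints_exp1,
                    replicate = seq_len(config$n_replicates),
                    tibble(condition = c("Ctrl", "Mg"),
                           channel = c("Cy3", "Cy5"))),
    tidyr::crossing(experiment = "exp2", timepoint = config$timepoints_exp23,
                    replicate = seq_len(config$n_replicates),
                    tibble(condition = c("HI", "MgHI"),
                           channel = c("Cy3", "Cy5"))),
    tidyr::crossing(experiment = "exp3", timepoint = config$timepoints_exp23,
                    replicate = seq_len(config$n_replicates),
                    tibble(condition = c("Ctrl", "HI"),
                           channel = c("Cy3", "Cy5")))) %>%
    mutate(sample_id = sprintf("%s_%s_%s_r%d", .data$experiment,
                               .data$condition, .data$timepoint,
                               .data$replicate))
  cond_contrast <- c(Ctrl = NA_character_, Mg = "mg", HI = "hi",
                     MgHI = "mghi_ctrl")
  one_color <- tidyr::crossing(probes %>% select("probe_id"), oc_samples) %>%
    mutate(eff_contrast = cond_contrast[.data$condition]) %>%
    left_join(probe_effects,
              by = c(probe_id = "probe_id", eff_contrast = "contrast",
                     timepoint = "timepoint")) %>%
    mutate(effect = tidyr::replace_na(.data$effect, 0)) %>%
    left_join(baseline, by = "probe_id") %>%
    arrange(.data$experiment, .data$timepoint, .data$replicate,
            .data$condition, .data$probe_id)
  n_oc <- nrow(one_color)
  one_color$signal <- 2^(one_color$base_log2 + one_color$effect +
                           stats::rnorm(n_oc, 0, config$noise_sd_log2))
  one_color$background <- config$background_level *
    2^stats::rnorm(n_oc, 0, 0.15)
  one_color <- one_color %>%
    mutate(uniform = TRUE) %>%
    select("probe_id", "experiment", "condition", "timepoint", "replicate",
           "sample_id", "signal", "background", "uniform")

  ## ---- design ----
  design <- bind_rows(
    two_color %>%
      distinct(.data$sample_id, .data$contrast, .data$timepoint,
               .data$replicate) %>%
      mutate(experiment = c(mg = "exp1", mghi_hi = "exp2",
                            hi = "exp3")[.data$contrast],
             condition = c(mg = "Mg_vs_Ctrl", mghi_hi = "MgHI_vs_HI",
                           hi = "HI_vs_Ctrl")[.data$contrast],
             channel = "log2ratio") %>%
      select("sample_id", "experiment", "condition", "timepoint",
             "replicate", "channel"),
    oc_samples %>%
      select("sample_id", "experiment", "condition", "timepoint",
             "replicate", "channel"))

  truth <- genes %>%
    mutate(expected_category = planted_expectation(.data$planted_class)) %>%
    select("gene", "planted_class", "expected_category")

  sim <- structure(
    list(two_color = two_color, one_color = one_color, design = design,
         probes = probes %>% select("probe_id", "gene_symbol", "status"),
         truth = truth, truth_effects = truth_effects,
         artifacts = tibble(table = character(), probe_id = character(),
                            sample_id = character(), type = character()),
         config = config),
    class = "mghi_sim")
  if (artifacts) sim <- inject_artifacts(sim) else sim
}

# deterministic largest-remainder quotas, or a multinomial draw
allocate_classes <- function(n, props, deterministic) {
  cls <- names(props)
  if (deterministic) {
    raw <- n * props
    counts <- floor(raw)
    rem <- n - sum(counts)
    if (rem > 0) {
      ord <- order(raw - counts, decreasing = TRUE)
      counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
    }
  } else {
    counts <- as.vector(stats::rmultinom(1, n, props))
    names(counts) <- cls
  }
  rep(cls, times = counts)
}

# gene-level planted log2 effects on the full contrast x timepoint grid
gene_truth_effects <- function(genes, config) {
  e <- config$effect_size_log2
  k1 <- length(config$timepoints_exp1)
  mid_idx <- if (k1 >= 3) seq(2, k1 - 1) else seq_len(k1)
  bi_idx <- if (k1 >= 3) c(2L, 3L) else c(1L, min(2L, k1))
  grid <- bind_rows(
    tibble(contrast = "mg", timepoint = config$timepoints_exp1,
           tp_idx = seq_len(k1)),
    tidyr::crossing(contrast = c("mghi_hi", "hi", "mghi_ctrl"),
                    tibble(timepoint = config$timepoints_exp23,
                           tp_idx = seq_along(config$timepoints_exp23))))
  tidyr::crossing(genes, grid) %>%
    mutate(true_log2_effect = case_when(
      .data$planted_class == "mg_only" & .data$contrast == "mg" &
        .data$tp_idx %in% mid_idx ~ .data$sign * e,
      .data$planted_class == "biphasic" & .data$contrast == "mg" &
        .data$tp_idx == bi_idx[1] ~ .data$sign * e,
      .data$planted_class == "biphasic" & .data$contrast == "mg" &
        .data$tp_idx == bi_idx[2] ~ -.data$sign * e,
      .data$planted_class == "de_novo" &
        .data$contrast %in% c("mghi_hi", "mghi_ctrl") ~ .data$sign * e,
      .data$planted_class == "reversed" & .data$contrast == "hi" ~
        .data$sign * e,
      .data$planted_class == "reversed" & .data$contrast == "mghi_hi" ~
        -.data$sign * e,
      .data$planted_class == "amplified" & .data$contrast %in%
        c("hi", "mghi_hi") ~ .data$sign * e,
      .data$planted_class == "amplified" & .data$contrast == "mghi_ctrl" ~
        2 * .data$sign * e,
      .data$planted_class == "insensitive" &
        .data$contrast %in% c("hi", "mghi_ctrl") ~ .data$sign * e,
      .data$planted_class == "hi_only" & .data$tp_idx == 1L &
        .data$contrast %in% c("hi", "mghi_ctrl") ~ .data$sign * e,
      .default = 0)) %>%
    select("gene", "contrast", "timepoint", "true_log2_effect")
}

#' Inject spot-quality and detection artifacts
#'
#' Flags a fraction of spots as non-uniform (Bernoulli per spot, both color
#' modes), and picks a fraction of probes to emulate transcripts expressed
#' below the detection level: every one-color spot of such a probe is pushed
#' to at most twice its local background, so the downstream detection filter
#' removes the probe. Dimming is probe-level because lack of detection is a
#' property of the transcript's abundance, not of single spots; a lone
#' background-level spot on an otherwise bright probe would be a uniformity
#' failure, which the spot-level flag already models. All draws are seeded
#' from the simulation seed and every altered spot is recorded in the
#' `artifacts` table so QC recovery can be verified exactly.
#'
#' @param sim An `mghi_sim` object from [simulate_experiment()].
#' @param config A [sim_config()]; defaults to the one stored in `sim`.
#'
#' @return The `mghi_sim` object with flags applied and `artifacts` filled.
#' @export
inject_artifacts <- function(sim, config = sim$config) {
  if (!inherits(sim, "mghi_sim")) abort("`sim` must be an mghi_sim object")
  withr::local_seed(config$seed + 1L)

  tc_bad <- stats::runif(nrow(sim$two_color)) < config$frac_low_quality
  oc_bad <- stats::runif(nrow(sim$one_color)) < config$frac_low_quality
  all_probes <- unique(sim$one_color$probe_id)
  dim_probes <- all_probes[stats::runif(length(all_probes)) <
                             config$frac_below_detection]
  oc_dim <- sim$one_color$probe_id %in% dim_probes

  sim$two_color$uniform[tc_bad] <- FALSE
  sim$one_color$uniform[oc_bad] <- FALSE
  n_dim <- sum(oc_dim)
  if (n_dim > 0) {
    sim$one_color$signal[oc_dim] <- 2 * sim$one_color$background[oc_dim] *
      stats::runif(n_dim, 0.2, 1)
  }

  sim$artifacts <- bind_rows(
    tibble(table = "two_color",
           probe_id = sim$two_color$probe_id[tc_bad],
           sample_id = sim$two_color$sample_id[tc_bad],
           type = "low_quality"),
    tibble(table = "one_color",
           probe_id = sim$one_color$probe_id[oc_bad],
           sample_id = sim$one_color$sample_id[oc_bad],
           type = "low_quality"),
    tibble(table = "one_color",
           probe_id = sim$one_color$probe_id[oc_dim],
           sample_id = sim$one_color$sample_id[oc_dim],
           type = "below_detection"))
  sim
}

#' @export
print.mghi_sim <- function(x, ...) {
  cat("<mghi_sim>\n")
  cat(sprintf("  %d genes, %d probes; %d two-color spots, %d one-color spots\n",
              nrow(x$truth), nrow(x$probes), nrow(x$two_color),
              nrow(x$one_color)))
  cat(sprintf("  artifacts injected: %d\n", nrow(x$artifacts)))
  invisible(x)
}
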