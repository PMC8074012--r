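#' Planted effect classes of the synthetic generator
#'
#' Each simulated gene carries one class describing how the treatment (Mg),
#' the insult (HI) and their combination (MgHI) act on it:
#'
#' * `null` - no effect anywhere.
#' * `mg_only` - Mg effect in naive animals that vanishes in the insult
#'   context (proper treatment effect, List A only).
#' * `hi_only` - insult effect at a single timepoint, unchanged by the
#'   treatment (ends up insult-insensitive, List C).
#' * `de_novo` - effect present in MgHI-vs-HI and MgHI-vs-Ctrl but absent
#'   from HI-vs-Ctrl (List B1).
#' * `reversed` - insult effect abolished by pretreatment: opposite signs in
#'   HI-vs-Ctrl and MgHI-vs-HI, near-zero MgHI-vs-Ctrl (List B2).
#' * `amplified` - insult effect enlarged by pretreatment: same sign in
#'   HI-vs-Ctrl and MgHI-vs-HI, larger MgHI-vs-Ctrl magnitude (List B3).
#' * `insensitive` - insult effect identical with or without pretreatment
#'   (List C).
#' * `biphasic` - treatment effect with successive opposite directions at
#'   two timepoints (both directions of List A).
#' * `splice_discordant` - two probes of the same gene with opposite effects
#'   at one timepoint (both directions of List A, splice conflict flag).
#'
#' @return Character vector of class labels.
#' @export
planted_classes <- function() {
  c("null", "mg_only", "hi_only", "de_novo", "reversed", "amplified",
    "insensitive", "biphasic", "splice_discordant")
}

#' Default mixture of planted classes
#'
#' A realistic bulk-brain mixture: a slight majority of unaffected genes and a
#' few hundred genes per interaction class at the default 2,000-gene scale.
#'
#' @return Named numeric vector summing to 1.
#' @export
default_class_proportions <- function() {
  c(null = 0.55, mg_only = 0.08, hi_only = 0.05, de_novo = 0.08,
    reversed = 0.06, amplified = 0.05, insensitive = 0.06,
    biphasic = 0.035, splice_discordant = 0.035)
}

# category each planted class should receive from the downstream pipeline
planted_expectation <- function(planted_class) {
  map <- c(null = "unaffected", mg_only = "mg_only", hi_only = "insensitive",
           de_novo = "de_novo", reversed = "reversed", amplified = "amplified",
           insensitive = "insensitive", biphasic = "mg_only",
           splice_discordant = "mg_only")
  unname(map[planted_class])
}

#' Configure a synthetic treatment-by-insult microarray experiment
#'
#' Describes the three-experiment layout used throughout the package:
#' experiment 1 compares treated (Mg) to control brains on two-color arrays at
#' five timepoints, experiment 2 compares pretreated-plus-insult (MgHI) to
#' insult-only (HI) at two timepoints, and experiment 3 compares HI to control
#' at the same two timepoints, with `n_replicates` arrays per
#' contrast/timepoint. One-color channel intensities of every array are
#' simulated alongside the log-ratios so that the one-color MgHI-vs-Ctrl
#' comparison (pooling control channels of experiments 1 and 3) is available.
#'
#' @param seed Integer seed; mandatory, every run is fully reproducible.
#' @param n_genes Number of genes to simulate.
#' @param probes_per_gene Named probability vector over probe counts
#'   `c("1" = ..., "2" = ..., "3" = ...)`.
#' @param n_replicates Arrays per contrast and timepoint (>= 2).
#' @param timepoints_exp1 Ordered timepoint labels of experiment 1.
#' @param timepoints_exp23 Ordered timepoint labels of experiments 2 and 3.
#' @param class_proportions Named vector over [planted_classes()] summing to 1.
#' @param effect_size_log2 Planted |log2| effect size.
#' @param noise_sd_log2 Standard deviation of the i.i.d. normal measurement
#'   noise on the log2 scale (per spot).
#' @param background_level Typical one-color local background (linear scale).
#' @param frac_low_quality Fraction of spots flagged non-uniform.
#' @param frac_below_detection Fraction of one-color spots pushed to or below
#'   twice their background (detection failures).
#' @param frac_riken Riken-clone probes added, as a fraction of gene probes.
#' @param frac_control Control probes added, as a fraction of gene probes.
#' @param deterministic_allocation If `TRUE` (default) class counts are exact
#'   quotas (largest-remainder rounding of `n_genes * proportion`); if `FALSE`
#'   classes are drawn multinomially.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed,
                       n_genes = 2000,
                       probes_per_gene = c("1" = 0.7, "2" = 0.2, "3" = 0.1),
                       n_replicates = 3,
                       timepoints_exp1 = c("1.5h", "3h", "6h", "12h", "24h"),
                       timepoints_exp23 = c("3h", "12h"),
                       class_proportions = default_class_proportions(),
                       effect_size_log2 = 2,
                       noise_sd_log2 = 0.25,
                       background_level = 30,
                       frac_low_quality = 0.02,
                       frac_below_detection = 0.02,
                       frac_riken = 0.05,
                       frac_control = 0.02,
                       deterministic_allocation = TRUE) {
  if (missing(seed) || is.null(seed)) {
    abort("`seed` is mandatory: simulations must be reproducible")
  }
  assert_scalar_number(seed, "seed")
  assert_scalar_number(n_genes, "n_genes", min = 1)
  assert_scalar_number(n_replicates, "n_replicates", min = 2)
  assert_scalar_number(effect_size_log2, "effect_size_log2", min = 1e-12)
  assert_scalar_number(noise_sd_log2, "noise_sd_log2", min = 0)
  assert_scalar_number(background_level, "background_level", min = 1e-12)
  for (f in c("frac_low_quality", "frac_below_detection",
              "frac_riken", "frac_control")) {
    assert_scalar_number(get(f), f, min = 0, max = 1)
  }
  if (!all(names(probes_per_gene) %in% c("1", "2", "3")) ||
      abs(sum(probes_per_gene) - 1) > 1e-9 || any(probes_per_gene < 0)) {
    abort("`probes_per_gene` must be a probability vector over counts 1..3")
  }
  if (is.null(names(class_proportions)) ||
      !all(names(class_proportions) %in% planted_classes())) {
    abort(sprintf("`class_proportions` names must be among: %s",
                  paste(planted_classes(), collapse = ", ")))
  }
  if (abs(sum(class_proportions) - 1) > 1e-9 || any(class_proportions < 0)) {
    abort("`class_proportions` must be nonnegative and sum to 1 (within 1e-9)")
  }
  if (length(timepoints_exp1) < 1 || length(timepoints_exp23) < 1) {
    abort("timepoint label vectors must be nonempty")
  }

  structure(
    list(seed = as.integer(seed),
         n_genes = as.integer(n_genes),
         probes_per_gene = probes_per_gene,
         n_replicates = as.integer(n_replicates),
         timepoints_exp1 = as.character(timepoints_exp1),
         timepoints_exp23 = as.character(timepoints_exp23),
         class_proportions = class_proportions,
         effect_size_log2 = effect_size_log2,
         noise_sd_log2 = noise_sd_log2,
         background_level = background_level,
         frac_low_quality = frac_low_quality,
         frac_below_detection = frac_below_detection,
         frac_riken = frac_riken,
         frac_control = frac_control,
         deterministic_allocation = isTRUE(deterministic_allocation)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  genes: %d  replicates: %d  seed: %d\n",
              x$n_genes, x$n_replicates, x$seed))
  cat(sprintf("  exp1 timepoints: %s\n", paste(x$timepoints_exp1, collapse = ", ")))
  cat(sprintf("  exp2/3 timepoints: %s\n", paste(x$timepoints_exp23, collapse = ", ")))
  cat(sprintf("  effect %.2f log2, noise sd %.3f log2\n",
              x$effect_size_log2, x$noise_sd_log2))
  pp <- x$class_proportions[x$class_proportions > 0]
  cat(sprintf("  classes: %s\n",
              paste(sprintf("%s=%.3g", names(pp), pp), collapse = " ")))
  invisible(x)
}
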