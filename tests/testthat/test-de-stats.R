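test_that("one-sample t matches the t distribution oracle and conventions", {
  out <- one_sample_t(c(1.0, 1.2, 0.8))
  expect_equal(out$t_stat, 8.6602540378, tolerance = 1e-9)
  expect_equal(out$p_value, 0.0130724576, tolerance = 1e-8)
  expect_identical(out$df, 2)

  z <- one_sample_t(c(0, 0, 0))
  expect_identical(z$p_value, 1)
  expect_false(z$degenerate)
  cc <- one_sample_t(c(0.5, 0.5, 0.5))
  expect_identical(cc$p_value, 0)
  expect_true(cc$degenerate)
  expect_error(one_sample_t(1), "at least 2")
})

test_that("two-group t matches the pooled oracle and is antisymmetric", {
  a <- c(1, 1.1, 0.9)
  b <- c(0, 0.1, -0.1)
  out <- two_group_t(a, b)
  expect_equal(out$estimate, 1.0, tolerance = 1e-12)
  expect_equal(out$t_stat, 12.2474487139, tolerance = 1e-9)
  expect_equal(out$p_value, 0.000255216749, tolerance = 1e-8)

  swapped <- two_group_t(b, a)
  expect_equal(swapped$t_stat, -out$t_stat, tolerance = 1e-12)
  expect_equal(swapped$p_value, out$p_value, tolerance = 1e-12)

  same <- two_group_t(c(1, 2, 3), c(1, 2, 3))
  expect_identical(same$t_stat, 0)
  expect_identical(same$p_value, 1)

  welch <- two_group_t(a, c(b, 0.4, -0.4), var_equal = FALSE)
  oracle <- stats::t.test(a, c(b, 0.4, -0.4))
  expect_equal(welch$p_value, oracle$p.value, tolerance = 1e-9)
  expect_error(two_group_t(a, 1), "at least 2")
})

test_that("BH adjustment follows the step-up formula and its invariances", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_identical(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(4)
  for (i in 1:10) {
    p <- stats::runif(50)
    adj <- bh_adjust(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    # monotone in rank
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
    # invariant to input order
    perm <- sample(50)
    expect_equal(bh_adjust(p[perm]), adj[perm])
    # thresholding adjusted values reproduces the classical step-up rule
    for (alpha in c(0.05, 0.2)) {
      m <- length(p)
      ps <- sort(p)
      passing <- which(ps <= alpha * seq_len(m) / m)
      cutoff <- if (length(passing)) ps[max(passing)] else -Inf
      expect_identical(adj <= alpha, p <= cutoff)
    }
  }
})

test_that("the union calling rule behaves as specified at its boundaries", {
  stats <- tibble::tibble(
    mean_log2_ratio = c(log2(2.14), log2(1.3), log2(1.3), 0),
    p_bh = c(0.2, 0.01, 0.2, 0.001))
  out <- call_differential(stats)
  expect_identical(out$called, c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(out$direction, c("induced", "induced", "none", "none"))

  both <- call_differential(stats, rule = "intersection")
  expect_identical(both$called, rep(FALSE, 4))
  ponly <- call_differential(stats, rule = "p_only", p_threshold = 1)
  # calls every entity with a nonzero mean, never a zero mean
  expect_identical(ponly$called, c(TRUE, TRUE, TRUE, FALSE))
})

test_that("null simulation keeps the raw t rejection rate at its nominal level", {
  cfg <- sim_config(seed = 13, n_genes = 2000,
                    probes_per_gene = c("1" = 1),
                    class_proportions = c(null = 1),
                    frac_low_quality = 0, frac_below_detection = 0,
                    frac_riken = 0, frac_control = 0)
  sim <- simulate_experiment(cfg)
  st <- two_color_stats(sim$two_color[sim$two_color$contrast == "mg", ])
  rate <- mean(st$p_raw <= 0.05)
  n <- nrow(st)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n))
})

test_that("planted two-fold effects are called with high power under the union rule", {
  sim <- noisy_sim()
  st <- call_differential(two_color_stats(
    dplyr::semi_join(sim$two_color, sim$probes[sim$probes$status == "gene", ],
                     by = "probe_id")))
  truth <- sim$truth_effects
  probe_truth <- dplyr::inner_join(
    dplyr::rename(sim$probes[sim$probes$status == "gene", ],
                  gene = "gene_symbol"),
    truth, by = "gene", relationship = "many-to-many")
  joined <- dplyr::inner_join(
    st, probe_truth[abs(probe_truth$true_log2_effect) == 2,
                    c("probe_id", "contrast", "timepoint")],
    by = c("probe_id", "contrast", "timepoint"))
  expect_gt(mean(joined$called), 0.9)
})

test_that("timepoint merging keeps directions, flags biphasic genes, finds the peak", {
  gs <- tibble::tibble(
    gene_symbol = c("g1", "g2", "g2", "g3", "g4"),
    contrast = "mg",
    timepoint = c("3h", "3h", "12h", "6h", "3h"),
    direction = c("induced", "induced", "repressed", "none", "induced"),
    called = c(TRUE, TRUE, TRUE, FALSE, TRUE))
  ml <- merge_timepoints(gs)
  tb <- tibble::as_tibble(ml)
  expect_setequal(tb$gene[tb$direction == "induced"], c("g1", "g2", "g4"))
  expect_setequal(tb$gene[tb$direction == "repressed"], "g2")
  expect_true(all(tb$biphasic[tb$gene == "g2"]))
  expect_false(any(tb$gene == "g3"))
  expect_identical(attr(ml, "peak_timepoint"), "3h")
  expect_identical(attr(ml, "n_at_peak"), 3L)
  expect_identical(nrow(kinetics(ml)), 3L)
})

test_that("amplitude summaries report signed quartiles and a rank-sum p", {
  fc <- tibble::tibble(direction = rep(c("induced", "repressed"), c(3, 3)),
                       fc = c(1.5, 2.0, 2.5, -2.5, -2.0, -1.5))
  out <- amplitude_summary(fc)
  expect_equal(out$median_fc[out$direction == "repressed"], -2.0)
  expect_equal(out$median_fc[out$direction == "induced"], 2.0)
  expect_true(all(out$q1 <= out$median_fc & out$median_fc <= out$q3))
  # identical amplitude distributions: p near 1
  expect_gt(out$ranksum_p[1], 0.9)

  sep <- tibble::tibble(direction = rep(c("induced", "repressed"), c(20, 20)),
                        fc = c(rep(1.5, 20), rep(-3, 20)))
  expect_lt(amplitude_summary(sep)$ranksum_p[1], 0.001)

  expect_warning(one_dir <- amplitude_summary(fc[fc$direction == "induced", ]),
                 "missing")
  expect_true(is.na(one_dir$ranksum_p))
})

test_that("the equivalence band demands small, insignificant, complete records", {
  st <- tibble::tibble(
    gene_symbol = c("g1", "g1", "g2", "g2", "g3"),
    timepoint = c("3h", "12h", "3h", "12h", "3h"),
    mean_log2_ratio = c(0.1, -0.2, 0.1, 1.2, 0),
    p_raw = c(0.8, 0.5, 0.9, 0.001, 0.9))
  # g1 equivalent everywhere; g2 fails the band at 12h; g3 lacks a timepoint
  expect_identical(equivalence_genes(st), "g1")
})
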