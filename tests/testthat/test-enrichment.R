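test_that("Fisher right tail matches exhaustive summation and is monotone", {
  expect_identical(fisher_exact(0, 10, 10, 100), 1)
  expect_identical(fisher_exact(10, 10, 10, 10), 1)
  expect_equal(fisher_exact(5, 10, 10, 100), 6.7162774827e-04,
               tolerance = 1e-9)
  expect_equal(fisher_exact(5, 10, 10, 100),
               brute_hyper_tail(5, 10, 10, 100), tolerance = 1e-12)
  p <- fisher_exact(0:10, 10, 10, 100)
  expect_true(all(diff(p) < 0))
  expect_error(fisher_exact(11, 10, 10, 100), "inconsistent")
  expect_error(fisher_exact(2, 10, 10, 5), "inconsistent")
})

test_that("EASE score is the jackknifed Fisher tail", {
  expect_identical(ease_score(0, 10, 10, 100), 1)
  expect_identical(ease_score(1, 10, 10, 100), 1)
  expect_equal(ease_score(5, 10, 10, 100), fisher_exact(4, 10, 10, 100),
               tolerance = 1e-12)
  expect_equal(ease_score(5, 10, 10, 100), 8.2248764426e-03, tolerance = 1e-9)
  # jackknife always weakens the evidence
  k <- 1:10
  expect_true(all(ease_score(k, 10, 10, 100) >=
                    fisher_exact(k, 10, 10, 100)))
})

test_that("fold enrichment is the ratio of rates", {
  expect_identical(fold_enrichment(2, 20, 10, 100), 1)
  expect_identical(fold_enrichment(0, 10, 10, 100), 0)
  expect_identical(fold_enrichment(5, 10, 10, 100), 5)
  expect_error(fold_enrichment(0, 0, 10, 100), "positive")
})

test_that("enrichment table carries counts, statistics and filters", {
  universe <- sprintf("u%03d", 1:100)
  sets <- list(hit = universe[1:15], other = universe[16:40],
               tiny = universe[41:45], empty = c("zzz"))
  expect_warning(
    out <- enrich(universe[1:15], sets, universe, profile = "keyword"),
    "empty")
  # the exactly-recovered set has the smallest p
  expect_identical(out$set_name[1], "hit")
  expect_identical(out$k[out$set_name == "hit"], 15L)
  expect_equal(out$fe, (out$k / out$n) / (out$K / out$N))
  expect_true(all(out$k <= pmin(out$n, out$K)))
  expect_true(all(out$p_ease >= out$p_fisher - 1e-12))
  # sets below the count filter cannot pass, whatever their p
  expect_false(out$passes_filter[out$set_name == "tiny"])
  expect_true(out$passes_filter[out$set_name == "hit"])
  # invariant to set ordering
  out2 <- suppressWarnings(enrich(universe[1:15], rev(sets), universe,
                                  profile = "keyword"))
  expect_identical(dplyr::arrange(out, set_name),
                   dplyr::arrange(out2, set_name))
  expect_error(suppressWarnings(enrich("absent", sets, universe)),
               "no genes")
})

test_that("Bonferroni filtering keeps the family-wise error near its level", {
  set.seed(8)
  universe <- sprintf("u%03d", 1:200)
  sets <- lapply(1:10, function(i) sample(universe, 20))
  names(sets) <- paste0("s", 1:10)
  n_sims <- 400
  any_hit <- logical(n_sims)
  for (i in seq_len(n_sims)) {
    q <- sample(universe, 20)
    tab <- enrich(q, sets, universe, profile = "none")
    any_hit[i] <- any(tab$p_bonferroni < 0.05)
  }
  rate <- mean(any_hit)
  # discreteness keeps the empirical FWER at or below ~5%
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / n_sims))
})

test_that("random queries give conservative, super-uniform Fisher p-values", {
  set.seed(21)
  universe <- sprintf("u%03d", 1:150)
  gset <- list(s = universe[1:30])
  p <- replicate(300, {
    q <- sample(universe, 15)
    enrich(q, gset, universe, profile = "none")$p_fisher
  })
  for (alpha in c(0.05, 0.1, 0.25)) {
    expect_lt(mean(p <= alpha), alpha + 3 * sqrt(alpha * (1 - alpha) / 300))
  }
})

test_that("regulator z-scores follow the sign-consistency formula", {
  universe <- c(sprintf("t%02d", 1:20), "x1", "x2")
  net <- tibble::tibble(regulator = "R", target = sprintf("t%02d", 1:10),
                        sign = 1)
  all_up <- gl("q", up = sprintf("t%02d", 1:10))
  out <- regulator_zscore(all_up, net, universe)
  expect_equal(out$z, 10 / sqrt(10), tolerance = 1e-12)
  expect_identical(out$predicted_state, "activated")

  half <- gl("q", up = sprintf("t%02d", 1:5), down = sprintf("t%02d", 6:10))
  out2 <- regulator_zscore(half, net, universe)
  expect_identical(out2$z, 0)
  expect_identical(out2$predicted_state, "undetermined")

  # z = -2 exactly is not significant (strict inequality)
  four_down <- gl("q", down = sprintf("t%02d", 1:4))
  net4 <- net[1:4, ]
  out3 <- regulator_zscore(four_down, net4, universe)
  expect_identical(out3$z, -2)
  expect_identical(out3$predicted_state, "undetermined")

  # regulators without overlapping directional targets are omitted
  lonely <- tibble::tibble(regulator = "L", target = "x9", sign = 1)
  expect_identical(nrow(regulator_zscore(all_up, lonely, universe)), 0L)
  expect_error(regulator_zscore(all_up, dplyr::bind_rows(net, net[1, ]),
                                universe), "unique")
})

test_that("ontogeny concordance labels anticipation vs antagonism", {
  dev <- tibble::tibble(gene = c("a", "b", "c"),
                        developmental_direction = c("increasing",
                                                    "increasing",
                                                    "decreasing"))
  q <- gl("q", up = c("a", "missing"), down = c("b", "c"))
  out <- ontogeny_concordance(q, dev)
  lab <- function(g) out$concordance[out$gene == g]
  expect_identical(lab("a"), "anticipating")
  expect_identical(lab("b"), "antagonistic")
  expect_identical(lab("c"), "anticipating")
  expect_identical(attr(out, "n_skipped"), 1L)
  smry <- attr(out, "summary")
  expect_identical(sum(smry$n_genes), 3L)
  expect_error(ontogeny_concordance(q, tibble::tibble(
    gene = "a", developmental_direction = "sideways")), "invalid")
})

test_that("GMT files round-trip through write and read", {
  sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g2", "g4"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_identical(back[order(names(back))], sets[order(names(sets))])
})
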