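# shared fixtures and oracles, built in code

# exhaustive hypergeometric right tail from binomial coefficients,
# independent of phyper
brute_hyper_tail <- function(k, n, K, N) {
  x <- k:min(n, K)
  sum(exp(lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)))
}

# quick directional list constructor
gl <- function(name, up = character(), down = character(), ...) {
  gene_list(tibble::tibble(
    gene = c(up, down),
    direction = c(rep("induced", length(up)), rep("repressed", length(down)))),
    name = name)
}

entries_of <- function(x) {
  df <- tibble::tibble(gene = x$gene, direction = x$direction)
  df[order(df$gene, df$direction), ]
}

# cache expensive simulations across test files
.sim_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- force(expr)
  .sim_cache[[key]]
}

noisy_sim <- function() {
  cached("noisy2000", simulate_experiment(sim_config(seed = 1, n_genes = 2000)))
}
noisy_result <- function() {
  cached("noisy2000_res", run_pipeline(noisy_sim()))
}
noiseless_sim <- function() {
  cached("noiseless600", simulate_experiment(
    sim_config(seed = 7, n_genes = 600, noise_sd_log2 = 0,
               frac_low_quality = 0, frac_below_detection = 0)))
}
noiseless_result <- function() {
  cached("noiseless600_res", run_pipeline(noiseless_sim()))
}

# recovery table: did any classified entry of the gene match expectation?
recovery_table <- function(sim, result) {
  cls <- tidy(result)
  dplyr::inner_join(sim$truth, cls, by = "gene") |>
    dplyr::group_by(gene, planted_class, expected_category) |>
    dplyr::summarise(hit = any(category == expected_category),
                     .groups = "drop")
}

# random directional lists over a small gene pool, for property tests
random_list <- function(name, pool, p = 0.4) {
  genes <- pool[stats::runif(length(pool)) < p]
  dirs <- sample(c("induced", "repressed"), length(genes), replace = TRUE)
  gene_list(tibble::tibble(gene = genes, direction = dirs), name = name)
}
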