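#' @importFrom rlang %||% abort warn
#' @importFrom dplyr %>% across all_of anti_join arrange bind_rows case_when
#'   count desc distinct filter first group_by if_else inner_join left_join
#'   mutate n n_distinct pull rename row_number select semi_join slice_head
#'   summarise ungroup
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom rlang .data .env
NULL

# round half away from zero, as printed percentages are usually rounded
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  trunc(abs(x) * p + 0.5) / p * sign(x)
}

assert_cols <- function(df, cols, arg = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing required column(s): %s",
                  arg, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

assert_scalar_number <- function(x, arg, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s]", arg, min, max))
  }
  invisible(x)
}

flip_direction <- function(direction) {
  out <- ifelse(direction == "induced", "repressed",
                ifelse(direction == "repressed", "induced", direction))
  out
}

# signed linear fold change from a mean log2 ratio
signed_fc <- function(mean_log2_ratio) {
  sign(mean_log2_ratio) * 2^abs(mean_log2_ratio)
}
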