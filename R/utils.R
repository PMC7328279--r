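#' @importFrom rlang .data abort warn inform `%||%`
#' @import dplyr
#' @importFrom tibble tibble as_tibble tribble
#' @importFrom purrr map map_dbl map_chr map2 imap list_rbind
#' @importFrom stats rnorm rbinom runif lm lm.fit pt pf pnorm anova
#'   complete.cases setNames quantile fisher.test
NULL

# Round half away from zero at `digits` decimals; base round() is banker's,
# the report tables round half-up.
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

geometric_mean <- function(x) exp(mean(log(x)))

assert_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("%s must lie in [0, 1]", what), class = "gvb_config_error")
  }
  invisible(x)
}

assert_genotype_values <- function(g) {
  bad <- !(is.na(g) | g %in% c(0L, 1L, 2L))
  if (any(bad)) {
    abort(
      sprintf("genotype values must be 0, 1, 2 or NA; found: %s",
              paste(unique(g[bad]), collapse = ", ")),
      class = "gvb_data_error"
    )
  }
  invisible(g)
}
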