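#' @importFrom rlang abort warn inform %||% .data
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join bind_rows n row_number across all_of distinct rename
#' @importFrom tibble tibble as_tibble
#' @importFrom stats glm binomial coef vcov pnorm pt qnorm qchisq quantile
#'   rpois rnorm rbinom runif relevel median sd setNames p.adjust plogis
#'   wilcox.test kruskal.test fisher.test cor.test rexp complete.cases
#' @importFrom utils head read.delim write.table packageVersion
NULL

# single place for the z quantile used in all 95% intervals
Z95 <- qnorm(0.975)

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

assert_cols <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  assert_that(length(missing) == 0,
              paste0(what, " is missing column(s): ",
                     paste(missing, collapse = ", ")))
}

#' Derive a stream-specific seed from a master seed
#'
#' Keeps independent simulation stages decorrelated while remaining a pure
#' function of the master seed. Result stays below 2^31.
#'
#' @param seed master integer seed
#' @param stream small integer offset for the stream
#' @return an integer seed
#' @keywords internal
derive_seed <- function(seed, stream = 0L) {
  as.integer((as.double(seed) * 48271 + 1009 * (stream + 1)) %% 2147483629)
}

two_sided_p <- function(z) 2 * pnorm(-abs(z))
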