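#' @importFrom stats aggregate cor dhyper fisher.test glm hclust lm p.adjust
#'   pchisq pnorm prcomp quantile rbinom rgamma rnorm rpois runif sd setNames
#'   var wilcox.test cutree dist binomial coef as.dist
#' @importFrom utils head read.delim write.table combn
#' @importFrom methods is
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; clinical rates in this package are
#' reported with conventional half-up rounding (0.555... -> 0.56 at 2 digits).
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# package-internal logging: stage-tagged messages, silenced via option
aml_log <- function(stage, ...) {
  if (isTRUE(getOption("amlscape.quiet", FALSE))) return(invisible(NULL))
  message(sprintf("[%s] %s", stage, paste0(...)))
}

aml_warn <- function(...) warning(..., call. = FALSE)

aml_stop <- function(...) stop(..., call. = FALSE)

# deterministic RNG scope: every stochastic op takes an explicit seed
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same cells; 1 for
#' identical partitions (up to label permutation), about 0 for independent ones.
#'
#' @param a,b label vectors of equal length
#' @return scalar ARI
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  tab <- table(a, b)
  ch2 <- function(n) n * (n - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / ch2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_idx - expected)
}
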