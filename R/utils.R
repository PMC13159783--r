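#' @keywords internal
"_PACKAGE"

#' @importFrom stats median sd var quantile rnorm runif rbinom predict
#'   coef glm binomial wilcox.test kruskal.test t.test aov fisher.test
#'   chisq.test lm qnorm plogis qlogis complete.cases as.formula
#'   setNames anova vcov confint fitted
#' @importFrom utils read.table write.csv head tail
NULL

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. All stochastic operations in the package route through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# Derive a child seed from a base seed and a stream index, staying within
# the 32-bit integer range R requires for set.seed().
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + as.double(index) * 104729) %% 2147483647)
}

stop_invalid <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

check_scalar <- function(x, field, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid(field, "must be a single finite number")
  }
  if (strict_lower && x <= lower) {
    stop_invalid(field, sprintf("must be > %g", lower))
  }
  if (!strict_lower && x < lower) {
    stop_invalid(field, sprintf("must be >= %g", lower))
  }
  if (strict_upper && x >= upper) {
    stop_invalid(field, sprintf("must be < %g", upper))
  }
  if (!strict_upper && x > upper) {
    stop_invalid(field, sprintf("must be <= %g", upper))
  }
  invisible(x)
}

# Population variance/sd (divide by n, not n - 1). The Poincare identity
# sd1^2 + sd2^2 = 2 * sdnn^2 is exact only under this convention.
var_pop <- function(x) mean((x - mean(x))^2)
sd_pop <- function(x) sqrt(var_pop(x))
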