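#' @importFrom rlang abort warn inform %||%
#' @importFrom stats rbinom runif rnorm quantile median sd var cor lm coef
#'   residuals fitted logLik pchisq pnorm qnorm pt anova aov p.adjust
#'   complete.cases as.formula prcomp hclust cutree dist rnbinom integrate
#'   setNames approx
#' @importFrom utils head tail
NULL

# Evaluate `expr` under a local RNG state seeded with `seed`; restores the
# caller's .Random.seed so independent analyses do not perturb each other.
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a reproducible sub-seed for a named analysis stream from a root seed.
# Keeps results below .Machine$integer.max so they remain valid R seeds.
derive_seed <- function(seed, stream) {
  if (is.null(seed)) {
    return(NULL)
  }
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587)
}

#' Haldane map function
#'
#' Converts a genetic distance in centimorgans to a recombination fraction
#' assuming no crossover interference, `r = (1 - exp(-2d/100)) / 2`.
#'
#' @param d_cM Genetic distance(s) in centimorgans.
#' @return Recombination fraction(s) in `[0, 0.5)`.
#' @examples
#' haldane(0)    # 0
#' haldane(5)    # ~0.0476
#' @export
haldane <- function(d_cM) {
  stopifnot(all(d_cM >= 0))
  (1 - exp(-2 * d_cM / 100)) / 2
}

assert_state <- function(x, what = "state", hybrid = FALSE) {
  ok <- if (hybrid) x %in% c(0, 0.5, 1) else x %in% c(0, 1)
  if (!all(ok | is.na(x))) {
    abort(sprintf(
      "%s values must be in {%s}; offending value(s): %s",
      what, if (hybrid) "0, 0.5, 1" else "0, 1",
      paste(unique(x[!ok & !is.na(x)])[1:min(3, sum(!ok, na.rm = TRUE))], collapse = ", ")
    ))
  }
  invisible(x)
}
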