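#' Fit the four fixed causal structures relating Q, M and E
#'
#' Gaussian linear factorizations of the joint density of methylation
#' divergence (M) and expression divergence (E) given the QTL epigenotype
#' (Q), for the four directed acyclic structures:
#' \describe{
#'   \item{i}{saturated, no direction: `f(M|Q) f(E|Q,M)`}
#'   \item{ii}{independent effects: `f(M|Q) f(E|Q)`}
#'   \item{iii}{Q acts on M through E: `f(E|Q) f(M|E)`}
#'   \item{iv}{Q acts on E through M: `f(M|Q) f(E|M)`}
#' }
#' Each conditional is an ordinary least-squares Gaussian regression;
#' `AIC = -2 logL + 2k` with `k` counting all regression coefficients plus
#' the two residual variances.
#'
#' @param q Binary epigenotype (0/1 or `"MM"`/`"UU"`), one per family.
#' @param m,e Numeric methylation and expression divergence, same length
#'   (>= 10).
#' @return Tibble with `model`, `loglik`, `k`, `aic`, `delta_aic`,
#'   `selected` (ties broken toward fewer parameters, then model order).
#' @export
fit_causal_models <- function(q, m, e) {
  if (is.character(q) || is.factor(q)) q <- as.numeric(as.character(q) == "UU")
  ok <- is.finite(q) & is.finite(m) & is.finite(e)
  q <- q[ok]
  m <- m[ok]
  e <- e[ok]
  if (length(q) < 10) abort("Need at least 10 complete trios.")
  if (var(m) == 0 || var(e) == 0) abort("Constant M or E.")
  ll <- function(fit) as.numeric(logLik(fit))
  models <- list(
    i = list(ll = ll(lm(m ~ q)) + ll(lm(e ~ q + m)), k = 3 + 4),
    ii = list(ll = ll(lm(m ~ q)) + ll(lm(e ~ q)), k = 3 + 3),
    iii = list(ll = ll(lm(e ~ q)) + ll(lm(m ~ e)), k = 3 + 3),
    iv = list(ll = ll(lm(m ~ q)) + ll(lm(e ~ m)), k = 3 + 3)
  )
  out <- tibble::tibble(
    model = names(models),
    loglik = vapply(models, `[[`, numeric(1), "ll"),
    k = vapply(models, `[[`, numeric(1), "k")
  )
  out$aic <- -2 * out$loglik + 2 * out$k
  out$delta_aic <- out$aic - min(out$aic)
  # tie-break: simpler model (smaller k), then fixed model order
  ord <- order(round(out$aic, 10), out$k, seq_len(nrow(out)))
  out$selected <- seq_len(nrow(out)) == ord[1]
  out
}

#' Bootstrap model selection among the causal structures
#'
#' Resamples trios with replacement, selects the minimum-AIC structure in
#' each resample, and reports the modal model with its selection
#' frequency. Degenerate resamples (constant Q, M or E) are redrawn, up to
#' `max_retries` attempts each.
#'
#' @inheritParams fit_causal_models
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param seed Optional seed; the same seed reproduces the selection.
#' @param max_retries Redraw cap for degenerate resamples.
#' @return A `causal_fit` object: list with `selected`, `support`,
#'   `frequencies` (tibble over models), `fit_full` (the full-data AIC
#'   table) and `n_boot`.
#' @export
bootstrap_select <- function(q, m, e, n_boot = 1000, seed = NULL,
                             max_retries = 100) {
  if (n_boot < 100) abort("`n_boot` must be at least 100.")
  if (is.character(q) || is.factor(q)) q <- as.numeric(as.character(q) == "UU")
  full <- fit_causal_models(q, m, e)
  n <- length(q)
  with_seed_(seed, {
    picks <- character(n_boot)
    for (b in seq_len(n_boot)) {
      for (try in seq_len(max_retries)) {
        idx <- sample.int(n, n, replace = TRUE)
        if (var(q[idx]) > 0 && var(m[idx]) > 0 && var(e[idx]) > 0) break
        if (try == max_retries) abort("Could not draw a non-degenerate resample.")
      }
      fit <- fit_causal_models(q[idx], m[idx], e[idx])
      picks[b] <- fit$model[fit$selected]
    }
    freq <- tibble::tibble(
      model = c("i", "ii", "iii", "iv"),
      frequency = as.numeric(table(factor(picks, c("i", "ii", "iii", "iv"))) / n_boot)
    )
    sel <- freq$model[which.max(freq$frequency)]
    structure(
      list(
        selected = sel,
        support = max(freq$frequency),
        frequencies = freq, fit_full = full, n_boot = n_boot
      ),
      class = "causal_fit"
    )
  })
}

#' @export
print.causal_fit <- function(x, ...) {
  cat(sprintf(
    "<causal_fit> model '%s' selected with %.1f%% bootstrap support (%d resamples)\n",
    x$selected, 100 * x$support, x$n_boot
  ))
  invisible(x)
}

#' @rdname bootstrap_select
#' @param x A `causal_fit` object.
#' @param ... Unused.
#' @method tidy causal_fit
#' @export
tidy.causal_fit <- function(x, ...) {
  dplyr::left_join(x$fit_full, x$frequencies, by = "model")
}

#' @rdname bootstrap_select
#' @method glance causal_fit
#' @export
glance.causal_fit <- function(x, ...) {
  tibble::tibble(
    selected = x$selected, support = x$support, n_boot = x$n_boot
  )
}
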