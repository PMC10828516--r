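#' Analytic decomposition of the epihybrid QTL contrast
#'
#' In the asymmetric cross design (every epiRIL crossed to the same
#' recurrent wild-type parent, heterosis defined as divergence from the
#' mid-parent value), the expected MM-minus-UU contrast at a focal locus,
#' after integrating the unknown background MM frequency `p` uniformly over
#' `[0, 1]` and collapsing the per-locus background effects `N * beta` to
#' aggregate `beta` terms, is
#' `2 b_D - (1/2) b_AxA + 2 b_AxD - 2 b_DxA`.
#' The dominance term enters directly; the additive-by-additive,
#' additive-by-dominance and dominance-by-additive background interaction
#' terms survive integration, while the dominance-by-dominance term
#' integrates out entirely. The contrast is therefore a confounded mixture
#' of dominance and background epistasis: the components cannot be
#' separated from the contrast alone.
#'
#' @param effects List or one-row data frame with elements `beta_d`,
#'   `beta_aa`, `beta_ad`, `beta_da` (and optionally `beta_dd`, which does
#'   not enter the integrated contrast); missing terms default to 0.
#' @return Scalar contrast value.
#' @examples
#' qtl_contrast_closed_form(list(beta_d = 1))    # 2
#' qtl_contrast_closed_form(list(beta_aa = 1))   # -0.5
#' @export
qtl_contrast_closed_form <- function(effects) {
  g <- function(nm) {
    v <- effects[[nm]] %||% 0
    if (!is.finite(v)) abort(sprintf("Effect `%s` must be finite.", nm))
    v
  }
  2 * g("beta_d") - 0.5 * g("beta_aa") + 2 * g("beta_ad") - 2 * g("beta_da")
}

#' Per-term contributions to the integrated QTL contrast
#'
#' @inheritParams qtl_contrast_closed_form
#' @return Tibble with `term`, `coefficient`, `effect`, `contribution`,
#'   plus a final row for the total.
#' @export
quantgen_decomposition <- function(effects) {
  terms <- tibble::tibble(
    term = c("dominance", "additive x additive", "additive x dominance",
             "dominance x additive", "dominance x dominance"),
    coefficient = c(2, -0.5, 2, -2, 0),
    effect = c(
      effects$beta_d %||% 0, effects$beta_aa %||% 0,
      effects$beta_ad %||% 0, effects$beta_da %||% 0,
      effects$beta_dd %||% 0
    )
  )
  terms$contribution <- terms$coefficient * terms$effect
  dplyr::bind_rows(
    terms,
    tibble::tibble(
      term = "total", coefficient = NA_real_, effect = NA_real_,
      contribution = sum(terms$contribution)
    )
  )
}

#' Integrate a function over the unit interval
#'
#' Thin quadrature wrapper used to integrate contrast expressions over the
#' background MM frequency `p`; exact to near machine precision for
#' polynomial integrands.
#'
#' @param f Function of a scalar (vectorization handled internally).
#' @return The integral over `[0, 1]`.
#' @examples
#' integrate_unit(function(p) p - 1)  # -0.5
#' @export
integrate_unit <- function(f) {
  integrate(Vectorize(f), 0, 1, rel.tol = 1e-12, abs.tol = 1e-12)$value
}

#' Forward-simulation oracle for the epihybrid QTL contrast
#'
#' Simulates the cross design directly under an explicit, indicator-coded
#' genotype-to-phenotype map and measures the empirical MM-vs-UU contrast
#' of the heterosis value `z = y_F1 - mid`. Parents: the recurrent parent
#' is MM at every locus; each simulated epiRIL is MM or UU at the focal
#' locus (probability 1/2 each, so both classes are observed) and MM with
#' probability `p` at each of `n_background` background loci. The F1
#' carries MU wherever the epiRIL parent is UU. The phenotype map codes
#' each locus additively as `x` (+1 MM, 0 MU, -1 UU) and for dominance as
#' `z` (1 if MU else 0), with focal main effects `beta_la`, `beta_ld`,
#' background main effects `beta_a`, `beta_d`, and focal-by-background
#' interactions `beta_aa`, `beta_ad`, `beta_da`, `beta_dd` applied to the
#' corresponding code products summed over background loci.
#'
#' Under this coding the dominance-only contrast equals `-beta_ld`,
#' independent of `p`; the factor-2 coefficients of the integrated
#' closed form correspond to a different (unstated) effect scaling, so the
#' simulator is used to verify structural properties (superposition,
#' p-independence without epistasis, zero under zero effects) rather than
#' coefficient scale.
#'
#' @param effects Named list of the coefficients above (missing ones are
#'   0), plus optional `sigma` residual SD (default 0).
#' @param p Background MM frequency in `[0, 1]`.
#' @param n_lines Number of simulated epiRIL families.
#' @param n_background Number of background loci.
#' @param seed Optional seed.
#' @return One-row tibble with `contrast`, `se`, `n_mm`, `n_uu`.
#' @export
contrast_forward_sim <- function(effects, p, n_lines = 10000,
                                 n_background = 20, seed = NULL) {
  if (p < 0 || p > 1) abort("`p` must lie in [0, 1].")
  g <- function(nm) effects[[nm]] %||% 0
  with_seed_(seed, {
    focal_uu <- rbinom(n_lines, 1, 0.5)
    if (length(unique(focal_uu)) < 2) {
      abort("Too few lines: both focal classes must be observed.")
    }
    bg_uu <- matrix(rbinom(n_lines * n_background, 1, 1 - p), n_lines)
    # additive (+1 MM, 0 MU, -1 UU) and dominance (het indicator) codes
    pheno <- function(x_f, z_f, x_b, z_b) {
      g("beta_la") * x_f + g("beta_ld") * z_f +
        g("beta_a") * rowSums(x_b) + g("beta_d") * rowSums(z_b) +
        g("beta_aa") * x_f * rowSums(x_b) +
        g("beta_ad") * x_f * rowSums(z_b) +
        g("beta_da") * z_f * rowSums(x_b) +
        g("beta_dd") * z_f * rowSums(z_b)
    }
    ones <- matrix(1, n_lines, n_background)
    zeros <- matrix(0, n_lines, n_background)
    y_wt <- pheno(rep(1, n_lines), rep(0, n_lines), ones, zeros)
    y_epi <- pheno(1 - 2 * focal_uu, rep(0, n_lines), 1 - 2 * bg_uu, zeros)
    # F1: MU wherever the epiRIL parent was UU
    y_f1 <- pheno(1 - focal_uu, focal_uu, 1 - bg_uu, bg_uu)
    sigma <- g("sigma")
    if (sigma > 0) y_f1 <- y_f1 + rnorm(n_lines, 0, sigma)
    mid <- (y_wt + y_epi) / 2
    z <- y_f1 - mid
    mm <- focal_uu == 0
    contrast <- mean(z[mm]) - mean(z[!mm])
    se <- sqrt(var(z[mm]) / sum(mm) + var(z[!mm]) / sum(!mm))
    tibble::tibble(
      contrast = contrast, se = se,
      n_mm = sum(mm), n_uu = sum(!mm)
    )
  })
}
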