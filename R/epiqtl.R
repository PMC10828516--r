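#' Ordered quantile (rank-to-normal) normalization
#'
#' Maps values onto standard-normal quantiles by rank,
#' `qnorm(rank / (n + 1))`, with ties receiving the average rank. The
#' transform is strictly monotone in the input ranks, so any strictly
#' monotone transform of the input yields an identical output.
#'
#' @param values Numeric vector with at least 3 finite values.
#' @return Numeric vector of the same length (NA preserved).
#' @examples
#' orq_normalize(c(1, 2, 3))  # symmetric around 0
#' @export
orq_normalize <- function(values) {
  ok <- is.finite(values)
  if (sum(ok) < 3) abort("Need at least 3 finite values.")
  if (length(unique(values[ok])) < 2) {
    abort("Constant input: no rank spread to normalize.")
  }
  out <- rep(NA_real_, length(values))
  r <- rank(values[ok], ties.method = "average")
  out[ok] <- qnorm(r / (sum(ok) + 1))
  out
}

#' Expected epigenotype probabilities on a pseudomarker grid
#'
#' For a fully homozygous two-class population, computes for every line and
#' every grid position the probability of the UU class given the flanking
#' marker epigenotypes, using Haldane recombination fractions on the cM
#' distances: `P = P(gL -> g) P(g -> gR) / P(gL -> gR)` with
#' `P(a -> b) = r` when the classes differ and `1 - r` otherwise. At marker
#' positions the probability equals the observed epigenotype (0 or 1).
#' Physical positions for pseudomarkers are interpolated piecewise linearly
#' between flanking markers.
#'
#' @param map An `epimap` with line epigenotypes.
#' @param step_cM Grid step in centimorgans (> 0).
#' @return A `genoprob` object: list with `grid` (tibble: `chrom`, `cM`,
#'   `bp`, `marker_id`, NA for pseudomarkers) and `prob` (lines x grid
#'   matrix of P(UU)).
#' @export
genotype_probabilities <- function(map, step_cM = 2) {
  stopifnot(inherits(map, "epimap"), !is.null(map$geno))
  if (step_cM <= 0) abort("`step_cM` must be positive.")
  grids <- list()
  probs <- list()
  for (ch in unique(map$markers$chrom)) {
    mk <- map$markers[map$markers$chrom == ch, ]
    g <- map$geno[, mk$marker_id, drop = FALSE]
    lo <- min(mk$cM)
    hi <- max(mk$cM)
    pos <- sort(unique(c(mk$cM, seq(lo, hi, by = step_cM))))
    pos <- pmin(pmax(pos, lo), hi) # clip to the marker span
    pos <- unique(pos)
    bp <- if (nrow(mk) > 1) {
      approx(mk$cM, mk$bp, xout = pos, rule = 2)$y
    } else {
      rep(mk$bp, length(pos))
    }
    pmat <- matrix(NA_real_, nrow(g), length(pos))
    at_marker <- match(pos, mk$cM)
    for (j in seq_along(pos)) {
      if (!is.na(at_marker[j])) {
        pmat[, j] <- g[, at_marker[j]]
        next
      }
      li <- max(which(mk$cM < pos[j]))
      ri <- min(which(mk$cM > pos[j]))
      r1 <- haldane(pos[j] - mk$cM[li])
      r2 <- haldane(mk$cM[ri] - pos[j])
      r12 <- haldane(mk$cM[ri] - mk$cM[li])
      gl <- g[, li]
      gr <- g[, ri]
      trans <- function(same, r) ifelse(same, 1 - r, r)
      # P(g = UU | gL, gR)
      num <- trans(gl == 1, r1) * trans(gr == 1, r2)
      den <- trans(gl == gr, r12)
      pmat[, j] <- num / den
    }
    grids[[ch]] <- tibble::tibble(
      chrom = ch, cM = pos, bp = bp,
      marker_id = mk$marker_id[at_marker]
    )
    probs[[ch]] <- pmat
  }
  structure(
    list(
      grid = dplyr::bind_rows(grids),
      prob = do.call(cbind, probs)
    ),
    class = "genoprob"
  )
}

# Core vectorized Haley-Knott engine: LOD for (possibly many) trait vectors
# against every grid column. Y: n x k matrix (no NAs), G: n x m probabilities.
hk_lod_matrix <- function(Y, G, lod_cap = 50) {
  n <- nrow(Y)
  Yc <- sweep(Y, 2, colMeans(Y))
  Gc <- sweep(G, 2, colMeans(G))
  syy <- colSums(Yc^2) # length k
  sxx <- colSums(Gc^2) # length m
  sxy <- crossprod(Gc, Yc) # m x k
  rss1 <- pmax(outer(rep(1, nrow(sxy)), syy) - sxy^2 / pmax(sxx, .Machine$double.eps), 0)
  lod <- (n / 2) * log10(outer(rep(1, nrow(sxy)), syy) / pmax(rss1, .Machine$double.eps))
  lod[sxx < .Machine$double.eps, ] <- 0 # monomorphic pseudomarker
  pmin(lod, lod_cap) # perfect fits capped at a finite sentinel
}

#' Genome scan by Haley-Knott regression
#'
#' Regresses the trait on the expected epigenotype at every pseudomarker
#' and reports `LOD = (n/2) log10(RSS0 / RSS1)` against the intercept-only
#' model. A perfect fit (RSS1 = 0) is capped at the `lod_cap` sentinel.
#'
#' @param map An `epimap` with epigenotypes, or a precomputed `genoprob`
#'   object (cheaper when scanning many traits).
#' @param trait Numeric vector, one value per line (names matched to line
#'   ids when present); at least 10 non-missing values.
#' @param step_cM Grid step when `map` is an `epimap`.
#' @param lod_cap Sentinel LOD for perfect fits.
#' @return An `epiqtl_scan` tibble: `chrom`, `cM`, `bp`, `marker_id`,
#'   `lod`, with attributes `n` (lines used) and `lod_cap`.
#' @export
hk_scan <- function(map, trait, step_cM = 2, lod_cap = 50) {
  gp <- if (inherits(map, "genoprob")) map else genotype_probabilities(map, step_cM)
  if (!is.null(names(trait)) && !is.null(rownames(gp$prob))) {
    trait <- trait[rownames(gp$prob)]
  }
  if (length(trait) != nrow(gp$prob)) {
    abort("`trait` must have one value per line.")
  }
  ok <- is.finite(trait)
  if (sum(ok) < 10) abort("Need at least 10 non-missing trait values.")
  y <- trait[ok]
  if (var(y) == 0) abort("Zero-variance trait.")
  lod <- hk_lod_matrix(matrix(y, ncol = 1), gp$prob[ok, , drop = FALSE], lod_cap)
  out <- dplyr::mutate(gp$grid, lod = as.vector(lod))
  structure(out,
    class = c("epiqtl_scan", class(out)),
    n = sum(ok), lod_cap = lod_cap
  )
}

#' Permutation-based genome-wide LOD significance threshold
#'
#' Permutes trait values across lines, rescans the genome, and returns the
#' `1 - alpha` quantile of the per-permutation genome-wide maximum LOD.
#' Controls the genome-wide false-positive rate at `alpha`.
#'
#' @inheritParams hk_scan
#' @param n_perm Number of permutations (>= 100).
#' @param alpha Genome-wide false positive rate.
#' @param seed Optional seed.
#' @return The LOD threshold (numeric scalar) with the null maximum-LOD
#'   vector attached as attribute `"max_lods"`.
#' @export
permutation_threshold <- function(map, trait, n_perm = 1000, alpha = 0.05,
                                  step_cM = 2, lod_cap = 50, seed = NULL) {
  if (n_perm < 100) abort("`n_perm` must be at least 100.")
  gp <- if (inherits(map, "genoprob")) map else genotype_probabilities(map, step_cM)
  if (!is.null(names(trait)) && !is.null(rownames(gp$prob))) {
    trait <- trait[rownames(gp$prob)]
  }
  ok <- is.finite(trait)
  y <- trait[ok]
  G <- gp$prob[ok, , drop = FALSE]
  with_seed_(seed, {
    P <- vapply(seq_len(n_perm), function(i) sample(y), numeric(length(y)))
    lod <- hk_lod_matrix(P, G, lod_cap) # m x n_perm
    max_lods <- apply(lod, 2, max)
    thr <- unname(quantile(max_lods, 1 - alpha))
    attr(thr, "max_lods") <- max_lods
    thr
  })
}

#' Extract peaks and LOD-drop confidence intervals from a scan
#'
#' Keeps the highest pseudomarker per chromosome whose LOD passes the
#' threshold (leftmost position on ties), with the confidence interval
#' defined as the widest contiguous run of grid positions around the peak
#' with `LOD >= peak - drop`.
#'
#' @param scan An `epiqtl_scan`.
#' @param threshold Genome-wide LOD threshold.
#' @param drop LOD drop for the confidence interval (> 0).
#' @return Tibble with one row per passing chromosome: `chrom`, `peak_cM`,
#'   `peak_bp`, `peak_marker`, `lod`, `ci_lo_cM`, `ci_hi_cM`, `ci_lo_bp`,
#'   `ci_hi_bp`. Empty (zero rows) when nothing passes.
#' @export
peaks_and_ci <- function(scan, threshold, drop = 2) {
  if (drop <= 0) abort("`drop` must be positive.")
  purrr::map_dfr(split(tibble::as_tibble(scan), scan$chrom), function(s) {
    s <- dplyr::arrange(s, .data$cM)
    if (max(s$lod) < threshold) {
      return(tibble::tibble())
    }
    pk <- which.max(s$lod) # which.max takes the leftmost tie
    keep <- s$lod >= s$lod[pk] - drop
    lo <- pk
    while (lo > 1 && keep[lo - 1]) lo <- lo - 1
    hi <- pk
    while (hi < nrow(s) && keep[hi + 1]) hi <- hi + 1
    tibble::tibble(
      chrom = s$chrom[1],
      peak_cM = s$cM[pk], peak_bp = s$bp[pk],
      peak_marker = s$marker_id[pk], lod = s$lod[pk],
      ci_lo_cM = s$cM[lo], ci_hi_cM = s$cM[hi],
      ci_lo_bp = s$bp[lo], ci_hi_bp = s$bp[hi]
    )
  })
}

#' Classify a QTL-target relation as local (cis) or distal (trans)
#'
#' The association is `cis` exactly when the target region's body is
#' contained in the peak's LOD-drop confidence interval on the same
#' chromosome; a target straddling the interval boundary is `trans`.
#'
#' @param peaks Tibble from [peaks_and_ci()] (or rows thereof).
#' @param target Tibble with `chrom`, `start`, `end` (bp), recycled or
#'   matched row-wise against `peaks`.
#' @return Character vector, `"cis"` or `"trans"`, one per peak row.
#' @export
cis_trans_call <- function(peaks, target) {
  n <- nrow(peaks)
  tchrom <- rep_len(target$chrom, n)
  tstart <- rep_len(target$start, n)
  tend <- rep_len(target$end, n)
  ifelse(
    tchrom == peaks$chrom & tstart >= peaks$ci_lo_bp & tend <= peaks$ci_hi_bp,
    "cis", "trans"
  )
}

#' QTL effect size and direction at a marker
#'
#' Ordinary least-squares regression of the trait on the epigenotype coded
#' MM = 0, UU = 1. A positive slope means the hypomethylated (UU) class has
#' the larger trait value.
#'
#' @param trait Numeric vector.
#' @param genotype Epigenotypes as 0/1 or `"MM"`/`"UU"`.
#' @return One-row tibble with `r_squared`, `slope`, `sign`.
#' @export
qtl_effect <- function(trait, genotype) {
  if (is.character(genotype) || is.factor(genotype)) {
    genotype <- as.numeric(as.character(genotype) == "UU")
  }
  ok <- is.finite(trait) & is.finite(genotype)
  trait <- trait[ok]
  genotype <- genotype[ok]
  if (length(unique(genotype)) < 2) {
    abort("Both epigenotype classes must be present at the peak marker.")
  }
  if (var(trait) == 0) {
    # a constant trait carries no association, whatever the genotype
    return(tibble::tibble(r_squared = 0, slope = 0, sign = "none"))
  }
  fit <- lm(trait ~ genotype)
  slope <- unname(coef(fit)[2])
  tibble::tibble(
    r_squared = summary(fit)$r.squared,
    slope = slope,
    sign = ifelse(slope > 0, "positive", "negative")
  )
}

#' Benjamini-Yekutieli adjustment
#'
#' Step-up false discovery rate control valid under arbitrary dependence,
#' with the harmonic-sum inflation factor `c(m) = sum(1/i)`.
#'
#' @param p_values Raw p-values in `[0, 1]`.
#' @return Adjusted p-values (monotone in the input, capped at 1).
#' @export
by_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(p_values, method = "BY")
}

#' Convert a LOD score to a pointwise p-value
#'
#' Chi-square approximation with one degree of freedom:
#' `p = P(chisq_1 >= 2 ln(10) LOD)`.
#'
#' @param lod LOD score(s).
#' @return p-value(s).
#' @export
lod_to_p <- function(lod) {
  pchisq(2 * log(10) * lod, df = 1, lower.tail = FALSE)
}

#' Map shared non-additive regions onto the epihaplotype map
#'
#' Runs the full per-trait chain for every shared NAD region: ordered
#' quantile normalization of the `%` mid-parent divergence, Haley-Knott
#' genome scan, per-trait permutation threshold, per-chromosome peak
#' extraction with LOD-drop confidence intervals, Benjamini-Yekutieli
#' adjustment of the best-peak p-values across traits, cis/trans calling
#' against each region's own coordinates, effect size and direction at the
#' peak marker, and the predominant remodeling scenario (TCM vs TCdM
#' majority across families) of each significant target.
#'
#' @param map An `epimap` with epigenotypes.
#' @param divergence Regions x families matrix of `%` mid-parent divergence
#'   (NA allowed); row names are region ids matching `regions`.
#' @param regions Region coordinates (`region_id`, `chrom`, `start`,
#'   `end`).
#' @param scenarios Optional region x family character matrix (or the long
#'   tibble from [classify_trios()]) used for the predominant-scenario
#'   label.
#' @param nad Optional indicator matrix for the sharing filter; defaults to
#'   `!is.na(divergence)`.
#' @param share_min_frac Minimum fraction of families in which a trait
#'   region must be remodeled (default 0.5).
#' @param step_cM,n_perm,alpha,drop,lod_cap Scan hyper-parameters: grid
#'   step, permutations per trait, genome-wide false positive rate, LOD
#'   drop for confidence intervals, perfect-fit cap.
#' @param fdr Benjamini-Yekutieli threshold across traits.
#' @param seed Optional root seed; per-trait permutation seeds derive from
#'   it.
#' @return A `nad_qtl` object: list with `associations` (one row per
#'   significant trait x peak: `trait_id`, `chrom`, `peak_cM`, `peak_bp`,
#'   `lod`, `threshold`, `p`, `p_by`, CI bounds, `cis_trans`, `r_squared`,
#'   `sign`, `predominant_scenario`), `scanned` (per-trait bookkeeping) and
#'   `failed` (traits skipped, with reasons).
#' @export
run_nad_qtl <- function(map, divergence, regions, scenarios = NULL,
                        nad = NULL, share_min_frac = 0.5, step_cM = 2,
                        n_perm = 1000, alpha = 0.05, drop = 2,
                        lod_cap = 50, fdr = 0.05, seed = NULL) {
  stopifnot(inherits(map, "epimap"), !is.null(map$geno))
  if (is.null(nad)) nad <- !is.na(divergence) + 0
  share <- rowMeans(nad == 1)
  traits <- rownames(divergence)[share >= share_min_frac]
  if (!length(traits)) abort("No trait passes the sharing filter.")
  gp <- genotype_probabilities(map, step_cM)
  failed <- list()
  rows <- list()
  for (tr in traits) {
    res <- tryCatch(
      {
        y <- orq_normalize(divergence[tr, ])
        names(y) <- colnames(divergence)
        scan <- hk_scan(gp, y, lod_cap = lod_cap)
        thr <- permutation_threshold(gp, y,
          n_perm = n_perm, alpha = alpha,
          lod_cap = lod_cap, seed = derive_seed(seed, tr)
        )
        pk <- peaks_and_ci(scan, thr, drop = drop)
        list(scan = scan, thr = as.numeric(thr), peaks = pk, trait = y)
      },
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failed[[tr]] <- conditionMessage(res)
      next
    }
    rows[[tr]] <- res
  }
  if (length(failed)) {
    inform(sprintf("%d trait(s) failed and were skipped.", length(failed)))
  }
  scanned <- purrr::imap_dfr(rows, function(r, tr) {
    tibble::tibble(
      trait_id = tr, threshold = r$thr,
      max_lod = max(r$peaks$lod, -Inf),
      n_peaks = nrow(r$peaks)
    )
  })
  assoc <- purrr::imap_dfr(rows, function(r, tr) {
    if (nrow(r$peaks) == 0) {
      return(tibble::tibble())
    }
    best <- r$peaks[which.max(r$peaks$lod), ]
    dplyr::mutate(r$peaks,
      trait_id = tr, threshold = r$thr,
      best_p = lod_to_p(best$lod), p = lod_to_p(.data$lod)
    )
  })
  if (nrow(assoc)) {
    # BY across traits on each trait's best-peak p-value
    best_by_trait <- dplyr::summarise(
      dplyr::group_by(assoc, .data$trait_id),
      best_p = min(.data$best_p), .groups = "drop"
    )
    best_by_trait$p_by <- by_adjust(best_by_trait$best_p)
    assoc <- dplyr::left_join(
      assoc, best_by_trait[, c("trait_id", "p_by")],
      by = "trait_id"
    )
    assoc <- assoc[assoc$p_by < fdr, ]
  }
  if (nrow(assoc)) {
    tgt <- regions[match(assoc$trait_id, regions$region_id), ]
    assoc$cis_trans <- cis_trans_call(assoc, tgt)
    eff <- purrr::map_dfr(seq_len(nrow(assoc)), function(i) {
      tr <- assoc$trait_id[i]
      # effect at the marker nearest the peak
      mk <- map$markers[map$markers$chrom == assoc$chrom[i], ]
      nearest <- mk$marker_id[which.min(abs(mk$cM - assoc$peak_cM[i]))]
      qtl_effect(rows[[tr]]$trait, map$geno[, nearest])
    })
    assoc <- dplyr::bind_cols(assoc, eff)
    assoc$predominant_scenario <- predominant_scenario_(assoc$trait_id, scenarios)
    assoc <- dplyr::relocate(assoc, "trait_id")
  }
  structure(
    list(
      associations = tibble::as_tibble(assoc), scanned = scanned,
      failed = failed, params = list(
        step_cM = step_cM, n_perm = n_perm,
        alpha = alpha, drop = drop, fdr = fdr
      )
    ),
    class = "nad_qtl"
  )
}

predominant_scenario_ <- function(trait_ids, scenarios) {
  if (is.null(scenarios)) {
    return(NA_character_)
  }
  if (is.data.frame(scenarios)) {
    tab <- scenarios[scenarios$region_id %in% trait_ids &
      scenarios$scenario != "ADD", c("region_id", "scenario")]
    tab$class <- ifelse(grepl("^TCM", tab$scenario), "TCM", "TCdM")
    lk <- dplyr::summarise(
      dplyr::group_by(tab, .data$region_id),
      class = names(sort(table(.data$class), decreasing = TRUE))[1],
      .groups = "drop"
    )
    return(lk$class[match(trait_ids, lk$region_id)])
  }
  vapply(trait_ids, function(tr) {
    s <- scenarios[tr, ]
    s <- s[s != "ADD"]
    if (!length(s)) {
      return(NA_character_)
    }
    cls <- ifelse(grepl("^TCM", s), "TCM", "TCdM")
    names(sort(table(cls), decreasing = TRUE))[1]
  }, character(1))
}

#' @export
print.nad_qtl <- function(x, ...) {
  cat(sprintf(
    "<nad_qtl> %d trait(s) scanned, %d significant association row(s), %d failed\n",
    nrow(x$scanned), nrow(x$associations), length(x$failed)
  ))
  invisible(x)
}

#' @rdname run_nad_qtl
#' @param x A `nad_qtl` object.
#' @param ... Unused.
#' @method tidy nad_qtl
#' @export
tidy.nad_qtl <- function(x, ...) x$associations

#' @rdname run_nad_qtl
#' @method glance nad_qtl
#' @export
glance.nad_qtl <- function(x, ...) {
  tibble::tibble(
    n_traits = nrow(x$scanned),
    n_significant = dplyr::n_distinct(x$associations$trait_id),
    n_failed = length(x$failed),
    frac_trans = if (nrow(x$associations)) {
      mean(x$associations$cis_trans == "trans")
    } else {
      NA_real_
    }
  )
}
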