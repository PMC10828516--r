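#' Adjust phenotypes for environmental covariates
#'
#' Removes outliers beyond `sd_cut` standard deviations of the raw values,
#' fits `value ~ covariates` by least squares with all covariates treated
#' as categorical fixed factors, and returns the residuals with the grand
#' mean re-added. Aliased (rank-deficient) design columns are dropped with
#' a warning.
#'
#' @param phenotypes Tibble with a `value` column plus the covariate
#'   columns.
#' @param covariates Character vector of covariate column names.
#' @param sd_cut Outlier threshold in standard deviations (Inf disables).
#' @return The input tibble, outliers removed, with `value_adj` added.
#' @export
adjust_environment <- function(phenotypes,
                               covariates = c("experiment", "block", "germination_date"),
                               sd_cut = 3) {
  missing_cov <- setdiff(covariates, names(phenotypes))
  if (length(missing_cov)) {
    abort(paste0("Missing covariate column(s): ", paste(missing_cov, collapse = ", ")))
  }
  v <- phenotypes$value
  keep <- abs(v - mean(v, na.rm = TRUE)) <= sd_cut * sd(v, na.rm = TRUE)
  keep[is.na(keep)] <- FALSE
  out <- phenotypes[keep, ]
  # covariates constant after filtering carry no information
  usable <- covariates[vapply(
    covariates, function(cv) length(unique(out[[cv]])) > 1, logical(1)
  )]
  if (!length(usable)) {
    out$value_adj <- out$value
    return(out)
  }
  fml <- as.formula(paste("value ~", paste(usable, collapse = " + ")))
  dat <- dplyr::mutate(out, dplyr::across(dplyr::all_of(usable), as.factor))
  fit <- lm(fml, data = dat)
  if (anyNA(coef(fit))) {
    warn("Rank-deficient covariate design; aliased levels dropped.")
  }
  out$value_adj <- residuals(fit) + mean(out$value)
  out
}

#' Per-family mid-parent heterosis table
#'
#' Computes, per family, the parental group means, the mid-parent value
#' `MPV = (mean_msCol + mean_epiRIL) / 2` and the mid-parent heterosis
#' `MPH = (mean_F1 - MPV) / MPV * 100`. Families with fewer than
#' `min_plants` plants in any group are excluded, as are families whose
#' MPV is numerically near zero (flagged in the `"excluded"` attribute).
#'
#' @param phenotypes Tibble with `family_id`, `group` (`msCol`, `epiRIL`,
#'   `F1`) and a value column.
#' @param value_col Which column to average (default `value_adj` if
#'   present, else `value`).
#' @param min_plants Minimum plants per group (default 5).
#' @param mpv_eps Families with `|MPV| < mpv_eps` are excluded.
#' @return Tibble with `family_id`, `mean_mscol`, `mean_epiril`, `mean_f1`,
#'   `mpv`, `mph`, `n_mscol`, `n_epiril`, `n_f1`.
#' @export
compute_mph <- function(phenotypes, value_col = NULL, min_plants = 5,
                        mpv_eps = 1e-8) {
  value_col <- value_col %||%
    (if ("value_adj" %in% names(phenotypes)) "value_adj" else "value")
  wide <- dplyr::summarise(
    dplyr::group_by(phenotypes, .data$family_id, .data$group),
    m = mean(.data[[value_col]], na.rm = TRUE),
    n = sum(!is.na(.data[[value_col]])),
    .groups = "drop"
  )
  wide <- tidyr::pivot_wider(wide,
    names_from = "group",
    values_from = c("m", "n"), values_fill = list(n = 0L)
  )
  need <- c("m_msCol", "m_epiRIL", "m_F1", "n_msCol", "n_epiRIL", "n_F1")
  miss <- setdiff(need, names(wide))
  for (cc in miss) wide[[cc]] <- if (grepl("^n_", cc)) 0L else NA_real_
  complete <- wide$n_msCol >= min_plants & wide$n_epiRIL >= min_plants &
    wide$n_F1 >= min_plants
  mpv <- (wide$m_msCol + wide$m_epiRIL) / 2
  usable <- complete & !is.na(mpv) & abs(mpv) >= mpv_eps
  excluded <- wide$family_id[!usable]
  if (length(excluded)) {
    inform(sprintf("%d family(ies) excluded (missing group, too few plants, or MPV near zero).", length(excluded)))
  }
  out <- tibble::tibble(
    family_id = wide$family_id,
    mean_mscol = wide$m_msCol, mean_epiril = wide$m_epiRIL,
    mean_f1 = wide$m_F1, mpv = mpv,
    mph = (wide$m_F1 - mpv) / mpv * 100,
    n_mscol = wide$n_msCol, n_epiril = wide$n_epiRIL, n_f1 = wide$n_F1
  )[usable, ]
  attr(out, "excluded") <- excluded
  out
}

#' Classify family-level transgression by Gaussian model comparison
#'
#' For each family, compares by AIC a Gaussian model in which the F1 mean is
#' constrained to the mid-parent value (additive) against one in which the
#' F1 mean is free. The free model wins only when its AIC is lower *and*
#' the F1 mean falls outside the parental range: above the better parent
#' (`high_parent`) or below the worse (`low_parent`); a free F1 mean within
#' the parental range retains the additive call. Families with fewer than 3
#' F1 replicates are `undetermined`.
#'
#' @param phenotypes Plant-level tibble with `family_id`, `group`, and a
#'   value column.
#' @param value_col Value column (defaults as in [compute_mph()]).
#' @return Tibble with `family_id`, `class`, `aic_additive`, `aic_free`,
#'   and the three group means.
#' @export
classify_transgression <- function(phenotypes, value_col = NULL) {
  value_col <- value_col %||%
    (if ("value_adj" %in% names(phenotypes)) "value_adj" else "value")
  purrr::map_dfr(split(phenotypes, phenotypes$family_id), function(d) {
    y <- d[[value_col]]
    g <- d$group
    out <- tibble::tibble(
      family_id = d$family_id[1], class = NA_character_,
      aic_additive = NA_real_, aic_free = NA_real_,
      mean_mscol = mean(y[g == "msCol"]),
      mean_epiril = mean(y[g == "epiRIL"]),
      mean_f1 = mean(y[g == "F1"])
    )
    if (sum(g == "F1") < 3 || sum(g == "msCol") < 1 || sum(g == "epiRIL") < 1) {
      out$class <- "undetermined"
      return(out)
    }
    # additive: F1 mean constrained to (m1 + m2) / 2; linear in (m1, m2)
    X_add <- cbind(
      (g == "msCol") + 0.5 * (g == "F1"),
      (g == "epiRIL") + 0.5 * (g == "F1")
    )
    fit_add <- lm(y ~ X_add - 1)
    X_free <- cbind((g == "msCol") + 0, (g == "epiRIL") + 0, (g == "F1") + 0)
    fit_free <- lm(y ~ X_free - 1)
    n <- length(y)
    aic_g <- function(fit, k) {
      rss <- sum(residuals(fit)^2)
      n * log(rss / n) + 2 * (k + 1) # +1 for sigma
    }
    out$aic_additive <- aic_g(fit_add, 2)
    out$aic_free <- aic_g(fit_free, 3)
    hi <- max(out$mean_mscol, out$mean_epiril)
    lo <- min(out$mean_mscol, out$mean_epiril)
    out$class <- if (out$aic_free < out$aic_additive && out$mean_f1 > hi) {
      "high_parent"
    } else if (out$aic_free < out$aic_additive && out$mean_f1 < lo) {
      "low_parent"
    } else {
      "additive"
    }
    out
  })
}

#' Between-family fraction of mid-parent heterosis variance
#'
#' One-way random-effects decomposition of plant-level MPH replicates by
#' the method of moments (ANOVA estimator with the unbalanced-design
#' coefficient `n0`): returns the between-family variance component as a
#' fraction of the total. A negative moment estimate is truncated at zero
#' and flagged.
#'
#' @param mph_replicates Tibble with `family_id` and `mph` (one row per
#'   sibling-based MPH replicate).
#' @return One-row tibble: `sigma2_family`, `sigma2_residual`, `fraction`,
#'   `truncated`, `n_families`.
#' @export
variance_components <- function(mph_replicates) {
  d <- mph_replicates[is.finite(mph_replicates$mph), ]
  counts <- table(d$family_id)
  counts <- counts[counts > 0]
  if (length(counts) < 2) abort("Need at least 2 families.")
  if (all(counts < 2)) abort("Need at least one family with >= 2 MPH replicates.")
  fit <- aov(mph ~ family_id, data = dplyr::mutate(d, family_id = factor(.data$family_id)))
  ms <- summary(fit)[[1]]$`Mean Sq`
  msb <- ms[1]
  msw <- ms[2]
  N <- nrow(d)
  a <- length(counts)
  n0 <- (N - sum(counts^2) / N) / (a - 1)
  s2f <- (msb - msw) / n0
  truncated <- s2f < 0
  s2f <- max(s2f, 0)
  tibble::tibble(
    sigma2_family = s2f, sigma2_residual = msw,
    fraction = if (s2f + msw == 0) 0 else s2f / (s2f + msw),
    truncated = truncated, n_families = a
  )
}

#' Plant-level MPH replicates
#'
#' Expresses each F1 plant's value as a percent divergence from its
#' family's mid-parent value, giving sibling-level MPH replicates for
#' variance decomposition.
#'
#' @param phenotypes Plant-level tibble (`family_id`, `group`, value).
#' @param mph_table Family-level table from [compute_mph()] (supplies MPV).
#' @param value_col Value column.
#' @return Tibble with `family_id`, `plant_id`, `mph`.
#' @export
mph_replicates <- function(phenotypes, mph_table, value_col = NULL) {
  value_col <- value_col %||%
    (if ("value_adj" %in% names(phenotypes)) "value_adj" else "value")
  f1 <- phenotypes[phenotypes$group == "F1", ]
  mpv <- mph_table$mpv[match(f1$family_id, mph_table$family_id)]
  out <- tibble::tibble(
    family_id = f1$family_id,
    plant_id = f1$plant_id %||% as.character(seq_len(nrow(f1))),
    mph = (f1[[value_col]] - mpv) / mpv * 100
  )
  out[!is.na(out$mph), ]
}

#' Phenotypic QTL scan for mid-parent heterosis
#'
#' Haley-Knott genome scan of family-level MPH with a per-trait permutation
#' threshold, exactly as in the methylation QTL analysis; peak markers are
#' additionally required to pass a one-way ANOVA of MPH on the marker
#' epigenotype at `anova_alpha`. For each retained QTL the per-class MPH
#' values (MM vs UU) are returned for effect plots.
#'
#' @param map An `epimap` with epigenotypes.
#' @param family_mph Named numeric vector of MPH, one value per line
#'   (names = line/family ids), or the tibble from [compute_mph()].
#' @param step_cM,n_perm,alpha,drop,lod_cap As in [run_nad_qtl()].
#' @param anova_alpha Retention threshold for the peak-marker ANOVA.
#' @param seed Optional seed for the permutations.
#' @return A `pheno_qtl` object: list with `peaks` (retained QTL rows with
#'   `anova_p`, `r_squared`, `sign`), `scan`, `threshold` and
#'   `effect_data` (tibble `family_id`, `marker_id`, `epigenotype`, `mph`).
#' @export
pheno_qtl_scan <- function(map, family_mph, step_cM = 2, n_perm = 1000,
                           alpha = 0.05, drop = 2, lod_cap = 50,
                           anova_alpha = 0.05, seed = NULL) {
  if (is.data.frame(family_mph)) {
    family_mph <- setNames(family_mph$mph, family_mph$family_id)
  }
  y <- family_mph[rownames(map$geno)]
  names(y) <- rownames(map$geno)
  gp <- genotype_probabilities(map, step_cM)
  scan <- hk_scan(gp, y, lod_cap = lod_cap)
  thr <- permutation_threshold(gp, y,
    n_perm = n_perm, alpha = alpha,
    lod_cap = lod_cap, seed = seed
  )
  pk <- peaks_and_ci(scan, thr, drop = drop)
  effect_data <- tibble::tibble()
  if (nrow(pk)) {
    res <- purrr::map_dfr(seq_len(nrow(pk)), function(i) {
      mk <- map$markers[map$markers$chrom == pk$chrom[i], ]
      nearest <- mk$marker_id[which.min(abs(mk$cM - pk$peak_cM[i]))]
      g <- map$geno[, nearest]
      ok <- is.finite(y)
      av <- anova(lm(y[ok] ~ factor(g[ok])))
      eff <- qtl_effect(y, g)
      dplyr::bind_cols(
        tibble::tibble(marker_id = nearest, anova_p = av$`Pr(>F)`[1]), eff
      )
    })
    pk <- dplyr::bind_cols(pk, res)
    pk <- pk[pk$anova_p < anova_alpha, ]
    if (nrow(pk)) {
      effect_data <- purrr::map_dfr(pk$marker_id, function(mk) {
        tibble::tibble(
          family_id = rownames(map$geno), marker_id = mk,
          epigenotype = ifelse(map$geno[, mk] == 1L, "UU", "MM"),
          mph = unname(y)
        )
      })
    }
  }
  structure(
    list(peaks = pk, scan = scan, threshold = as.numeric(thr), effect_data = effect_data),
    class = "pheno_qtl"
  )
}

#' @export
print.pheno_qtl <- function(x, ...) {
  cat(sprintf(
    "<pheno_qtl> %d retained QTL (threshold %.2f)\n",
    nrow(x$peaks), x$threshold
  ))
  invisible(x)
}

#' Conditional epigenome-wide association study for heterosis
#'
#' Tests whether "de novo" non-additive regions (those without a detected
#' QTL of their own) explain heterotic variance beyond a core model of peak
#' QTL epigenotypes. For each region, the core model `MPH ~ core markers`
#' is compared with the nested model adding that region's `%` mid-parent
#' methylation divergence, by a likelihood ratio test (chi-square, 1 df);
#' p-values are Benjamini-Yekutieli adjusted. Significant regions are
#' grouped by hierarchical clustering on principal-component scores (the
#' cluster count maximizes the average silhouette over `k_range`), one
#' proxy region with maximal added R-squared is kept per cluster, and the
#' final model core + proxies yields the core vs de novo variance split.
#'
#' @param core_geno Matrix (families x markers, 0/1) of core QTL
#'   epigenotypes.
#' @param nad_divergence Matrix (regions x families) of `%` mid-parent
#'   methylation divergence for de novo regions.
#' @param family_mph Named numeric MPH per family.
#' @param fdr Benjamini-Yekutieli cutoff.
#' @param k_range Candidate cluster counts.
#' @return A `cond_ewas` object: list with `table` (per-region LRT
#'   results), `proxies`, `k`, `r2_core`, `r2_denovo`, `r2_total`.
#' @export
conditional_ewas <- function(core_geno, nad_divergence, family_mph,
                             fdr = 0.05, k_range = 2:10) {
  fam <- intersect(
    rownames(core_geno),
    intersect(colnames(nad_divergence), names(family_mph))
  )
  if (length(fam) < nrow(core_geno)) {
    core_geno <- core_geno[fam, , drop = FALSE]
  }
  y <- family_mph[fam]
  X <- core_geno[fam, , drop = FALSE]
  D <- nad_divergence[, fam, drop = FALSE]
  core <- lm(y ~ X)
  rss0 <- sum(residuals(core)^2)
  r2_core <- summary(core)$r.squared
  n <- length(y)
  tab <- purrr::map_dfr(rownames(D), function(id) {
    d <- D[id, ]
    ok <- is.finite(d) & is.finite(y)
    if (sum(ok) < ncol(X) + 3 || var(d[ok]) == 0) {
      return(tibble::tibble(
        nad_id = id, lrt = NA_real_, p = NA_real_, added_r2 = NA_real_
      ))
    }
    f0 <- lm(y[ok] ~ X[ok, , drop = FALSE])
    f1 <- lm(y[ok] ~ X[ok, , drop = FALSE] + d[ok])
    nn <- sum(ok)
    lrt <- nn * log(sum(residuals(f0)^2) / sum(residuals(f1)^2))
    tibble::tibble(
      nad_id = id, lrt = lrt,
      p = pchisq(lrt, df = 1, lower.tail = FALSE),
      added_r2 = summary(f1)$r.squared - summary(f0)$r.squared
    )
  })
  tab$q <- by_adjust(tab$p)
  sig <- tab$nad_id[!is.na(tab$q) & tab$q < fdr]
  proxies <- character()
  k <- NA_integer_
  r2_total <- r2_core
  cluster_assign <- NULL
  if (length(sig) >= 2) {
    M <- D[sig, , drop = FALSE]
    M[!is.finite(M)] <- 0
    keep_col <- apply(M, 2, sd) > 0
    pc <- prcomp(M[, keep_col, drop = FALSE], scale. = TRUE)
    npc <- min(5, ncol(pc$x))
    sc <- pc$x[, seq_len(npc), drop = FALSE]
    hc <- hclust(dist(sc), method = "ward.D2")
    ks <- k_range[k_range < length(sig)]
    if (length(ks)) {
      sil <- vapply(ks, function(kk) {
        cl <- cutree(hc, kk)
        mean(cluster::silhouette(cl, dist(sc))[, 3])
      }, numeric(1))
      k <- ks[which.max(sil)]
      cl <- cutree(hc, k)
    } else {
      k <- 1L
      cl <- rep(1L, length(sig))
    }
    cluster_assign <- tibble::tibble(nad_id = sig, cluster = unname(cl))
    proxies <- vapply(split(sig, cl), function(ids) {
      r2 <- tab$added_r2[match(ids, tab$nad_id)]
      ids[which.max(r2)]
    }, character(1))
    P <- t(D[proxies, , drop = FALSE])
    P[!is.finite(P)] <- 0
    final <- lm(y ~ X + P)
    if (anyNA(coef(final))) {
      warn("Collinear proxy set; aliased proxies dropped from the final model.")
    }
    r2_total <- summary(final)$r.squared
  } else if (length(sig) == 1) {
    proxies <- sig
    k <- 1L
    d <- D[sig, ]
    d[!is.finite(d)] <- 0
    r2_total <- summary(lm(y ~ X + d))$r.squared
  }
  if (!is.null(cluster_assign)) {
    tab <- dplyr::left_join(tab, cluster_assign, by = "nad_id")
  } else {
    tab$cluster <- NA_integer_
  }
  structure(
    list(
      table = tab, proxies = unname(proxies), k = k,
      r2_core = r2_core, r2_denovo = r2_total - r2_core,
      r2_total = r2_total, n_families = n
    ),
    class = "cond_ewas"
  )
}

#' @export
print.cond_ewas <- function(x, ...) {
  cat(sprintf(
    "<cond_ewas> %d region(s) tested, %d proxies in %s cluster(s); R2 core %.3f + de novo %.3f = %.3f\n",
    nrow(x$table), length(x$proxies), x$k, x$r2_core, x$r2_denovo, x$r2_total
  ))
  invisible(x)
}

#' @rdname conditional_ewas
#' @param x A `cond_ewas` object.
#' @param ... Unused.
#' @method tidy cond_ewas
#' @export
tidy.cond_ewas <- function(x, ...) x$table

#' @rdname conditional_ewas
#' @method glance cond_ewas
#' @export
glance.cond_ewas <- function(x, ...) {
  tibble::tibble(
    r2_core = x$r2_core, r2_denovo = x$r2_denovo, r2_total = x$r2_total,
    k_clusters = x$k, n_proxies = length(x$proxies),
    n_families = x$n_families
  )
}

#' Linkage disequilibrium between two markers
#'
#' Squared Pearson correlation of the binary epigenotype codes.
#'
#' @param genotype_a,genotype_b Vectors over the same lines, coded 0/1 or
#'   `"MM"`/`"UU"`.
#' @return Scalar r-squared.
#' @export
marker_ld <- function(genotype_a, genotype_b) {
  code <- function(g) {
    if (is.character(g) || is.factor(g)) as.numeric(as.character(g) == "UU") else as.numeric(g)
  }
  a <- code(genotype_a)
  b <- code(genotype_b)
  if (var(a) == 0 || var(b) == 0) abort("Monomorphic marker.")
  cor(a, b)^2
}
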