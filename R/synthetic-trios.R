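#' Build a synthetic region specification tied to a marker map
#'
#' Lays 200-bp regions (on a 50-bp step grid) along each chromosome:
#' one "marker-local" region at every marker position (the segregating
#' parental DMR the marker tags) plus background regions at random grid
#' positions. Pericentromere intervals default to the middle 40% of each
#' chromosome.
#'
#' @param map An `epimap` (skeleton or populated).
#' @param n_background Background regions per chromosome.
#' @param region_size,step_bp Region width and step grid in bp; the step
#'   must divide the region size.
#' @param contexts Cytosine contexts to assign (recycled over regions).
#' @param meth_prob Probability that a background region is methylated in
#'   both parents.
#' @param peri_fraction Width of the pericentromere as a fraction of the
#'   chromosome, centred on the midpoint.
#' @param seed Optional seed for background placement.
#' @return List with `regions` (tibble: `region_id`, `chrom`, `start`,
#'   `end`, `context`, `role`, `marker_id`, `mscol_state`) and `peri`
#'   (tibble: `chrom`, `start`, `end`), 0-based half-open coordinates.
#' @export
build_region_spec <- function(map, n_background = 40, region_size = 200,
                              step_bp = 50, contexts = c("CG", "CHG", "CHH"),
                              meth_prob = 0.5, peri_fraction = 0.4,
                              seed = NULL) {
  stopifnot(inherits(map, "epimap"))
  if (region_size %% step_bp != 0) {
    abort("`step_bp` must divide `region_size`.")
  }
  with_seed_(seed, {
    chrom_span <- dplyr::summarise(
      dplyr::group_by(map$markers, .data$chrom),
      max_bp = max(.data$bp) + 1e5
    )
    marker_regions <- dplyr::transmute(
      map$markers,
      chrom = .data$chrom,
      start = pmax(0, (.data$bp %/% step_bp) * step_bp),
      end = .data$start + region_size,
      role = "marker_local",
      marker_id = .data$marker_id
    )
    bg <- purrr::pmap_dfr(chrom_span, function(chrom, max_bp) {
      pos <- sort(sample.int(max_bp %/% step_bp, n_background)) * step_bp
      tibble::tibble(
        chrom = chrom, start = pos, end = pos + region_size,
        role = "background", marker_id = NA_character_
      )
    })
    regions <- dplyr::arrange(
      dplyr::bind_rows(marker_regions, bg),
      .data$chrom, .data$start, .data$role
    )
    regions <- dplyr::distinct(regions, .data$chrom, .data$start, .keep_all = TRUE)
    regions$region_id <- sprintf("reg_%04d", seq_len(nrow(regions)))
    regions$context <- rep_len(contexts, nrow(regions))
    # Parents: marker-local regions are methylated in the wild-type maternal
    # parent (they are ddm1-induced hypomethylation markers); background
    # regions get a fixed random parental state.
    regions$mscol_state <- ifelse(
      regions$role == "marker_local", 1,
      as.numeric(runif(nrow(regions)) < meth_prob)
    )
    regions <- dplyr::relocate(regions, "region_id")
    peri <- dplyr::transmute(
      chrom_span,
      chrom = .data$chrom,
      start = round(.data$max_bp * (0.5 - peri_fraction / 2)),
      end = round(.data$max_bp * (0.5 + peri_fraction / 2))
    )
    list(regions = regions, peri = dplyr::ungroup(peri))
  })
}

#' Declare planted methylation QTL effects
#'
#' @param marker_id Controlling marker.
#' @param target_region_ids Regions remodeled when the effect fires.
#' @param effect_sign `+1`: trans-chromosomal methylation (TCM, hybrid gain)
#'   in families whose paternal epiRIL is UU at the marker; `-1`:
#'   trans-chromosomal demethylation (TCdM, hybrid loss) in UU families.
#'   MM families stay additive at the targets.
#' @param penetrance Probability the remodeling event occurs in a
#'   susceptible family, in `[0, 1]`.
#' @return Tibble with one row per (marker, target) pair.
#' @export
plant_qtl <- function(marker_id, target_region_ids, effect_sign = 1,
                      penetrance = 1) {
  if (penetrance < 0 || penetrance > 1) {
    abort("`penetrance` must lie in [0, 1].")
  }
  if (!effect_sign %in% c(-1, 1)) {
    abort("`effect_sign` must be +1 or -1.")
  }
  tibble::tibble(
    marker_id = marker_id, target_region_id = target_region_ids,
    effect_sign = effect_sign, penetrance = penetrance
  )
}

#' Simulate trio methylation state matrices
#'
#' Generates region-level state calls for the maternal msCol parent, each
#' paternal epiRIL and each F1 hybrid. Parents are binary (0 unmethylated, 1
#' methylated); hybrids may be intermediate (0.5). The epiRIL state at a
#' marker-local region is unmethylated exactly when the line is UU at that
#' marker (subject to a small call-error rate). Hybrid states follow the
#' additive expectation -- the mid-parent value {0, 0.5, 1} mapped directly
#' onto states -- except at planted QTL target regions, where in susceptible
#' (UU) families a TCM or TCdM event fires with probability `penetrance`,
#' shifting the hybrid one state step above or below the mid-parent value.
#'
#' @param map An `epimap` with line epigenotypes.
#' @param region_spec Output of [build_region_spec()].
#' @param planted_qtl Optional tibble from [plant_qtl()] (rows may be bound
#'   together for several QTL).
#' @param noise Per-call probability of flipping an epiRIL marker-local
#'   state call.
#' @param seed Optional seed.
#' @return A `trio_states` object: list with `regions`, `peri`, `mscol`
#'   (named numeric vector per region), `epiril` and `hybrid` (region x
#'   family matrices), `families` (character vector of family ids) and
#'   `planted_qtl`.
#' @export
simulate_trio_methylomes <- function(map, region_spec, planted_qtl = NULL,
                                     noise = 0, seed = NULL) {
  stopifnot(inherits(map, "epimap"), !is.null(map$geno))
  regions <- region_spec$regions
  if (!is.null(planted_qtl)) {
    bad_m <- setdiff(planted_qtl$marker_id, map$markers$marker_id)
    if (length(bad_m)) abort(paste0("Unknown marker id(s): ", paste(bad_m, collapse = ", ")))
    bad_r <- setdiff(planted_qtl$target_region_id, regions$region_id)
    if (length(bad_r)) abort(paste0("Unknown region id(s): ", paste(bad_r, collapse = ", ")))
  }
  with_seed_(seed, {
    fams <- rownames(map$geno)
    n_reg <- nrow(regions)
    n_fam <- length(fams)
    mscol <- setNames(regions$mscol_state, regions$region_id)
    # Planted target regions get parental states that leave room for the
    # planted event: TCM targets are SMR-unmethylated (MPV 0), TCdM targets
    # SMR-methylated (MPV 1).
    if (!is.null(planted_qtl)) {
      tcm <- planted_qtl$target_region_id[planted_qtl$effect_sign > 0]
      tcdm <- planted_qtl$target_region_id[planted_qtl$effect_sign < 0]
      mscol[tcm] <- 0
      mscol[tcdm] <- 1
    }
    epiril <- matrix(rep(mscol, n_fam), n_reg, n_fam,
      dimnames = list(regions$region_id, fams)
    )
    is_local <- regions$role == "marker_local"
    if (any(is_local)) {
      g <- t(map$geno[, regions$marker_id[is_local], drop = FALSE]) # regions x fams
      st <- 1 - g # UU line -> unmethylated at its marker DMR
      if (noise > 0) {
        flip <- matrix(runif(length(st)) < noise, nrow(st), ncol(st))
        st[flip] <- 1 - st[flip]
      }
      epiril[is_local, ] <- st
    }
    mpv <- (matrix(mscol, n_reg, n_fam) + epiril) / 2
    hybrid <- mpv # additive expectation maps {0,.5,1} onto states directly
    if (!is.null(planted_qtl)) {
      for (k in seq_len(nrow(planted_qtl))) {
        q <- planted_qtl[k, ]
        uu <- map$geno[, q$marker_id] == 1L
        fires <- uu & (runif(n_fam) < q$penetrance)
        if (any(fires)) {
          i <- match(q$target_region_id, regions$region_id)
          cur <- hybrid[i, fires]
          hybrid[i, fires] <- if (q$effect_sign > 0) pmin(1, cur + 0.5) else pmax(0, cur - 0.5)
        }
      }
    }
    dimnames(hybrid) <- dimnames(epiril)
    structure(
      list(
        regions = regions, peri = region_spec$peri, mscol = mscol,
        epiril = epiril, hybrid = hybrid, families = fams,
        planted_qtl = planted_qtl
      ),
      class = "trio_states"
    )
  })
}

#' @export
print.trio_states <- function(x, ...) {
  cat(sprintf(
    "<trio_states> %d regions x %d families (%d planted QTL target rows)\n",
    nrow(x$regions), length(x$families),
    if (is.null(x$planted_qtl)) 0L else nrow(x$planted_qtl)
  ))
  invisible(x)
}

#' Declare planted phenotypic QTL effects
#'
#' @param marker_id Marker carrying the effect.
#' @param mph_effect Difference in mean mid-parent heterosis (percentage
#'   points) between MM and UU families; positive values mean MM families
#'   show the higher heterosis, the direction observed for leaf area.
#' @return One-row tibble.
#' @export
plant_pheno_qtl <- function(marker_id, mph_effect) {
  tibble::tibble(marker_id = marker_id, mph_effect = mph_effect)
}

#' Simulate per-plant phenotypes for parents and hybrids
#'
#' Generates plant-level values for the maternal parent, the paternal epiRIL
#' and the F1 of every family so that mid-parent heterosis (MPH) is
#' computable. Family-level MPH is built as the sum of planted marker
#' effects (applied to MM families), a family random effect, and plant-level
#' residual noise; both variance components are expressed in MPH percentage
#' points. Fixed covariate effects (experiment, block, germination date) are
#' added on the raw measurement scale so that environment adjustment can be
#' exercised downstream.
#'
#' @param map An `epimap` with line epigenotypes; one family per line.
#' @param pheno_qtl Optional tibble from [plant_pheno_qtl()].
#' @param n_sibs Plants per family and group (>= 1).
#' @param variance List with `family` and `residual` variances (MPH
#'   percentage-point scale, both >= 0).
#' @param covariate_design List of named numeric vectors giving the fixed
#'   effect of each covariate level on the raw scale; defaults to three
#'   experiments, eight blocks and three germination dates with modest
#'   effects.
#' @param grand_mean Baseline plant value (arbitrary units, e.g. projected
#'   leaf area).
#' @param seed Optional seed.
#' @return Tibble with `plant_id`, `family_id`, `group` (`msCol`, `epiRIL`,
#'   `F1`), `value`, `experiment`, `block`, `germination_date`.
#' @export
simulate_phenotypes <- function(map, pheno_qtl = NULL, n_sibs = 6,
                                variance = list(family = 30, residual = 70),
                                covariate_design = default_covariate_design(),
                                grand_mean = 100, seed = NULL) {
  stopifnot(inherits(map, "epimap"), !is.null(map$geno))
  if (n_sibs < 1) abort("`n_sibs` must be at least 1.")
  if (variance$family < 0 || variance$residual < 0) {
    abort("Variance components must be non-negative.")
  }
  if (!is.null(pheno_qtl)) {
    bad <- setdiff(pheno_qtl$marker_id, map$markers$marker_id)
    if (length(bad)) abort(paste0("Unknown marker id(s): ", paste(bad, collapse = ", ")))
  }
  with_seed_(seed, {
    fams <- rownames(map$geno)
    n_fam <- length(fams)
    fam_eff <- rnorm(n_fam, 0, sqrt(variance$family))
    qtl_eff <- rep(0, n_fam)
    if (!is.null(pheno_qtl)) {
      for (k in seq_len(nrow(pheno_qtl))) {
        mm <- map$geno[, pheno_qtl$marker_id[k]] == 0L
        qtl_eff <- qtl_eff + pheno_qtl$mph_effect[k] * as.numeric(mm)
      }
    }
    mph_true <- qtl_eff + fam_eff
    grid <- tidyr::expand_grid(
      family_id = fams,
      group = c("msCol", "epiRIL", "F1"),
      sib = seq_len(n_sibs)
    )
    fi <- match(grid$family_id, fams)
    group_mean <- ifelse(
      grid$group == "F1",
      grand_mean * (1 + mph_true[fi] / 100),
      grand_mean
    )
    res <- rnorm(nrow(grid), 0, sqrt(variance$residual))
    value <- group_mean + grand_mean * res / 100
    out <- tibble::tibble(
      plant_id = sprintf("%s_%s_%02d", grid$family_id, grid$group, grid$sib),
      family_id = grid$family_id,
      group = grid$group,
      value = value
    )
    for (cv in names(covariate_design)) {
      lev <- sample(names(covariate_design[[cv]]), nrow(out), replace = TRUE)
      out[[cv]] <- lev
      out$value <- out$value + unname(covariate_design[[cv]][lev])
    }
    out
  })
}

#' @rdname simulate_phenotypes
#' @export
default_covariate_design <- function() {
  list(
    experiment = c(exp1 = 0, exp2 = 2, exp3 = -2),
    block = setNames(seq(-1.75, 1.75, by = 0.5), paste0("block", 1:8)),
    germination_date = c(d0 = 0, d1 = 1, d2 = -1)
  )
}

#' Simulate methylation-coupled count matrices
#'
#' Draws negative-binomial counts whose mean is tied to the methylation
#' state of each region (24-nt sRNA-like track) or of a linked region (gene
#' expression-like track). The mean for a sample is
#' `base_mean * multiplier[state]`, with multipliers keyed by state call
#' (`"0"`, `"0.5"`, `"1"`); a direction of `-1` for a gene swaps the
#' multipliers so expression decreases with methylation.
#'
#' @param trios A `trio_states` object.
#' @param coupling List with `base_mean` (> 0 or 0 for an all-zero track),
#'   `multipliers` (named, all > 0), `dispersion` (> 0; NB size is
#'   `1/dispersion`).
#' @param features Tibble (`feature_id`, `region_id`, `direction`) linking
#'   count features to regions; defaults to one sRNA feature per region with
#'   direction `+1`.
#' @param seed Optional seed.
#' @return List with `counts` (features x samples integer matrix; columns
#'   `msCol`, then one per epiRIL, then one per hybrid) and `features`.
#' @export
simulate_counts <- function(trios, coupling = list(
                              base_mean = 20,
                              multipliers = c(`0` = 1, `0.5` = 2, `1` = 4),
                              dispersion = 0.1
                            ),
                            features = NULL, seed = NULL) {
  stopifnot(inherits(trios, "trio_states"))
  if (any(coupling$multipliers <= 0)) abort("Coupling multipliers must be > 0.")
  if (coupling$dispersion <= 0) abort("Dispersion must be > 0.")
  if (is.null(features)) {
    features <- tibble::tibble(
      feature_id = paste0("sRNA_", trios$regions$region_id),
      region_id = trios$regions$region_id,
      direction = 1
    )
  }
  bad <- setdiff(features$region_id, trios$regions$region_id)
  if (length(bad)) abort(paste0("Unknown region id(s): ", paste(bad, collapse = ", ")))
  with_seed_(seed, {
    ri <- match(features$region_id, trios$regions$region_id)
    state_mat <- cbind(
      msCol = trios$mscol,
      trios$epiril,
      trios$hybrid
    )[ri, , drop = FALSE]
    colnames(state_mat) <- c(
      "msCol",
      paste0(colnames(trios$epiril), "_epiRIL"),
      paste0(colnames(trios$hybrid), "_F1")
    )
    mult <- coupling$multipliers[as.character(state_mat)]
    mult <- matrix(mult, nrow(state_mat), ncol(state_mat))
    flip <- features$direction < 0
    if (any(flip)) {
      # reverse coupling: high methylation -> low expression
      rng <- range(coupling$multipliers)
      mult[flip, ] <- sum(rng) - mult[flip, ]
    }
    mu <- coupling$base_mean * mult
    counts <- matrix(
      rnbinom(length(mu), mu = mu, size = 1 / coupling$dispersion),
      nrow(mu), ncol(mu),
      dimnames = list(features$feature_id, colnames(state_mat))
    )
    list(counts = counts, features = features)
  })
}
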