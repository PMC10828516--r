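test_that("ordered quantile normalization is a rank-to-normal map", {
  x <- c(1, 2, 3)
  z <- orq_normalize(x)
  expect_equal(z[2], 0)
  expect_equal(z[1], -z[3])
  # rank invariance under strictly monotone transforms
  set.seed(1)
  y <- rnorm(50)
  expect_equal(orq_normalize(y), orq_normalize(exp(y)))
  # ties map to equal outputs
  t <- orq_normalize(c(1, 1, 2, 3))
  expect_equal(t[1], t[2])
  # large already-normal sample stays close to N(0,1)
  big <- rnorm(5000)
  ks <- suppressWarnings(stats::ks.test(orq_normalize(big), "pnorm"))
  expect_gt(ks$p.value, 0.01)
  expect_error(orq_normalize(c(1, 1, 1)), "Constant")
  expect_error(orq_normalize(c(1, 2)), "3 finite")
})

test_that("genotype probabilities follow the two-point Haldane formula", {
  spec <- list(
    chromosomes = tibble::tibble(chrom = "chr1", length_cM = 10, length_bp = 1e6),
    spacing_cM = 10
  )
  ped <- simulate_epiril_pedigree(simulate_marker_map(spec), 200, seed = 3)
  gp <- genotype_probabilities(ped, step_cM = 5)
  # marker positions reproduce the observed genotypes
  at0 <- which(gp$grid$cM == 0)
  expect_equal(gp$prob[, at0], unname(ped$geno[, 1]))
  # midpoint between discordant flanks -> 1/2 by symmetry
  mid <- which(gp$grid$cM == 5)
  disc <- ped$geno[, 1] != ped$geno[, 2]
  expect_true(all(abs(gp$prob[disc, mid] - 0.5) < 1e-12))
  # flanking UU/UU at 10 cM, midpoint: closed-form (1-r5)^2 / (1-r10)
  uu <- ped$geno[, 1] == 1 & ped$geno[, 2] == 1
  skip_if(!any(uu))
  r5 <- haldane(5)
  r10 <- haldane(10)
  expect_equal(
    unique(gp$prob[uu, mid]),
    (1 - r5)^2 / (1 - r10),
    tolerance = 1e-12
  )
  expect_equal(round((1 - r5)^2 / (1 - r10), 4), 0.9975)
  expect_error(genotype_probabilities(ped, step_cM = 0), "positive")
})

test_that("Haley-Knott LOD at marker positions equals single-marker regression", {
  ped <- tiny_panel(80, seed = 13)
  set.seed(5)
  y <- 0.8 * ped$geno[, 4] + rnorm(80)
  names(y) <- rownames(ped$geno)
  scan <- hk_scan(ped, y, step_cM = 2)
  n <- attr(scan, "n")
  for (mk in sample(ped$markers$marker_id, 5)) {
    g <- ped$geno[, mk]
    rss0 <- sum((y - mean(y))^2)
    rss1 <- sum(residuals(lm(y ~ g))^2)
    lod_oracle <- (n / 2) * log10(rss0 / rss1)
    got <- scan$lod[which(scan$marker_id == mk)]
    expect_equal(got, lod_oracle, tolerance = 1e-9)
  }
})

test_that("hk_scan handles null, perfect-fit and degenerate traits", {
  ped <- tiny_panel(200, seed = 17)
  set.seed(2)
  y0 <- rnorm(200)
  names(y0) <- rownames(ped$geno)
  s0 <- hk_scan(ped, y0)
  expect_lt(max(s0$lod), 6) # null trait: no extreme LOD
  # perfect fit capped at the sentinel
  yp <- as.numeric(ped$geno[, 3])
  names(yp) <- rownames(ped$geno)
  sp <- hk_scan(ped, yp, lod_cap = 50)
  expect_equal(max(sp$lod), 50)
  yc <- rep(1, 200)
  names(yc) <- rownames(ped$geno)
  expect_error(hk_scan(ped, yc), "Zero-variance")
  expect_error(hk_scan(ped, y0[1:5]), "one value per line")
})

test_that("permutation threshold edge cases and stability", {
  ped <- tiny_panel(60, seed = 19)
  set.seed(3)
  y <- rnorm(60)
  names(y) <- rownames(ped$geno)
  thr1 <- permutation_threshold(ped, y, n_perm = 200, alpha = 1, seed = 1)
  expect_equal(
    as.numeric(thr1),
    min(attr(thr1, "max_lods"))
  )
  ta <- permutation_threshold(ped, y, n_perm = 400, seed = 2)
  tb <- permutation_threshold(ped, y, n_perm = 800, seed = 3)
  expect_lt(abs(as.numeric(ta) - as.numeric(tb)), 0.5)
  expect_error(permutation_threshold(ped, y, n_perm = 10), "at least 100")
})

test_that("peaks and confidence intervals follow the LOD-drop rule", {
  grid <- tibble::tibble(
    chrom = rep(c("chr1", "chr2"), each = 11),
    cM = rep(seq(0, 20, by = 2), 2),
    bp = rep(seq(0, 2e6, by = 2e5), 2),
    marker_id = NA_character_,
    lod = c(
      pmax(6 - abs(seq(-10, 10, by = 2)) / 2, 0), # triangular peak, max 6
      rep(0.5, 11)
    )
  )
  scan <- structure(grid, class = c("epiqtl_scan", class(grid)))
  pk <- peaks_and_ci(scan, threshold = 3, drop = 2)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$chrom, "chr1")
  expect_equal(pk$peak_cM, 10)
  # CI spans LOD >= 4: positions where 6 - |d|/2 >= 4 -> |d| <= 4 cM
  expect_equal(pk$ci_lo_cM, 6)
  expect_equal(pk$ci_hi_cM, 14)
  # flat curve below threshold -> no peaks
  expect_equal(nrow(peaks_and_ci(scan, threshold = 10)), 0)
  # both chromosomes above threshold -> one peak per chromosome
  grid2 <- dplyr::mutate(grid, lod = .data$lod + 3)
  scan2 <- structure(grid2, class = class(scan))
  expect_equal(nrow(peaks_and_ci(scan2, threshold = 3)), 2)
  expect_error(peaks_and_ci(scan, 3, drop = 0), "positive")
})

test_that("cis/trans calls require containment in the confidence interval", {
  pk <- tibble::tibble(
    chrom = "chr1", ci_lo_bp = 1e5, ci_hi_bp = 2e5
  )
  expect_equal(
    cis_trans_call(pk, tibble::tibble(chrom = "chr2", start = 1.5e5, end = 1.6e5)),
    "trans"
  )
  expect_equal(
    cis_trans_call(pk, tibble::tibble(chrom = "chr1", start = 1.5e5, end = 1.6e5)),
    "cis"
  )
  # straddling the boundary -> trans
  expect_equal(
    cis_trans_call(pk, tibble::tibble(chrom = "chr1", start = 1.9e5, end = 2.1e5)),
    "trans"
  )
})

test_that("QTL effect regression returns R2 and slope direction", {
  g <- c(rep(0, 10), rep(1, 10))
  expect_equal(qtl_effect(rep(5, 20), g)$r_squared, 0)
  r <- qtl_effect(2 * g, g)
  expect_equal(r$r_squared, 1)
  expect_equal(r$sign, "positive")
  expect_error(qtl_effect(rnorm(10), rep(1, 10)), "Both epigenotype")
  # MM/UU coding equals 0/1 coding
  expect_equal(
    qtl_effect(2 * g + 1, ifelse(g == 1, "UU", "MM")),
    qtl_effect(2 * g + 1, g)
  )
})

test_that("Benjamini-Yekutieli adjustment matches the hand-computed example", {
  expect_equal(by_adjust(c(0.01, 0.02, 0.03)), rep(0.055, 3), tolerance = 1e-12)
  expect_equal(by_adjust(0.2), 0.2) # m = 1
  p <- runif(20)
  expect_true(all(by_adjust(p) >= p)) # conservative
  # monotone transform of raw p-values
  o <- order(p)
  expect_true(all(diff(by_adjust(p)[o]) >= -1e-12))
  expect_error(by_adjust(c(-0.1, 0.5)), "\\[0, 1\\]")
})

test_that("planted effect size is recovered across simulated panels", {
  # slope/R2 recovery: planted R2 ~ 0.38-style effect at n = 169
  set.seed(12)
  r2s <- replicate(20, {
    g <- rbinom(169, 1, 0.25)
    beta <- 1
    # choose noise so the population R2 is 0.38
    vg <- var(g) * beta^2
    ve <- vg * (1 - 0.38) / 0.38
    y <- beta * g + rnorm(169, 0, sqrt(ve))
    qtl_effect(y, g)$r_squared
  })
  expect_lt(abs(mean(r2s) - 0.38), 0.08)
})

test_that("full NAD-QTL chain recovers a planted distal QTL and controls the null", {
  px <- planted_trios(n_lines = 80, penetrance = 1, seed = 91)
  sc <- classify_trios(px$trios)
  res <- run_nad_qtl(
    px$map, scenario_divergence_matrix(sc), px$rs$regions,
    scenarios = sc, nad = scenario_nad_matrix(sc),
    share_min_frac = 0.1, n_perm = 200, seed = 7
  )
  a <- tidy(res)
  expect_true(all(px$qtl$target_region_id %in% a$trait_id))
  hit <- a[a$trait_id == px$qtl$target_region_id[1], ]
  mk <- px$map$markers[px$map$markers$marker_id == px$qtl$marker_id[1], ]
  expect_true(mk$chrom %in% hit$chrom)
  expect_equal(unique(hit$cis_trans), "trans")
  expect_equal(unique(hit$predominant_scenario), "TCM")
  expect_equal(unique(hit$sign), "positive")

  # null panel: no planted effects -> no (or almost no) discoveries
  p0 <- planted_trios(n_lines = 80, penetrance = 0, seed = 92)
  sc0 <- classify_trios(p0$trios)
  expect_error(
    run_nad_qtl(
      p0$map, scenario_divergence_matrix(sc0), p0$rs$regions,
      nad = scenario_nad_matrix(sc0), share_min_frac = 0.1,
      n_perm = 200, seed = 8
    ),
    "sharing filter" # nothing is remodeled, so no trait qualifies
  )
})
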