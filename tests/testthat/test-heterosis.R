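test_that("environment adjustment removes planted fixed effects and outliers", {
  set.seed(21)
  n <- 400
  d <- tibble::tibble(
    plant_id = as.character(1:n),
    family_id = rep(paste0("f", 1:40), each = 10),
    group = "F1",
    block = rep(c("b1", "b2"), n / 2),
    experiment = "e1",
    germination_date = "d0",
    value = rnorm(n, 100, 3) + ifelse(rep(c(TRUE, FALSE), n / 2), 10, 0)
  )
  adj <- adjust_environment(d)
  delta <- abs(
    mean(adj$value_adj[adj$block == "b1"]) - mean(adj$value_adj[adj$block == "b2"])
  )
  expect_lt(delta, 1)
  # no covariate effect -> adjusted values track the raw ones
  d0 <- dplyr::mutate(d, value = rnorm(n, 100, 3))
  adj0 <- adjust_environment(d0)
  expect_gt(cor(adj0$value, adj0$value_adj), 0.99)
  # outliers beyond 3 SD are removed before fitting
  d2 <- d
  d2$value[1] <- 1e5
  adj2 <- adjust_environment(d2)
  expect_false("1" %in% adj2$plant_id)
})

test_that("MPH arithmetic matches hand computation and exclusion rules", {
  mk <- function(f, g, v, n = 6) {
    tibble::tibble(
      plant_id = paste(f, g, seq_len(n)), family_id = f, group = g,
      value = rep(v, n)
    )
  }
  d <- dplyr::bind_rows(
    mk("famA", "msCol", 100), mk("famA", "epiRIL", 140), mk("famA", "F1", 150),
    mk("famB", "msCol", 100), mk("famB", "epiRIL", 140), mk("famB", "F1", 140),
    mk("famC", "msCol", 100), mk("famC", "epiRIL", 140), mk("famC", "F1", 120),
    mk("famD", "msCol", 100), mk("famD", "epiRIL", 140), mk("famD", "F1", 150, n = 2)
  )
  mph <- suppressMessages(compute_mph(d))
  expect_equal(mph$mph[mph$family_id == "famA"], 25)
  expect_equal(mph$mph[mph$family_id == "famB"], 100 / 6, tolerance = 1e-9)
  expect_equal(mph$mph[mph$family_id == "famC"], 0)
  # famD has < 5 F1 plants -> excluded
  expect_false("famD" %in% mph$family_id)
  expect_true("famD" %in% attr(mph, "excluded"))
  # scale invariance: multiplying all phenotypes leaves MPH unchanged
  mph2 <- suppressMessages(compute_mph(dplyr::mutate(d, value = value * 3.7)))
  expect_equal(mph$mph, mph2$mph)
})

test_that("transgression classification separates the three regimes", {
  set.seed(31)
  mk <- function(f, g, mu, n = 18, sdv = 2) {
    tibble::tibble(
      plant_id = paste(f, g, seq_len(n)), family_id = f, group = g,
      value = rnorm(n, mu, sdv)
    )
  }
  d <- dplyr::bind_rows(
    # F1 at exactly the MPV -> additive
    mk("add", "msCol", 100), mk("add", "epiRIL", 120), mk("add", "F1", 110),
    # F1 far above the better parent -> high parent
    mk("hi", "msCol", 100), mk("hi", "epiRIL", 120), mk("hi", "F1", 130),
    # F1 far below the worse parent -> low parent
    mk("lo", "msCol", 100), mk("lo", "epiRIL", 120), mk("lo", "F1", 90),
    # too few F1 replicates -> undetermined
    dplyr::bind_rows(
      mk("und", "msCol", 100), mk("und", "epiRIL", 120),
      mk("und", "F1", 110, n = 2)
    )
  )
  cls <- classify_transgression(d)
  got <- setNames(cls$class, cls$family_id)
  expect_equal(unname(got[c("add", "hi", "lo", "und")]),
    c("additive", "high_parent", "low_parent", "undetermined"))
})

test_that("transgression classifier is calibrated against generator truth", {
  set.seed(32)
  sim_family <- function(f1_shift) {
    g <- rep(c("msCol", "epiRIL", "F1"), each = 18)
    mu <- c(msCol = 100, epiRIL = 110, F1 = 105 + f1_shift)
    tibble::tibble(
      plant_id = paste0("p", seq_along(g)), family_id = "f",
      group = g, value = rnorm(length(g), mu[g], 3)
    )
  }
  # high-parent truth at a 2 SD effect above the better parent
  hits <- replicate(30, {
    classify_transgression(sim_family(5 + 2 * 3))$class == "high_parent"
  })
  expect_gte(mean(hits), 0.9)
  # additive truth mislabelled rarely
  adds <- replicate(30, {
    classify_transgression(sim_family(0))$class == "additive"
  })
  expect_gte(mean(adds), 0.9)
})

test_that("variance components recover planted splits and handle edge cases", {
  # all family means equal -> fraction 0 (truncated)
  d0 <- tibble::tibble(
    family_id = rep(paste0("f", 1:20), each = 4),
    mph = rep(rnorm(1), 80)
  )
  d0$mph <- 5 # constant
  vc0 <- variance_components(d0)
  expect_equal(vc0$fraction, 0)
  # planted 30:70 split at 500 families
  set.seed(33)
  fam <- rnorm(500, 0, sqrt(30))
  d <- tibble::tibble(
    family_id = rep(paste0("f", 1:500), each = 6),
    mph = rep(fam, each = 6) + rnorm(3000, 0, sqrt(70))
  )
  vc <- variance_components(d)
  expect_lt(abs(vc$fraction - 0.30), 0.03)
  # single replicate per family is unidentifiable
  d1 <- tibble::tibble(family_id = paste0("f", 1:10), mph = rnorm(10))
  expect_error(variance_components(d1), ">= 2 MPH replicates")
  # cross-check the moment estimator against REML (lme4)
  skip_if_not_installed("lme4")
  fit <- lme4::lmer(mph ~ 1 + (1 | family_id), data = d)
  vcs <- as.data.frame(lme4::VarCorr(fit))$vcov
  reml_frac <- vcs[1] / sum(vcs)
  expect_lt(abs(vc$fraction - reml_frac), 0.02)
})

test_that("phenotypic QTL scan detects a planted marker with the right direction", {
  map <- tiny_panel(190, seed = 41)
  mk <- map$markers$marker_id[9]
  ph <- simulate_phenotypes(map,
    pheno_qtl = plant_pheno_qtl(mk, 8),
    n_sibs = 8, variance = list(family = 10, residual = 40),
    covariate_design = list(), seed = 42
  )
  mph <- suppressMessages(compute_mph(ph, min_plants = 5))
  pq <- pheno_qtl_scan(map, mph, n_perm = 300, seed = 43)
  expect_gte(nrow(pq$peaks), 1)
  expect_true(map$markers$chrom[map$markers$marker_id == mk] %in% pq$peaks$chrom)
  # MM families carry the positive effect -> negative slope on the UU code
  expect_true("negative" %in% pq$peaks$sign)
  expect_true(all(pq$peaks$anova_p < 0.05))
  # effect data reproduces the MM > UU pattern
  ed <- pq$effect_data[pq$effect_data$marker_id == pq$peaks$marker_id[1], ]
  expect_gt(
    mean(ed$mph[ed$epigenotype == "MM"], na.rm = TRUE),
    mean(ed$mph[ed$epigenotype == "UU"], na.rm = TRUE)
  )
})

test_that("phenotypic QTL scan is quiet under the null", {
  map <- tiny_panel(100, seed = 44)
  set.seed(45)
  hits <- replicate(10, {
    y <- rnorm(100)
    names(y) <- rownames(map$geno)
    pq <- pheno_qtl_scan(map, y, n_perm = 200, seed = sample.int(1e6, 1))
    nrow(pq$peaks) > 0
  })
  expect_lte(mean(hits), 0.3)
})

test_that("conditional EWAS finds planted de novo structure and stays null otherwise", {
  set.seed(51)
  n_fam <- 120
  fams <- paste0("f", seq_len(n_fam))
  core <- matrix(rbinom(n_fam * 3, 1, 0.25), n_fam,
    dimnames = list(fams, paste0("q", 1:3))
  )
  lat <- matrix(rnorm(n_fam * 4), n_fam, 4)
  mph <- setNames(
    as.vector(core %*% c(5, 4, 3) + lat %*% rep(3, 4) + rnorm(n_fam, 0, 2)),
    fams
  )
  D <- rbind(
    t(sapply(1:32, function(i) lat[, (i - 1) %/% 8 + 1] * 10 + rnorm(n_fam, 0, 2))),
    t(sapply(1:16, function(i) rnorm(n_fam, 0, 5)))
  )
  dimnames(D) <- list(paste0("nad", 1:48), fams)
  ew <- conditional_ewas(core, D, mph)
  expect_equal(ew$k, 4) # planted 4-cluster structure
  expect_equal(length(ew$proxies), 4)
  expect_gt(ew$r2_denovo, 0.3)
  expect_lt(ew$r2_total, 1)
  expect_equal(nrow(tidy(ew)), 48)

  # zero planted de novo effects -> about nothing added beyond the core
  D0 <- matrix(rnorm(30 * n_fam, 0, 5), 30,
    dimnames = list(paste0("z", 1:30), fams)
  )
  mph0 <- setNames(as.vector(core %*% c(5, 4, 3) + rnorm(n_fam, 0, 3)), fams)
  ew0 <- conditional_ewas(core, D0, mph0)
  expect_lt(ew0$r2_denovo, 0.1)
  # null LRT p-values are roughly uniform
  expect_gt(mean(ew0$table$p > 0.5, na.rm = TRUE), 0.25)

  # a region equal to the core-model residual saturates the nested model
  res <- residuals(lm(mph ~ core))
  Dr <- matrix(res, 1, dimnames = list("sat", fams))
  ewr <- conditional_ewas(core, Dr, mph)
  expect_equal(ewr$r2_total, 1, tolerance = 1e-6)
})

test_that("marker LD is the squared genotype correlation", {
  g <- rbinom(100, 1, 0.3)
  expect_equal(marker_ld(g, g), 1)
  expect_equal(
    marker_ld(ifelse(g == 1, "UU", "MM"), g), 1
  )
  set.seed(52)
  a <- rbinom(5000, 1, 0.5)
  b <- rbinom(5000, 1, 0.5)
  expect_lt(marker_ld(a, b), 0.01)
  expect_error(marker_ld(rep(1, 10), rbinom(10, 1, .5)), "Monomorphic")
  # pedigree oracle: LD decays with map distance along a chromosome
  spec <- list(
    chromosomes = tibble::tibble(chrom = "c", length_cM = 60, length_bp = 6e6),
    spacing_cM = 10
  )
  ped <- simulate_epiril_pedigree(simulate_marker_map(spec), 5000, seed = 53)
  r2_near <- marker_ld(ped$geno[, 1], ped$geno[, 2]) # 10 cM
  r2_far <- marker_ld(ped$geno[, 1], ped$geno[, 7]) # 60 cM
  expect_gt(r2_near, 0.4)
  expect_gt(r2_near, r2_far + 0.2)
})
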