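test_that("marker map skeleton follows the spacing grid and sort order", {
  map <- simulate_marker_map()
  expect_equal(nrow(map$markers), 144)
  expect_equal(dplyr::n_distinct(map$markers$chrom), 5)
  # sorted by chromosome then cM, bp monotone with cM
  by_chr <- split(map$markers, map$markers$chrom)
  for (mk in by_chr) {
    expect_true(all(diff(mk$cM) > 0))
    expect_true(all(diff(mk$bp) > 0))
  }
  # spacing 5 cM over 100 cM -> 21 markers
  one <- simulate_marker_map(list(
    chromosomes = tibble::tibble(chrom = "chrA", length_cM = 100, length_bp = 1e7),
    spacing_cM = 5
  ))
  expect_equal(nrow(one$markers), 21)
  # degenerate 0-cM chromosome -> a single marker
  degen <- simulate_marker_map(list(
    chromosomes = tibble::tibble(chrom = "chrA", length_cM = 0, length_bp = 1e6),
    spacing_cM = 5
  ))
  expect_equal(nrow(degen$markers), 1)
  expect_error(
    simulate_marker_map(list(
      chromosomes = tibble::tibble(chrom = "chrA", length_cM = 10, length_bp = 1e6),
      spacing_cM = 0
    )),
    "spacing"
  )
})

test_that("pedigree UU frequency converges to 25% and heterozygotes resolve", {
  one_locus <- simulate_marker_map(list(
    chromosomes = tibble::tibble(chrom = "chr1", length_cM = 0, length_bp = 1e6),
    spacing_cM = 5
  ))
  ped <- simulate_epiril_pedigree(one_locus, 50000, seed = 101)
  freq <- mean(ped$geno)
  # 0.25 +/- 3 binomial SEs at n = 50,000
  se <- sqrt(0.25 * 0.75 / 50000)
  expect_lt(abs(freq - 0.25), 3 * se)
  expect_true(all(ped$geno %in% c(0L, 1L))) # fully homozygous output
  expect_error(simulate_epiril_pedigree(one_locus, 0), "at least 1")
})

test_that("zero recombination distance gives identical genotype columns", {
  spec <- list(
    chromosomes = tibble::tibble(chrom = "chr1", length_cM = 0, length_bp = 1e6),
    spacing_cM = 5
  )
  map <- simulate_marker_map(spec)
  # duplicate the marker at the same cM position
  map$markers <- dplyr::bind_rows(map$markers, map$markers)
  map$markers$marker_id <- c("a", "b")
  ped <- simulate_epiril_pedigree(map, 500, seed = 5)
  expect_identical(unname(ped$geno[, "a"]), unname(ped$geno[, "b"]))
})

test_that("residual heterozygote fraction entering resolution matches Mendelian halving", {
  # Expected het fraction after BC1 + 6 SSD = 0.5 * (1/2)^6 = 1/128.
  # Oracle: direct single-locus Markov simulation without the map machinery.
  set.seed(77)
  n <- 2e5
  # BC1: F1 gamete (M or U equally) + wt M allele -> het with prob 1/2
  het <- rbinom(n, 1, 0.5) == 1
  for (g in 1:6) {
    # selfing a het: offspring het with prob 1/2
    stay <- rbinom(n, 1, 0.5) == 1
    het <- het & stay
  }
  expect_lt(abs(mean(het) - 1 / 128), 4 * sqrt((1 / 128) / n))
})

test_that("marker-marker genotype association decays with map distance", {
  spec <- list(
    chromosomes = tibble::tibble(chrom = "chr1", length_cM = 80, length_bp = 8e6),
    spacing_cM = 10
  )
  ped <- simulate_epiril_pedigree(simulate_marker_map(spec), 4000, seed = 31)
  g <- ped$geno
  # observed recombination fraction between adjacent and distant markers
  rf <- function(a, b) mean(g[, a] != g[, b])
  r_adj <- rf(1, 2) # 10 cM apart
  r_far <- rf(1, 8) # 70 cM apart
  expect_lt(r_adj, r_far)
  # pedigree accumulates recombination across meioses: the population-scale
  # fraction lies between the single-meiosis Haldane value and the
  # selfing-RIL limit 2r / (1 + 2r)
  r1 <- haldane(10)
  expect_gt(r_adj, r1 * 0.9)
  expect_lt(r_adj, 2 * r1 / (1 + 2 * r1) + 0.03)
})

test_that("same seed reproduces the pedigree bit-identically", {
  map <- simulate_marker_map(tiny_map_spec())
  a <- simulate_epiril_pedigree(map, 40, seed = 9)
  b <- simulate_epiril_pedigree(map, 40, seed = 9)
  expect_identical(a$geno, b$geno)
})

test_that("trio simulator plants remodeling only where configured", {
  px <- planted_trios(n_lines = 60, penetrance = 0, seed = 41)
  sc <- classify_trios(px$trios)
  # penetrance 0 -> fully additive hybrids
  expect_true(all(sc$HD == 0))
  expect_true(all(sc$scenario == "ADD"))

  py <- planted_trios(n_lines = 60, penetrance = 1, seed = 42)
  sc <- classify_trios(py$trios)
  uu_fams <- rownames(py$map$geno)[py$map$geno[, py$qtl$marker_id[1]] == 1L]
  tgt <- sc[sc$region_id %in% py$qtl$target_region_id, ]
  # TCM in exactly the UU-parent families
  expect_true(all(tgt$scenario[tgt$family_id %in% uu_fams] == "TCM_SMR"))
  expect_true(all(tgt$scenario[!tgt$family_id %in% uu_fams] == "ADD"))

  expect_error(
    simulate_trio_methylomes(py$map, py$rs, plant_qtl("nope", "reg_0001")),
    "Unknown marker"
  )
})

test_that("planted penetrance is recovered within its binomial 99% interval", {
  pz <- planted_trios(n_lines = 169, penetrance = 0.6, seed = 43)
  sc <- classify_trios(pz$trios)
  uu_fams <- rownames(pz$map$geno)[pz$map$geno[, pz$qtl$marker_id[1]] == 1L]
  tgt <- sc[sc$region_id %in% pz$qtl$target_region_id &
    sc$family_id %in% uu_fams, ]
  obs <- mean(tgt$scenario != "ADD")
  n <- nrow(tgt)
  hw <- 2.58 * sqrt(0.6 * 0.4 / n)
  expect_lt(abs(obs - 0.6), hw)
})

test_that("phenotype simulator produces the configured MPH structure", {
  map <- tiny_panel(40, seed = 5)
  # all effects zero, zero variance -> every plant at the grand mean
  ph0 <- simulate_phenotypes(map,
    n_sibs = 3,
    variance = list(family = 0, residual = 0),
    covariate_design = list(), grand_mean = 100, seed = 1
  )
  expect_true(all(ph0$value == 100))
  mph0 <- suppressMessages(compute_mph(ph0, min_plants = 3))
  expect_true(all(mph0$mph == 0))
  expect_error(simulate_phenotypes(map, n_sibs = 0), "n_sibs")

  # +10% MPH on MM families shows up as the MM-UU group contrast
  big <- tiny_panel(400, seed = 6)
  ph <- simulate_phenotypes(big,
    pheno_qtl = plant_pheno_qtl(big$markers$marker_id[1], 10),
    n_sibs = 8, variance = list(family = 0, residual = 10),
    covariate_design = list(), seed = 2
  )
  mph <- suppressMessages(compute_mph(ph, min_plants = 5))
  mm <- big$geno[mph$family_id, 1] == 0L
  expect_lt(abs((mean(mph$mph[mm]) - mean(mph$mph[!mm])) - 10), 1)
})

test_that("variance split in simulated phenotypes is recoverable", {
  big <- tiny_panel(500, seed = 7)
  ph <- simulate_phenotypes(big,
    n_sibs = 8,
    variance = list(family = 30, residual = 70),
    covariate_design = list(), seed = 3
  )
  mph <- suppressMessages(compute_mph(ph, min_plants = 5))
  vc <- variance_components(mph_replicates(ph, mph))
  expect_lt(abs(vc$fraction - 0.30), 0.05)
})

test_that("count coupling scales negative-binomial means with methylation state", {
  px <- planted_trios(n_lines = 30, seed = 51)
  # flat multipliers: no U-vs-M mean difference
  flat <- simulate_counts(px$trios,
    coupling = list(
      base_mean = 30, multipliers = c(`0` = 1, `0.5` = 1, `1` = 1),
      dispersion = 0.05
    ), seed = 1
  )
  st <- px$trios$mscol
  expect_lt(
    abs(mean(flat$counts[st == 1, "msCol"]) - mean(flat$counts[st == 0, "msCol"])),
    3
  )
  # 4x multiplier recovered as an empirical mean ratio near 4
  big_rs <- build_region_spec(tiny_panel(4, seed = 52),
    n_background = 5000,
    seed = 53
  )
  tr <- simulate_trio_methylomes(tiny_panel(4, seed = 52), big_rs, seed = 54)
  cnt <- simulate_counts(tr,
    coupling = list(
      base_mean = 20, multipliers = c(`0` = 1, `0.5` = 2, `1` = 4),
      dispersion = 0.1
    ), seed = 2
  )
  st <- tr$mscol
  ratio <- mean(cnt$counts[st == 1, "msCol"]) / mean(cnt$counts[st == 0, "msCol"])
  expect_lt(abs(ratio - 4), 0.3)
  # zero mean -> all-zero counts
  z <- simulate_counts(px$trios,
    coupling = list(
      base_mean = 0, multipliers = c(`0` = 1, `0.5` = 2, `1` = 4),
      dispersion = 0.1
    ), seed = 3
  )
  expect_true(all(z$counts == 0))
  expect_error(
    simulate_counts(px$trios, coupling = list(
      base_mean = 10, multipliers = c(`0` = 1, `0.5` = 2, `1` = 4),
      dispersion = 0
    )),
    "Dispersion"
  )
})
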