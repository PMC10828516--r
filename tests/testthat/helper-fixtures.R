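# Small in-code fixtures shared across test files.

tiny_map_spec <- function(spacing_cM = 10) {
  list(
    chromosomes = tibble::tibble(
      chrom = c("chr1", "chr2"),
      length_cM = c(60, 40),
      length_bp = c(6e6, 4e6)
    ),
    spacing_cM = spacing_cM
  )
}

# a populated small panel: 80 lines on the tiny map
tiny_panel <- function(n_lines = 80, seed = 11) {
  simulate_epiril_pedigree(simulate_marker_map(tiny_map_spec()), n_lines, seed = seed)
}

# panel + trios with one planted distal TCM QTL at full penetrance
planted_trios <- function(n_lines = 60, penetrance = 1, seed = 21,
                          effect_sign = 1, n_background = 12) {
  map <- tiny_panel(n_lines, seed = seed)
  rs <- build_region_spec(map, n_background = n_background, seed = seed + 1)
  bg <- rs$regions$region_id[rs$regions$role == "background"]
  pq <- plant_qtl(map$markers$marker_id[2], bg[1:2],
    effect_sign = effect_sign, penetrance = penetrance
  )
  trios <- simulate_trio_methylomes(map, rs, pq, seed = seed + 2)
  list(map = map, rs = rs, trios = trios, qtl = pq)
}

# all 12 valid (msCol, epiRIL, hybrid) state combinations
trio_state_grid <- function() {
  tidyr::expand_grid(
    mscol = c(0, 1), epiril = c(0, 1), hybrid = c(0, 0.5, 1)
  )
}
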