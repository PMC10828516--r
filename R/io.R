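#' @name epihybrid_io
#' @title Readers and writers for pipeline tables
#'
#' @description Plain-text interchange formats used by the pipeline:
#' marker map CSV (marker metadata plus one MM/UU column per line), state
#' matrix TSV (region metadata plus one state column per sample), plant
#' phenotype TSV, count TSV, regions BED (0-based half-open) and a flat
#' `key = value` configuration format. Writers record the generating seed
#' in a `#` header comment when one is supplied; readers skip `#` lines.
NULL

write_with_header <- function(x, path, seed = NULL, delim = "\t") {
  if (!is.null(seed)) {
    writeLines(sprintf("# seed: %d", as.integer(seed)), path)
    readr::write_delim(x, path, delim = delim, append = TRUE, col_names = TRUE)
  } else {
    readr::write_delim(x, path, delim = delim)
  }
  invisible(path)
}

#' @rdname epihybrid_io
#' @param map An `epimap`.
#' @param path File path.
#' @param seed Seed to record in the header comment.
#' @export
write_marker_map <- function(map, path, seed = NULL) {
  tab <- map$markers
  if (!is.null(map$geno)) {
    calls <- tibble::as_tibble(t(ifelse(map$geno == 1L, "UU", "MM")))
    names(calls) <- rownames(map$geno)
    tab <- dplyr::bind_cols(tab, calls)
  }
  write_with_header(tab, path, seed, delim = ",")
}

#' @rdname epihybrid_io
#' @export
read_marker_map <- function(path) {
  tab <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  need <- c("marker_id", "chrom", "cM", "bp")
  check_schema_(tab, need, path)
  line_cols <- setdiff(names(tab), need)
  geno <- NULL
  if (length(line_cols)) {
    vals <- as.matrix(tab[, line_cols])
    bad <- !vals %in% c("MM", "UU")
    if (any(bad)) abort("Epigenotype calls must be MM or UU.")
    geno <- t(vals == "UU") + 0L
    dimnames(geno) <- list(line_cols, tab$marker_id)
  }
  new_epimap(tab[, need], geno)
}

#' @rdname epihybrid_io
#' @param trios A `trio_states` object.
#' @export
write_state_matrix <- function(trios, path, seed = NULL) {
  tab <- dplyr::bind_cols(
    trios$regions[, c("region_id", "chrom", "start", "end", "context")],
    tibble::tibble(msCol = unname(trios$mscol)),
    tibble::as_tibble(trios$epiril, .name_repair = ~ paste0(.x, "_epiRIL")),
    tibble::as_tibble(trios$hybrid, .name_repair = ~ paste0(.x, "_F1"))
  )
  write_with_header(tab, path, seed)
}

#' @rdname epihybrid_io
#' @export
read_state_matrix <- function(path) {
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  need <- c("region_id", "chrom", "start", "end", "context", "msCol")
  check_schema_(tab, need, path)
  if (anyDuplicated(tab$region_id)) abort("Duplicate region_id values.")
  epi_cols <- grep("_epiRIL$", names(tab), value = TRUE)
  f1_cols <- grep("_F1$", names(tab), value = TRUE)
  fams <- sub("_epiRIL$", "", epi_cols)
  epiril <- as.matrix(tab[, epi_cols])
  hybrid <- as.matrix(tab[, f1_cols])
  dimnames(epiril) <- dimnames(hybrid) <- list(tab$region_id, fams)
  structure(
    list(
      regions = tab[, c("region_id", "chrom", "start", "end", "context")],
      peri = NULL,
      mscol = setNames(tab$msCol, tab$region_id),
      epiril = epiril, hybrid = hybrid, families = fams, planted_qtl = NULL
    ),
    class = "trio_states"
  )
}

#' @rdname epihybrid_io
#' @param tbl A tibble to write/validate.
#' @export
write_phenotypes <- function(tbl, path, seed = NULL) {
  write_with_header(tbl, path, seed)
}

#' @rdname epihybrid_io
#' @export
read_phenotypes <- function(path) {
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  check_schema_(tab, c("plant_id", "family_id", "group", "value"), path)
  bad <- setdiff(unique(tab$group), c("msCol", "epiRIL", "F1"))
  if (length(bad)) abort(paste0("Unknown group label(s): ", paste(bad, collapse = ", ")))
  tab
}

#' @rdname epihybrid_io
#' @param counts Matrix with feature row names.
#' @export
write_counts <- function(counts, path, seed = NULL) {
  write_with_header(
    tibble::as_tibble(counts, rownames = "feature_id"), path, seed
  )
}

#' @rdname epihybrid_io
#' @export
read_counts <- function(path) {
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  check_schema_(tab, "feature_id", path)
  m <- as.matrix(tab[, -1])
  rownames(m) <- tab$feature_id
  m
}

#' @rdname epihybrid_io
#' @param regions Tibble with `chrom`, `start`, `end` (and optionally
#'   `region_id`).
#' @export
write_regions_bed <- function(regions, path, seed = NULL) {
  bed <- tibble::tibble(
    chrom = regions$chrom, start = regions$start, end = regions$end,
    name = regions[["region_id"]] %||% "."
  )
  if (!is.null(seed)) {
    writeLines(sprintf("# seed: %d", as.integer(seed)), path)
    readr::write_tsv(bed, path, col_names = FALSE, append = TRUE)
  } else {
    readr::write_tsv(bed, path, col_names = FALSE)
  }
  invisible(path)
}

#' @rdname epihybrid_io
#' @export
read_bed <- function(path) {
  tab <- readr::read_tsv(path,
    comment = "#", col_names = FALSE,
    show_col_types = FALSE
  )
  if (ncol(tab) < 3) abort("A BED file needs at least 3 columns.")
  names(tab)[1:3] <- c("chrom", "start", "end")
  if (ncol(tab) >= 4) names(tab)[4] <- "region_id"
  if (any(tab$start >= tab$end)) {
    abort("BED intervals must satisfy start < end (0-based half-open).")
  }
  tab
}

check_schema_ <- function(tab, need, path) {
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    abort(sprintf(
      "%s: missing required column(s): %s", path, paste(miss, collapse = ", ")
    ))
  }
  invisible(tab)
}

#' Default pipeline configuration
#'
#' Every analysis threshold is a named key defaulting to its standard
#' value: 200-bp regions on a 50-bp step, the >= 10-cytosine bin filter
#' recorded upstream, sharing filters of >= 2 families (shared label),
#' >= 10 families (correlations) and >= 50% of families (QTL traits), a
#' 2-cM scan step, 1,000 permutations at a 5% genome-wide error rate,
#' 2-LOD (methylation) and 1-LOD (phenotype comparison) confidence drops,
#' p < 0.05 and FDR < 0.05 cutoffs, 1-kb gene linking, and the
#' CPM >= 1 in >= 2 samples count filter.
#'
#' @param n_lines,n_sibs Simulated panel size.
#' @param n_perm Permutations per trait (lowered in the demo
#'   configuration).
#' @return Nested list of configuration sections.
#' @export
default_config <- function(n_lines = 169, n_sibs = 6, n_perm = 1000) {
  list(
    simulate = list(
      n_lines = n_lines, n_sibs = n_sibs, n_background = 40,
      region_size = 200, step_bp = 50, min_cytosines = 10,
      noise = 0, variance_family = 30, variance_residual = 70
    ),
    classify = list(t_low = 0.2, t_high = 0.8, divergence_mode = "ratio"),
    correlate = list(min_families = 10, alpha = 0.05, min_shared = 2),
    mapqtl = list(
      step_cM = 2, n_perm = n_perm, alpha = 0.05, drop = 2,
      lod_cap = 50, fdr = 0.05, share_min_frac = 0.5
    ),
    heterosis = list(
      min_plants = 5, sd_cut = 3, anova_alpha = 0.05,
      pheno_drop = 1
    ),
    omics = list(min_cpm = 1, min_samples = 2, max_gene_distance = 1000),
    causal = list(n_boot = 1000),
    stages = c(
      "simulate", "classify", "correlate", "mapqtl",
      "heterosis", "omics", "causal"
    )
  )
}

#' Small demonstration configuration
#'
#' A scaled-down panel that exercises every stage quickly: fewer lines,
#' fewer permutations, smaller bootstrap counts.
#'
#' @return Configuration list as in [default_config()].
#' @export
demo_config <- function() {
  cfg <- default_config(n_lines = 60, n_sibs = 6, n_perm = 200)
  cfg$causal$n_boot <- 200
  # planted fully penetrant effects fire in the UU families only (~25% of
  # the panel), so the demo lowers the trait sharing filter below that
  cfg$mapqtl$share_min_frac <- 0.15
  cfg
}

#' @rdname epihybrid_io
#' @param config Nested configuration list.
#' @export
write_config <- function(config, path) {
  flat <- unlist(config)
  writeLines(paste(names(flat), unname(flat), sep = " = "), path)
  invisible(path)
}

#' @rdname epihybrid_io
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, " = ", fixed = TRUE)
  flat <- setNames(
    vapply(kv, `[`, character(1), 2),
    vapply(kv, `[`, character(1), 1)
  )
  out <- list()
  for (key in names(flat)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    val <- utils::type.convert(flat[[key]], as.is = TRUE)
    if (length(parts) == 1) {
      out[[parts]] <- c(out[[parts]], val)
    } else {
      sec <- sub("[0-9]+$", "", parts[2])
      if (length(parts) == 2 && grepl("[0-9]$", parts[2]) && sec != parts[2]) {
        out[[parts[1]]][[sec]] <- c(out[[parts[1]]][[sec]], val)
      } else {
        out[[parts[1]]][[parts[2]]] <- val
      }
    }
  }
  out
}

#' Run the full synthetic-data pipeline
#'
#' Executes the stages simulate, classify, correlate, mapqtl, heterosis,
#' omics and causal in order on a simulated panel, writing each stage's
#' tables under `outdir` and returning a run manifest (configuration
#' snapshot, seed, output checksums, stage timings, package version).
#' Re-running with the same configuration and seed reproduces
#' byte-identical outputs. Stages may be skipped via `config$stages`; a
#' stage that needs a missing earlier product fails with a clear error.
#'
#' @param config Configuration list (see [default_config()],
#'   [demo_config()]).
#' @param outdir Output directory (created if needed).
#' @param seed Root seed; all stage seeds derive from it by name.
#' @return The manifest, invisibly (also written to
#'   `manifest.txt` in `outdir`).
#' @export
run_pipeline <- function(config = demo_config(), outdir = tempfile("epihybrid_run_"),
                         seed = 1) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages
  timings <- c()
  outputs <- character()
  state <- new.env(parent = emptyenv())
  run_stage <- function(name, fn) {
    if (!name %in% stages) {
      return(invisible(NULL))
    }
    t0 <- proc.time()[["elapsed"]]
    tryCatch(fn(), error = function(e) {
      abort(sprintf("Stage '%s' failed: %s", name, conditionMessage(e)))
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 2)
  }
  need <- function(what, stage) {
    if (!exists(what, envir = state)) {
      abort(sprintf(
        "Stage '%s' needs '%s' from an earlier stage that was skipped.",
        stage, what
      ))
    }
    get(what, envir = state)
  }
  run_stage("simulate", function() {
    sim <- config$simulate
    map <- simulate_marker_map()
    map <- simulate_epiril_pedigree(map, sim$n_lines, seed = derive_seed(seed, "pedigree"))
    rs <- build_region_spec(map,
      n_background = sim$n_background,
      region_size = sim$region_size, step_bp = sim$step_bp,
      seed = derive_seed(seed, "regions")
    )
    # one distal methylation QTL and one phenotypic QTL by default
    tcm_targets <- rs$regions$region_id[rs$regions$role == "background"][1:3]
    pq <- plant_qtl(map$markers$marker_id[3], tcm_targets,
      effect_sign = 1, penetrance = 1
    )
    trios <- simulate_trio_methylomes(map, rs,
      planted_qtl = pq,
      noise = sim$noise, seed = derive_seed(seed, "trios")
    )
    pheno <- simulate_phenotypes(map,
      pheno_qtl = plant_pheno_qtl(map$markers$marker_id[10], 10),
      n_sibs = sim$n_sibs,
      variance = list(family = sim$variance_family, residual = sim$variance_residual),
      seed = derive_seed(seed, "phenotypes")
    )
    cnt <- simulate_counts(trios, seed = derive_seed(seed, "counts"))
    assign("map", map, state)
    assign("trios", trios, state)
    assign("pheno", pheno, state)
    assign("counts", cnt, state)
    outputs <<- c(
      outputs,
      write_marker_map(map, file.path(outdir, "marker_map.csv"), seed),
      write_state_matrix(trios, file.path(outdir, "state_matrix.tsv"), seed),
      write_phenotypes(pheno, file.path(outdir, "phenotypes.tsv"), seed),
      write_counts(cnt$counts, file.path(outdir, "srna_counts.tsv"), seed),
      write_regions_bed(trios$regions, file.path(outdir, "regions.bed")),
      write_regions_bed(trios$peri, file.path(outdir, "pericentromeres.bed"))
    )
  })
  run_stage("classify", function() {
    trios <- need("trios", "classify")
    scen <- classify_trios(trios, divergence_mode = config$classify$divergence_mode)
    assign("scenarios", scen, state)
    outputs <<- c(outputs, write_with_header(
      scen, file.path(outdir, "trio_scenarios.tsv")
    ))
  })
  run_stage("correlate", function() {
    scen <- need("scenarios", "correlate")
    trios <- need("trios", "correlate")
    div <- scenario_divergence_matrix(scen)
    nad <- scenario_nad_matrix(scen)
    cors <- tryCatch(
      pairwise_nad_correlations(div,
        nad = nad,
        min_families = config$correlate$min_families,
        alpha = config$correlate$alpha
      ),
      error = function(e) {
        tibble::tibble(
          region_a = character(), region_b = character(), n = integer(),
          pearson_r = double(), p_value = double(), sign = character(),
          majority_flag = logical()
        )
      }
    )
    if (nrow(cors)) {
      cors <- compartment_categorize(cors, trios$regions, trios$peri)
    }
    assign("correlations", cors, state)
    outputs <<- c(outputs, write_with_header(
      cors, file.path(outdir, "nad_correlations.tsv")
    ))
  })
  run_stage("mapqtl", function() {
    scen <- need("scenarios", "mapqtl")
    trios <- need("trios", "mapqtl")
    map <- need("map", "mapqtl")
    mq <- config$mapqtl
    qtl <- run_nad_qtl(
      map,
      scenario_divergence_matrix(scen), trios$regions,
      scenarios = scen, nad = scenario_nad_matrix(scen),
      share_min_frac = mq$share_min_frac, step_cM = mq$step_cM,
      n_perm = mq$n_perm, alpha = mq$alpha, drop = mq$drop,
      lod_cap = mq$lod_cap, fdr = mq$fdr,
      seed = derive_seed(seed, "mapqtl")
    )
    assign("nad_qtl", qtl, state)
    outputs <<- c(outputs, write_with_header(
      tidy(qtl), file.path(outdir, "nad_qtl.tsv")
    ))
  })
  run_stage("heterosis", function() {
    pheno <- need("pheno", "heterosis")
    map <- need("map", "heterosis")
    het <- config$heterosis
    adj <- adjust_environment(pheno, sd_cut = het$sd_cut)
    mph <- compute_mph(adj, min_plants = min(het$min_plants, config$simulate$n_sibs))
    pq <- pheno_qtl_scan(map, mph,
      step_cM = config$mapqtl$step_cM,
      n_perm = config$mapqtl$n_perm, alpha = config$mapqtl$alpha,
      drop = config$mapqtl$drop, anova_alpha = het$anova_alpha,
      seed = derive_seed(seed, "phenoqtl")
    )
    assign("mph", mph, state)
    assign("pheno_qtl", pq, state)
    outputs <<- c(
      outputs,
      write_with_header(mph, file.path(outdir, "heterosis.tsv")),
      write_with_header(pq$peaks, file.path(outdir, "pheno_qtl.tsv"))
    )
  })
  run_stage("omics", function() {
    cnt <- need("counts", "omics")
    trios <- need("trios", "omics")
    norm <- filter_and_normalize_counts(cnt$counts,
      min_cpm = config$omics$min_cpm,
      min_samples = config$omics$min_samples
    )
    design <- tibble::tibble(
      family_id = trios$families,
      mscol = "msCol",
      epiril = paste0(trios$families, "_epiRIL"),
      hybrid = paste0(trios$families, "_F1")
    )
    div <- omics_divergence(norm, design)
    assign("omics_div", div, state)
    outputs <<- c(outputs, write_with_header(
      div, file.path(outdir, "srna_divergence.tsv")
    ))
  })
  run_stage("causal", function() {
    trios <- need("trios", "causal")
    map <- need("map", "causal")
    div <- need("omics_div", "causal")
    scen <- need("scenarios", "causal")
    # one worked causal fit on the first planted target
    tgt <- trios$planted_qtl
    if (is.null(tgt)) {
      assign("causal", NULL, state)
      return(invisible(NULL))
    }
    reg <- tgt$target_region_id[1]
    mk <- tgt$marker_id[1]
    qv <- map$geno[, mk]
    mdiv <- scen$pct_mpdiv[scen$region_id == reg]
    names(mdiv) <- scen$family_id[scen$region_id == reg]
    srna <- div[div$feature_id == paste0("sRNA_", reg), ]
    ev <- setNames(srna$pct_mpdiv, srna$family_id)
    fams <- intersect(names(mdiv), names(ev))
    # deterministic jitter keeps within-class variance positive when the
    # planted effect is fully penetrant
    jit <- seq_along(fams) * 1e-6
    fit <- tryCatch(
      bootstrap_select(qv[fams], mdiv[fams] + jit,
        ev[fams],
        n_boot = config$causal$n_boot,
        seed = derive_seed(seed, "causal")
      ),
      error = function(e) NULL
    )
    assign("causal", fit, state)
    if (!is.null(fit)) {
      outputs <<- c(outputs, write_with_header(
        tidy(fit), file.path(outdir, "causal_fit.tsv")
      ))
    }
  })
  manifest <- list(
    version = as.character(utils::packageVersion("epihybridr")),
    seed = seed,
    stages = stages,
    timings = timings,
    outputs = tibble::tibble(
      path = basename(outputs),
      md5 = unname(tools::md5sum(outputs))
    ),
    config = config
  )
  man_path <- file.path(outdir, "manifest.txt")
  writeLines(c(
    sprintf("version = %s", manifest$version),
    sprintf("seed = %d", seed),
    sprintf("stage.%s.seconds = %s", names(timings), unlist(timings)),
    sprintf("output.%s.md5 = %s", manifest$outputs$path, manifest$outputs$md5)
  ), man_path)
  write_config(config, file.path(outdir, "config.txt"))
  invisible(manifest)
}

#' Reshape a long scenario table into a divergence matrix
#'
#' @param scenario_table Output of [classify_trios()].
#' @return Matrix regions x families of `%` mid-parent divergence
#'   (0 where the region is additive in that family).
#' @export
scenario_divergence_matrix <- function(scenario_table) {
  wide <- tidyr::pivot_wider(
    scenario_table[, c("region_id", "family_id", "pct_mpdiv", "scenario")],
    id_cols = "region_id", names_from = "family_id",
    values_from = "pct_mpdiv"
  )
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$region_id
  m
}

#' @rdname scenario_divergence_matrix
#' @return For `scenario_nad_matrix`: binary matrix marking non-additive
#'   region x family records.
#' @export
scenario_nad_matrix <- function(scenario_table) {
  wide <- tidyr::pivot_wider(
    scenario_table[, c("region_id", "family_id", "scenario")],
    id_cols = "region_id", names_from = "family_id",
    values_from = "scenario"
  )
  m <- (as.matrix(wide[, -1]) != "ADD") + 0
  rownames(m) <- wide$region_id
  m
}
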