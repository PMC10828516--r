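#' Pairwise correlations of mid-parent divergence between remodeled regions
#'
#' Computes Pearson correlations, over families, of the mid-parent
#' methylation divergence between every pair of regions that share a
#' remodeling scenario in at least `min_families` families. Two-sided
#' p-values come from the t distribution; pairs with fewer than three
#' complete observations are skipped. Each record carries a flag for the
#' stricter inclusion rule that both regions be remodeled in at least half
#' of the families.
#'
#' @param divergence Numeric matrix, regions x families, of `%` mid-parent
#'   divergence (NA where not remodeled or missing).
#' @param nad Optional binary indicator matrix (same shape) marking where a
#'   region is remodeled; defaults to `!is.na(divergence)`.
#' @param min_families Minimum families sharing a remodeling event for a
#'   region to enter the analysis (>= 2).
#' @param alpha Keep pairs with `p < alpha`; `alpha = 1` keeps all.
#' @param adjust `"none"` (raw p-values, the default) or `"BY"` for a
#'   Benjamini-Yekutieli adjusted column used for filtering instead.
#' @return Tibble with `region_a`, `region_b`, `n`, `pearson_r`, `p_value`,
#'   `sign`, `majority_flag` (both regions remodeled in >= 50% of
#'   families). Skipped pairs are reported in the `"skipped"` attribute.
#' @export
pairwise_nad_correlations <- function(divergence, nad = NULL,
                                      min_families = 10, alpha = 0.05,
                                      adjust = c("none", "BY")) {
  adjust <- match.arg(adjust)
  if (min_families < 2) abort("`min_families` must be at least 2.")
  if (is.null(nad)) nad <- !is.na(divergence) + 0
  keep <- rowSums(nad == 1) >= min_families
  if (sum(keep) < 2) {
    abort("Fewer than two regions pass the sharing filter.")
  }
  d <- divergence[keep, , drop = FALSE]
  majority <- rowMeans(nad[keep, , drop = FALSE] == 1) >= 0.5
  ids <- rownames(d) %||% as.character(seq_len(nrow(d)))
  n_fam <- ncol(d)
  # pairwise-complete Pearson r and counts via matrix algebra
  r <- suppressWarnings(cor(t(d), use = "pairwise.complete.obs"))
  obs <- !is.na(d) + 0
  n_pair <- obs %*% t(obs)
  pairs <- which(upper.tri(r), arr.ind = TRUE)
  n <- n_pair[pairs]
  rv <- r[pairs]
  skipped <- n < 3 | is.na(rv)
  tstat <- rv * sqrt((n - 2) / pmax(1 - rv^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = pmax(n - 2, 1))
  p[rv^2 >= 1] <- 0
  out <- tibble::tibble(
    region_a = ids[pairs[, 1]],
    region_b = ids[pairs[, 2]],
    n = as.integer(n),
    pearson_r = rv,
    p_value = p,
    sign = ifelse(rv > 0, "positive", "negative"),
    majority_flag = majority[pairs[, 1]] & majority[pairs[, 2]]
  )
  skip_tbl <- out[skipped, c("region_a", "region_b", "n")]
  out <- out[!skipped, ]
  if (adjust == "BY") {
    out$p_adj <- p.adjust(out$p_value, method = "BY")
    out <- out[out$p_adj < alpha, ]
  } else {
    out <- out[out$p_value < alpha, ]
  }
  if (nrow(skip_tbl)) {
    inform(sprintf("%d pair(s) skipped (fewer than 3 paired observations).", nrow(skip_tbl)))
  }
  attr(out, "skipped") <- skip_tbl
  out
}

#' Assign regions to chromosome-arm or pericentromere compartments
#'
#' A region is pericentromeric when its midpoint falls inside a
#' pericentromere interval (0-based half-open, so a midpoint exactly at the
#' interval start is inside).
#'
#' @param regions Tibble with `region_id`, `chrom`, `start`, `end`.
#' @param peri Pericentromere intervals (`chrom`, `start`, `end`).
#' @return Input tibble with a `compartment` column (`"arm"` / `"peri"`).
#' @export
region_compartment <- function(regions, peri) {
  missing_chr <- setdiff(unique(regions$chrom), unique(peri$chrom))
  if (length(missing_chr)) {
    abort(paste0(
      "Chromosome(s) absent from the pericentromere BED: ",
      paste(missing_chr, collapse = ", ")
    ))
  }
  mid <- (regions$start + regions$end) %/% 2
  in_peri <- purrr::map_lgl(seq_len(nrow(regions)), function(i) {
    p <- peri[peri$chrom == regions$chrom[i], ]
    any(mid[i] >= p$start & mid[i] < p$end)
  })
  dplyr::mutate(regions, compartment = ifelse(in_peri, "peri", "arm"))
}

#' Categorize region pairs by compartment and chromosome
#'
#' @param pairs Tibble with `region_a`, `region_b` (e.g. from
#'   [pairwise_nad_correlations()]).
#' @param regions Region coordinates covering all ids in `pairs`.
#' @param peri Pericentromere intervals.
#' @return `pairs` with `category` (`arm-arm`, `arm-peri`, `peri-peri`,
#'   unordered) and `chromosomal` (`intra` / `inter`).
#' @export
compartment_categorize <- function(pairs, regions, peri) {
  comp <- region_compartment(regions, peri)
  ia <- match(pairs$region_a, comp$region_id)
  ib <- match(pairs$region_b, comp$region_id)
  if (anyNA(ia) || anyNA(ib)) abort("Some pair members are missing from `regions`.")
  ca <- comp$compartment[ia]
  cb <- comp$compartment[ib]
  category <- ifelse(ca == cb, paste(ca, cb, sep = "-"), "arm-peri")
  dplyr::mutate(
    pairs,
    category = category,
    chromosomal = ifelse(comp$chrom[ia] == comp$chrom[ib], "intra", "inter")
  )
}

#' Distances from SMR remodeling events to the nearest DMR event
#'
#' For one family's scenario table, computes the edge-to-edge distance (bp,
#' 0 if overlapping or adjacent) from each query region to the nearest
#' target region on the same chromosome, for the four query/target pairings
#' of interest: SMR-TCM and SMR-ADD versus DMR-TCM, and SMR-TCdM and
#' SMR-ADD versus DMR-TCdM. Queries on chromosomes without any target of
#' the required type get a missing distance.
#'
#' @param scenario_table One family's rows from [classify_trios()] (columns
#'   `region_id`, `chrom`, `start`, `end`, `scenario`).
#' @return Tibble with `group`, `region_id`, `chrom`, `distance`; per-group
#'   medians are attached as the `"medians"` attribute and returned by
#'   [proximity_medians()].
#' @export
proximity_to_dmr_events <- function(scenario_table) {
  smr <- function(s) scenario_table$scenario == s
  dmr_like <- function(tbl, lab) tbl[tbl$scenario == lab, ]
  is_smr_add <- scenario_table$scenario == "ADD" & scenario_table$PD == 0
  groups <- list(
    `SMR-TCM to DMR-TCM` = list(q = smr("TCM_SMR"), t = "TCM_DMR"),
    `SMR-ADD to DMR-TCM` = list(q = is_smr_add, t = "TCM_DMR"),
    `SMR-TCdM to DMR-TCdM` = list(q = smr("TCdM_SMR"), t = "TCdM_DMR"),
    `SMR-ADD to DMR-TCdM` = list(q = is_smr_add, t = "TCdM_DMR")
  )
  out <- purrr::imap_dfr(groups, function(g, name) {
    q <- scenario_table[g$q, ]
    t <- dmr_like(scenario_table, g$t)
    if (nrow(q) == 0) {
      return(tibble::tibble(
        group = character(), region_id = character(),
        chrom = character(), distance = numeric()
      ))
    }
    dist <- purrr::map_dbl(seq_len(nrow(q)), function(i) {
      tt <- t[t$chrom == q$chrom[i], ]
      if (nrow(tt) == 0) {
        return(NA_real_)
      }
      # edge-to-edge gap between half-open intervals, 0 when overlapping
      min(pmax(0, pmax(tt$start - q$end[i], q$start[i] - tt$end)))
    })
    tibble::tibble(
      group = name, region_id = q$region_id,
      chrom = q$chrom, distance = dist
    )
  })
  med <- dplyr::summarise(
    dplyr::group_by(out, .data$group),
    median_bp = median(.data$distance, na.rm = TRUE),
    n = dplyr::n(),
    .groups = "drop"
  )
  attr(out, "medians") <- med
  out
}

#' @rdname proximity_to_dmr_events
#' @param distances Output of [proximity_to_dmr_events()].
#' @export
proximity_medians <- function(distances) {
  attr(distances, "medians")
}
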