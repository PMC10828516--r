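#' Discretize region methylation levels into state calls
#'
#' A two-threshold stand-in for an HMM state caller: levels at or below
#' `t_low` are unmethylated (0), at or above `t_high` methylated (1).
#' Hybrids keep the middle band as the intermediate state (0.5); parents
#' are binary by definition, so a parental level in the middle band is
#' resolved to the nearer bound and flagged ambiguous.
#'
#' @param levels Numeric methylation levels in `[0, 1]`.
#' @param t_low,t_high Lower and upper thresholds, `t_low < t_high`.
#' @param is_parent Logical; parents are forced binary.
#' @return Tibble with `level`, `state` and `ambiguous`.
#' @examples
#' call_region_states(c(0, 0.5, 0.9), is_parent = FALSE)
#' @export
call_region_states <- function(levels, t_low = 0.2, t_high = 0.8,
                               is_parent = FALSE) {
  if (t_low >= t_high) abort("`t_low` must be smaller than `t_high`.")
  if (any(levels < 0 | levels > 1, na.rm = TRUE)) {
    abort("Methylation levels must lie in [0, 1].")
  }
  state <- ifelse(levels <= t_low, 0, ifelse(levels >= t_high, 1, 0.5))
  ambiguous <- rep(FALSE, length(levels))
  if (is_parent) {
    mid <- state == 0.5 & !is.na(state)
    # nearer-bound rule; exact midpoint resolves upward
    state[mid] <- as.numeric(levels[mid] >= (t_low + t_high) / 2)
    ambiguous[mid] <- TRUE
  }
  tibble::tibble(level = levels, state = state, ambiguous = ambiguous)
}

#' Classify a trio of region states into a remodeling scenario
#'
#' Computes, per region and family, the parental divergence
#' `PD = msCol - epiRIL`, the mid-parent value `MPV = (msCol + epiRIL)/2`
#' and the hybrid divergence `HD = hybrid - MPV`, and assigns exactly one of
#' five scenario labels: `ADD` (HD = 0), trans-chromosomal methylation
#' (`TCM_*`, HD > 0) or demethylation (`TCdM_*`, HD < 0), within a parental
#' DMR (`*_DMR`, PD != 0) or a similarly methylated region (`*_SMR`,
#' PD = 0).
#'
#' @param mscol,epiril Parental state calls in `{0, 1}` (vectors recycle to
#'   a common length).
#' @param hybrid Hybrid state calls in `{0, 0.5, 1}`.
#' @return Tibble with `PD`, `MPV`, `HD`, `scenario`.
#' @examples
#' classify_trio(0, 0, 1)   # TCM_SMR
#' classify_trio(1, 0, 0)   # TCdM_DMR
#' @export
classify_trio <- function(mscol, epiril, hybrid) {
  assert_state(mscol, "msCol parent")
  assert_state(epiril, "epiRIL parent")
  assert_state(hybrid, "hybrid", hybrid = TRUE)
  n <- max(length(mscol), length(epiril), length(hybrid))
  mscol <- rep_len(mscol, n)
  epiril <- rep_len(epiril, n)
  hybrid <- rep_len(hybrid, n)
  pd <- mscol - epiril
  mpv <- (mscol + epiril) / 2
  hd <- hybrid - mpv
  scenario <- ifelse(
    hd == 0, "ADD",
    paste0(ifelse(hd > 0, "TCM", "TCdM"), "_", ifelse(pd != 0, "DMR", "SMR"))
  )
  tibble::tibble(PD = pd, MPV = mpv, HD = hd, scenario = scenario)
}

#' Mid-parent divergence in percent
#'
#' `ratio` mode returns `(H - MPV) / MPV * 100`; `difference` mode returns
#' `(H - MPV) * 100`. In ratio mode, records with `MPV = 0` (where the ratio
#' is undefined) fall back to difference mode and are flagged.
#'
#' @param hybrid,mscol,epiril Finite numeric vectors (states or levels).
#' @param mode `"ratio"` or `"difference"`.
#' @return Tibble with `pct_mpdiv` and `fallback`.
#' @examples
#' midparent_divergence(15, 12, 8)          # +50
#' midparent_divergence(0.5, 0, 0)          # +50, flagged fallback
#' @export
midparent_divergence <- function(hybrid, mscol, epiril,
                                 mode = c("ratio", "difference")) {
  mode <- match.arg(mode)
  if (!all(is.finite(hybrid) & is.finite(mscol) & is.finite(epiril))) {
    abort("All values must be finite.")
  }
  mpv <- (mscol + epiril) / 2
  hd <- hybrid - mpv
  if (mode == "difference") {
    return(tibble::tibble(pct_mpdiv = hd * 100, fallback = FALSE))
  }
  fallback <- mpv == 0
  pct <- ifelse(fallback, hd * 100, hd / mpv * 100)
  tibble::tibble(pct_mpdiv = pct, fallback = fallback)
}

#' Classify every region of every trio
#'
#' Applies [classify_trio()] and [midparent_divergence()] across a
#' `trio_states` object, producing one row per region x family.
#'
#' @param trios A `trio_states` object from [simulate_trio_methylomes()] or
#'   assembled from read state matrices.
#' @param divergence_mode Passed to [midparent_divergence()].
#' @return Tibble (`region_id`, `family_id`, `chrom`, `start`, `end`,
#'   `context`, `mscol`, `epiril`, `hybrid`, `PD`, `MPV`, `HD`, `scenario`,
#'   `pct_mpdiv`, `fallback`).
#' @export
classify_trios <- function(trios, divergence_mode = "ratio") {
  stopifnot(inherits(trios, "trio_states"))
  n_fam <- length(trios$families)
  n_reg <- nrow(trios$regions)
  mscol <- rep(trios$mscol, n_fam)
  epiril <- as.vector(trios$epiril)
  hybrid <- as.vector(trios$hybrid)
  cls <- classify_trio(mscol, epiril, hybrid)
  div <- midparent_divergence(hybrid, mscol, epiril, mode = divergence_mode)
  meta <- trios$regions[rep(seq_len(n_reg), n_fam),
    c("region_id", "chrom", "start", "end", "context")
  ]
  dplyr::bind_cols(
    meta,
    tibble::tibble(
      family_id = rep(trios$families, each = n_reg),
      mscol = mscol, epiril = epiril, hybrid = hybrid
    ),
    cls, div
  )
}

#' Bootstrap test for DMR enrichment among remodeled regions
#'
#' Tests whether non-additive (NAD) regions contain more parental DMRs than
#' expected by chance: the observed DMR frequency within the NAD set is
#' compared with the frequencies in `n_boot` random draws of the same size
#' from the full region universe. The empirical p-value is
#' `(1 + #\{null >= observed\}) / (n_boot + 1)`.
#'
#' @param scenario_table Tibble with at least a `scenario` column (any
#'   output of [classify_trios()]); rows are region x family records.
#' @param n_boot Number of bootstrap draws (>= 1).
#' @param seed Optional seed.
#' @return An `enrichment_boot` object (list: `observed`, `null_freqs`,
#'   `p_value`, `n_nad`, `n_boot`); see [tidy.enrichment_boot()].
#' @export
enrichment_bootstrap <- function(scenario_table, n_boot = 1000, seed = NULL) {
  if (n_boot < 1) abort("`n_boot` must be at least 1.")
  if (nrow(scenario_table) == 0) abort("Empty region universe.")
  is_dmr <- if ("PD" %in% names(scenario_table)) {
    scenario_table$PD != 0
  } else {
    grepl("_DMR$", scenario_table$scenario)
  }
  is_nad <- scenario_table$scenario != "ADD"
  n_nad <- sum(is_nad)
  if (n_nad == 0) abort("The NAD set is empty; nothing to test.")
  observed <- mean(is_dmr[is_nad])
  with_seed_(seed, {
    null_freqs <- vapply(
      seq_len(n_boot),
      function(i) mean(is_dmr[sample.int(length(is_dmr), n_nad)]),
      numeric(1)
    )
    structure(
      list(
        observed = observed, null_freqs = null_freqs,
        p_value = (1 + sum(null_freqs >= observed)) / (n_boot + 1),
        n_nad = n_nad, n_boot = n_boot
      ),
      class = "enrichment_boot"
    )
  })
}

#' @export
print.enrichment_boot <- function(x, ...) {
  cat(sprintf(
    "<enrichment_boot> observed DMR freq in NADs %.4f vs null median %.4f; p = %.4g (%d draws)\n",
    x$observed, median(x$null_freqs), x$p_value, x$n_boot
  ))
  invisible(x)
}

#' @rdname enrichment_bootstrap
#' @param x An `enrichment_boot` object.
#' @param ... Unused.
#' @method tidy enrichment_boot
#' @export
tidy.enrichment_boot <- function(x, ...) {
  tibble::tibble(
    observed_freq = x$observed,
    null_median = median(x$null_freqs),
    p_value = x$p_value,
    n_nad = x$n_nad,
    n_boot = x$n_boot
  )
}

#' Label regions as shared or private remodeling events
#'
#' A region is `shared` when it is remodeled in at least `min_shared`
#' families, `private` when remodeled in exactly one, and unlabelled
#' (`NA`) otherwise.
#'
#' @param nad_indicator Binary matrix, regions x families (1 = remodeled).
#' @param min_shared Minimum families for the shared label (>= 2).
#' @return Tibble with `region_id`, `n_families`, `label`.
#' @export
shared_private_labels <- function(nad_indicator, min_shared = 2) {
  if (min_shared < 2) abort("`min_shared` must be at least 2.")
  if (!all(nad_indicator %in% c(0, 1))) abort("Indicator matrix must be binary.")
  n <- rowSums(nad_indicator)
  tibble::tibble(
    region_id = rownames(nad_indicator) %||% as.character(seq_along(n)),
    n_families = as.integer(n),
    label = dplyr::case_when(
      n >= min_shared ~ "shared",
      n == 1 ~ "private",
      TRUE ~ NA_character_
    )
  )
}

#' Count labelled regions in sliding genomic windows
#'
#' Counts regions whose midpoint falls inside each half-open window
#' `[w, w + window_bp)`, with windows advancing by `step_bp` from position 0
#' to the last region midpoint per chromosome.
#'
#' @param regions Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param window_bp,step_bp Window width and step in bp (> 0).
#' @return Tibble with `chrom`, `win_start`, `win_end`, `count`.
#' @export
window_density <- function(regions, window_bp = 10000, step_bp = 10000) {
  if (window_bp <= 0 || step_bp <= 0) abort("Window and step must be positive.")
  if (nrow(regions) == 0) {
    return(tibble::tibble(
      chrom = character(), win_start = numeric(),
      win_end = numeric(), count = integer()
    ))
  }
  mid <- (regions$start + regions$end) %/% 2
  purrr::map_dfr(split(mid, regions$chrom), .id = "chrom", function(m) {
    starts <- seq(0, max(m), by = step_bp)
    counts <- vapply(
      starts,
      function(w) sum(m >= w & m < w + window_bp),
      integer(1)
    )
    tibble::tibble(win_start = starts, win_end = starts + window_bp, count = counts)
  })
}
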