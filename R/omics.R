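#' Filter low-expressed features and TMM-normalize counts
#'
#' Keeps features with at least `min_cpm` counts-per-million in at least
#' `min_samples` samples, computes trimmed-mean-of-M-values scaling factors
#' (30% M-trim, 5% A-trim, reference library closest to the mean upper
#' quartile) and returns counts-per-million on the effective library sizes.
#'
#' @param counts Integer matrix (features x samples) with row names, or a
#'   tibble whose first column is `feature_id`.
#' @param min_cpm,min_samples Filter thresholds.
#' @return A `normalized_counts` object: list with `cpm` (tibble,
#'   `feature_id` + one column per sample), `norm_factors` (tibble with
#'   `sample`, `lib_size`, `norm_factor`) and `kept` (feature ids).
#' @export
filter_and_normalize_counts <- function(counts, min_cpm = 1, min_samples = 2) {
  if (is.data.frame(counts)) {
    m <- as.matrix(counts[, -1])
    rownames(m) <- counts[[1]]
    counts <- m
  }
  if (any(counts < 0)) abort("Counts must be non-negative.")
  lib <- colSums(counts)
  if (any(lib == 0)) {
    abort(paste0(
      "All-zero library(ies): ",
      paste(colnames(counts)[lib == 0], collapse = ", ")
    ))
  }
  keep <- rowSums(edgeR::cpm(counts) >= min_cpm) >= min_samples
  dge <- edgeR::DGEList(counts = counts[keep, , drop = FALSE])
  dge <- edgeR::calcNormFactors(dge, method = "TMM")
  cpm <- edgeR::cpm(dge, normalized.lib.sizes = TRUE)
  structure(
    list(
      cpm = tibble::as_tibble(cpm, rownames = "feature_id"),
      norm_factors = tibble::tibble(
        sample = colnames(counts),
        lib_size = unname(dge$samples$lib.size),
        norm_factor = unname(dge$samples$norm.factors)
      ),
      kept = rownames(counts)[keep]
    ),
    class = "normalized_counts"
  )
}

#' @export
print.normalized_counts <- function(x, ...) {
  cat(sprintf(
    "<normalized_counts> %d feature(s) x %d sample(s) after filtering\n",
    nrow(x$cpm), nrow(x$norm_factors)
  ))
  invisible(x)
}

#' Per-feature mid-parent divergence of normalized counts
#'
#' Computes `(hybrid - MPV) / MPV * 100` per feature and trio from
#' normalized counts, where MPV is the mean of the two parental samples.
#' Records with MPV = 0 get a missing divergence and are flagged.
#'
#' @param normalized A `normalized_counts` object or a CPM tibble with
#'   `feature_id`.
#' @param trio_design Tibble with `family_id`, `mscol`, `epiril`, `hybrid`
#'   giving the sample (column) names of each trio.
#' @return Long tibble: `feature_id`, `family_id`, `pct_mpdiv`, `flagged`.
#' @export
omics_divergence <- function(normalized, trio_design) {
  cpm <- if (inherits(normalized, "normalized_counts")) normalized$cpm else normalized
  m <- as.matrix(cpm[, -1])
  rownames(m) <- cpm$feature_id
  missing_cols <- setdiff(
    unlist(trio_design[, c("mscol", "epiril", "hybrid")]),
    colnames(m)
  )
  if (length(missing_cols)) {
    abort(paste0("Trio sample column(s) missing: ", paste(missing_cols, collapse = ", ")))
  }
  purrr::pmap_dfr(trio_design, function(family_id, mscol, epiril, hybrid, ...) {
    mpv <- (m[, mscol] + m[, epiril]) / 2
    flagged <- unname(mpv == 0)
    tibble::tibble(
      feature_id = rownames(m),
      family_id = family_id,
      pct_mpdiv = unname(ifelse(flagged, NA_real_, (m[, hybrid] - mpv) / mpv * 100)),
      flagged = flagged
    )
  })
}

#' Link regions to nearby genes
#'
#' Pairs each region with every gene whose edge-to-edge distance is at most
#' `max_distance` bp (0 for overlap; strand-ignored). Gene annotation may
#' be a GFF3 file (1-based closed coordinates, converted at parse time) or
#' a tibble with `gene_id`, `chrom`, `start`, `end` already 0-based
#' half-open.
#'
#' @param regions Tibble with `region_id`, `chrom`, `start`, `end`.
#' @param genes GFF3 path or gene tibble.
#' @param max_distance Maximum gap in bp (>= 0; default 1000).
#' @return Tibble with `region_id`, `gene_id`, `distance`.
#' @export
link_regions_to_genes <- function(regions, genes, max_distance = 1000) {
  if (max_distance < 0) abort("`max_distance` must be non-negative.")
  if (is.character(genes)) {
    genes <- read_gff3_genes(genes)
  }
  gr_reg <- GenomicRanges::GRanges(
    regions$chrom,
    IRanges::IRanges(regions$start + 1, regions$end)
  )
  gr_gene <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(genes$start + 1, genes$end)
  )
  hits <- GenomicRanges::findOverlaps(gr_reg, gr_gene,
    maxgap = max_distance, ignore.strand = TRUE
  )
  if (length(hits) == 0) {
    return(tibble::tibble(
      region_id = character(), gene_id = character(),
      distance = numeric()
    ))
  }
  d <- GenomicRanges::distance(
    gr_reg[S4Vectors::queryHits(hits)],
    gr_gene[S4Vectors::subjectHits(hits)]
  )
  out <- tibble::tibble(
    region_id = regions$region_id[S4Vectors::queryHits(hits)],
    gene_id = genes$gene_id[S4Vectors::subjectHits(hits)],
    distance = as.numeric(d)
  )
  out[out$distance <= max_distance, ]
}

#' Fraction of regions overlapping genes, per category
#'
#' Annotation-style summary: for each level of `by` (e.g. the remodeling
#' scenario), the fraction of regions overlapping a gene (distance 0) and
#' the fraction within `max_distance`.
#'
#' @param regions Tibble with `region_id` and the `by` column.
#' @param links Output of [link_regions_to_genes()].
#' @param by Grouping column name in `regions`.
#' @return Tibble with `category`, `n_regions`, `frac_overlap`,
#'   `frac_linked`.
#' @export
category_overlap_fractions <- function(regions, links, by = "scenario") {
  overlap_ids <- unique(links$region_id[links$distance == 0])
  linked_ids <- unique(links$region_id)
  dplyr::summarise(
    dplyr::group_by(regions, category = .data[[by]]),
    n_regions = dplyr::n(),
    frac_overlap = mean(.data$region_id %in% overlap_ids),
    frac_linked = mean(.data$region_id %in% linked_ids),
    .groups = "drop"
  )
}

#' Correlate two mid-parent divergence tracks across trios
#'
#' Pearson correlation, per linked pair, of e.g. methylation and sRNA (or
#' methylation and expression) divergence over families. Features with
#' fewer than 3 complete paired observations are skipped; callers should
#' drop features with no reads in any sample beforehand (or rely on the
#' missing divergences those produce).
#'
#' @param div_a,div_b Long divergence tibbles (`feature_id`, `family_id`,
#'   `pct_mpdiv`) -- region ids count as feature ids.
#' @param pairs Tibble with `feature_a`, `feature_b` naming the pairs to
#'   test (a from `div_a`, b from `div_b`).
#' @param alpha Significance level.
#' @return Tibble with `feature_a`, `feature_b`, `n`, `pearson_r`,
#'   `p_value`, `significant`.
#' @export
divergence_correlation <- function(div_a, div_b, pairs, alpha = 0.05) {
  out <- purrr::pmap_dfr(pairs, function(feature_a, feature_b, ...) {
    a <- div_a[div_a$feature_id == feature_a, c("family_id", "pct_mpdiv")]
    b <- div_b[div_b$feature_id == feature_b, c("family_id", "pct_mpdiv")]
    j <- dplyr::inner_join(a, b, by = "family_id", suffix = c("_a", "_b"))
    j <- j[complete.cases(j), ]
    if (nrow(j) < 3 || sd(j$pct_mpdiv_a) == 0 || sd(j$pct_mpdiv_b) == 0) {
      return(tibble::tibble(
        feature_a = feature_a, feature_b = feature_b,
        n = nrow(j), pearson_r = NA_real_, p_value = NA_real_,
        significant = NA
      ))
    }
    ct <- stats::cor.test(j$pct_mpdiv_a, j$pct_mpdiv_b)
    tibble::tibble(
      feature_a = feature_a, feature_b = feature_b, n = nrow(j),
      pearson_r = unname(ct$estimate), p_value = ct$p.value,
      significant = ct$p.value < alpha
    )
  })
  out
}

#' Candidate-gene filtering chain
#'
#' Pure function implementing the gene-linking chain: QTL target regions
#' are linked to genes within `max_distance`; links are re-tested in a trio
#' subset by requiring either a significant methylation-expression
#' divergence correlation or a direct association of the gene's expression
#' divergence with the QTL epigenotype; the unique gene list is returned.
#'
#' @param target_regions Tibble of QTL target regions (`region_id`,
#'   `chrom`, `start`, `end`).
#' @param genes Gene tibble or GFF3 path.
#' @param meth_div,expr_div Long divergence tibbles for the trio subset.
#' @param qtl_geno Named 0/1 vector of the QTL epigenotype per family.
#' @param max_distance Gene-linking distance (default 1000 bp).
#' @param alpha Significance level for both tests.
#' @return List with `links`, `correlations`, `direct`, and `genes` (the
#'   unique candidate gene ids).
#' @export
candidate_gene_chain <- function(target_regions, genes, meth_div, expr_div,
                                 qtl_geno, max_distance = 1000, alpha = 0.05) {
  links <- link_regions_to_genes(target_regions, genes, max_distance)
  if (nrow(links) == 0) {
    return(list(
      links = links, correlations = tibble::tibble(),
      direct = tibble::tibble(), genes = character()
    ))
  }
  pairs <- tibble::tibble(feature_a = links$region_id, feature_b = links$gene_id)
  corr <- divergence_correlation(meth_div, expr_div, pairs, alpha)
  direct <- purrr::map_dfr(unique(links$gene_id), function(g) {
    e <- expr_div[expr_div$feature_id == g, ]
    gg <- qtl_geno[e$family_id]
    ok <- is.finite(e$pct_mpdiv) & is.finite(gg)
    if (sum(ok) < 3 || length(unique(gg[ok])) < 2) {
      return(tibble::tibble(gene_id = g, p_value = NA_real_, significant = NA))
    }
    fit <- lm(e$pct_mpdiv[ok] ~ gg[ok])
    p <- summary(fit)$coefficients[2, 4]
    tibble::tibble(gene_id = g, p_value = p, significant = p < alpha)
  })
  # corr rows align one-to-one with link rows
  g1 <- links$gene_id[which(corr$significant %in% TRUE)]
  g2 <- direct$gene_id[direct$significant %in% TRUE]
  list(
    links = links, correlations = corr, direct = direct,
    genes = sort(unique(c(g1, g2)))
  )
}

# Parse a GFF3 file down to gene features with 0-based half-open coords.
read_gff3_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  ids <- gr$ID %||% gr$gene_id %||% as.character(seq_along(gr))
  tibble::tibble(
    gene_id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr)
  )
}
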