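#' Default specification for a synthetic epihaplotype marker map
#'
#' Describes five chromosomes with genetic (cM) and physical (bp) lengths in
#' the range typical of the *Arabidopsis thaliana* genome, and a regular
#' marker spacing chosen so that the default map carries 144 segregating
#' markers in total -- the size of the published epiRIL recombination map.
#'
#' @param spacing_cM Distance between adjacent markers in centimorgans.
#' @return A list with elements `chromosomes` (tibble: `chrom`, `length_cM`,
#'   `length_bp`) and `spacing_cM`.
#' @export
default_map_spec <- function(spacing_cM = 5) {
  list(
    chromosomes = tibble::tibble(
      chrom = paste0("chr", 1:5),
      length_cM = c(135, 105, 120, 125, 210),
      length_bp = c(30.4e6, 19.7e6, 23.5e6, 18.6e6, 27.0e6)
    ),
    spacing_cM = spacing_cM
  )
}

#' Simulate an epihaplotype marker map skeleton
#'
#' Lays markers on a regular centimorgan grid along each chromosome and
#' interpolates physical positions linearly from the chromosome's bp length.
#' The default specification yields 144 markers on 5 chromosomes.
#'
#' @param spec Map specification as returned by [default_map_spec()].
#' @return An `epimap` object with a `markers` tibble (`marker_id`, `chrom`,
#'   `cM`, `bp`) and `geno = NULL` (no lines simulated yet).
#' @seealso [simulate_epiril_pedigree()] to populate line epigenotypes.
#' @examples
#' map <- simulate_marker_map()
#' nrow(map$markers)  # 144
#' @export
simulate_marker_map <- function(spec = default_map_spec()) {
  if (!is.list(spec) || is.null(spec$chromosomes) || is.null(spec$spacing_cM)) {
    abort("`spec` must be a list with elements `chromosomes` and `spacing_cM`.")
  }
  if (spec$spacing_cM <= 0) {
    abort("Marker spacing must be positive.")
  }
  if (any(spec$chromosomes$length_cM < 0) || any(spec$chromosomes$length_bp <= 0)) {
    abort("Chromosome lengths must be non-negative (cM) and positive (bp).")
  }
  markers <- purrr::pmap_dfr(
    spec$chromosomes,
    function(chrom, length_cM, length_bp) {
      cM <- seq(0, length_cM, by = spec$spacing_cM)
      if (length_cM == 0) cM <- 0
      bp <- if (length_cM == 0) {
        round(length_bp / 2)
      } else {
        round(cM / length_cM * length_bp)
      }
      tibble::tibble(chrom = chrom, cM = cM, bp = bp)
    }
  )
  markers <- dplyr::arrange(markers, .data$chrom, .data$cM)
  markers <- dplyr::mutate(
    dplyr::group_by(markers, .data$chrom),
    marker_id = sprintf("MM%s_%03d", sub("^chr", "", .data$chrom[1]), dplyr::row_number())
  )
  markers <- dplyr::relocate(dplyr::ungroup(markers), "marker_id")
  new_epimap(markers, geno = NULL)
}

new_epimap <- function(markers, geno) {
  structure(list(markers = markers, geno = geno), class = "epimap")
}

#' @export
print.epimap <- function(x, ...) {
  cat(sprintf(
    "<epimap> %d markers on %d chromosome(s)%s\n",
    nrow(x$markers), dplyr::n_distinct(x$markers$chrom),
    if (is.null(x$geno)) " (skeleton, no lines)" else sprintf(", %d lines", nrow(x$geno))
  ))
  invisible(x)
}

#' Tidy the marker table or epigenotypes of an epimap
#'
#' @param x An `epimap`.
#' @param ... Unused.
#' @return The markers tibble; if line epigenotypes are present, joined with
#'   one row per line x marker carrying `line_id` and `epigenotype`
#'   (`"MM"`/`"UU"`).
#' @method tidy epimap
#' @export
tidy.epimap <- function(x, ...) {
  if (is.null(x$geno)) {
    return(x$markers)
  }
  long <- tibble::as_tibble(x$geno, rownames = "line_id")
  long <- tidyr::pivot_longer(long, -"line_id",
    names_to = "marker_id", values_to = "code"
  )
  long$epigenotype <- ifelse(long$code == 1L, "UU", "MM")
  dplyr::left_join(long[, c("line_id", "marker_id", "epigenotype")],
    x$markers,
    by = "marker_id"
  )
}

# One meiosis for a matrix pair of haplotypes (lines x markers, one
# chromosome, cM sorted). Crossovers between adjacent markers are i.i.d.
# Bernoulli with the Haldane recombination fraction for the interval.
gamete_ <- function(h1, h2, r_adj) {
  n <- nrow(h1)
  m <- ncol(h1)
  out <- matrix(0L, n, m)
  cur <- rbinom(n, 1L, 0.5)        # 0 -> read h1, 1 -> read h2
  out[, 1] <- ifelse(cur == 0L, h1[, 1], h2[, 1])
  if (m > 1) {
    for (j in 2:m) {
      flip <- runif(n) < r_adj[j - 1]
      cur <- ifelse(flip, 1L - cur, cur)
      out[, j] <- ifelse(cur == 0L, h1[, j], h2[, j])
    }
  }
  out
}

#' Simulate epiRIL epigenotypes through the derivation pedigree
#'
#' Propagates each line through the cross design that produced the epiRIL
#' population: a fully methylated wild-type founder (MM at every segregating
#' locus) crossed to a fully hypomethylated ddm1 founder (UU), the F1
#' backcrossed to the wild type, followed by six generations of single-seed
#' descent. Recombination between adjacent markers follows the Haldane map
#' function on the cM distance at every meiosis, independently per line.
#' Residual heterozygotes remaining after the six selfing generations
#' (expected fraction (1/2)*(1/2)^6, about 0.78% of lines per locus) are
#' resolved to a random homozygote, so the output is fully homozygous.
#' Under this design the expected UU frequency at any segregating locus is
#' exactly 25%.
#'
#' @param map An `epimap` skeleton from [simulate_marker_map()].
#' @param n_lines Number of epiRILs to simulate (>= 1).
#' @param seed Optional integer seed; same seed gives bit-identical output.
#' @return The `epimap` with a `geno` matrix (lines x markers; 0 = MM,
#'   1 = UU), row names `epiRIL_###`.
#' @examples
#' map <- simulate_marker_map()
#' map <- simulate_epiril_pedigree(map, n_lines = 50, seed = 1)
#' @export
simulate_epiril_pedigree <- function(map, n_lines, seed = NULL) {
  stopifnot(inherits(map, "epimap"))
  if (!is.numeric(n_lines) || n_lines < 1) {
    abort("`n_lines` must be at least 1.")
  }
  n_lines <- as.integer(n_lines)
  with_seed_(seed, {
    geno <- matrix(0L, n_lines, nrow(map$markers),
      dimnames = list(
        sprintf("epiRIL_%03d", seq_len(n_lines)),
        map$markers$marker_id
      )
    )
    for (ch in unique(map$markers$chrom)) {
      idx <- which(map$markers$chrom == ch)
      cM <- map$markers$cM[idx]
      r_adj <- haldane(diff(cM))
      m <- length(idx)
      # F1 is MU at every locus: one wt (0) and one ddm1 (1) haplotype.
      f1_h1 <- matrix(0L, n_lines, m)
      f1_h2 <- matrix(1L, n_lines, m)
      # Backcross to wild type: one recombinant F1 gamete + one wt gamete.
      h1 <- gamete_(f1_h1, f1_h2, r_adj)
      h2 <- matrix(0L, n_lines, m)
      # Six rounds of single-seed descent (selfing).
      for (g in 1:6) {
        a <- gamete_(h1, h2, r_adj)
        b <- gamete_(h1, h2, r_adj)
        h1 <- a
        h2 <- b
      }
      tot <- h1 + h2                      # 0 = MM, 1 = MU, 2 = UU
      het <- tot == 1L
      if (any(het)) {
        # resolve residual heterozygotes by one further gamete drawn from
        # the line's own haplotypes, preserving linkage between loci
        fix <- gamete_(h1, h2, r_adj)
        tot[het] <- 2L * fix[het]
      }
      geno[, idx] <- tot %/% 2L
    }
    new_epimap(map$markers, geno)
  })
}

#' Fraction of UU calls per marker
#'
#' @param map An `epimap` with simulated lines.
#' @return Tibble with `marker_id`, `chrom`, `cM`, `bp` and `uu_freq`.
#' @export
uu_frequency <- function(map) {
  stopifnot(inherits(map, "epimap"), !is.null(map$geno))
  dplyr::mutate(map$markers, uu_freq = unname(colMeans(map$geno == 1L)))
}
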