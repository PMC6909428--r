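#' SNP-index from stranded DP4 read counts
#'
#' The SNP-index of a pool at a site is the fraction of reads carrying the
#' alternative (mutant) allele: `(alt_fwd + alt_rev) / total`. It is
#' undefined (`NA`) at zero depth. 1.0 means the pool is fixed for the
#' mutant allele.
#'
#' @param dp4 a numeric vector of length 4 (`ref_fwd, ref_rev, alt_fwd,
#'   alt_rev`) or a 4-column matrix/data.frame of such rows.
#' @return A single fraction in \[0, 1\] (or vector, one per row), `NA`
#'   where total depth is zero.
#' @examples
#' snp_index(c(0, 0, 10, 12))  # 1.0
#' snp_index(c(4, 4, 2, 2))    # 1/3
#' @export
snp_index <- function(dp4) {
  if (is.data.frame(dp4)) dp4 <- as.matrix(dp4)
  if (is.null(dim(dp4))) {
    if (length(dp4) != 4L) stop("dp4 must have 4 counts")
    dp4 <- matrix(dp4, nrow = 1L)
  }
  if (ncol(dp4) != 4L) stop("dp4 must have 4 columns")
  if (any(dp4 < 0)) stop("read counts must be non-negative")
  tot <- rowSums(dp4)
  alt <- dp4[, 3L] + dp4[, 4L]
  ifelse(tot > 0, alt / tot, NA_real_)
}

#' Per-pool SNP-indices for a set of pooled variants
#'
#' Adds per-pool SNP-index and depth columns to a `pooled_variants` table.
#'
#' @param variants a `pooled_variants` data.frame (see
#'   [assemble_pooled_variants()] / [read_pooled_vcf()]).
#' @return A `snp_index_result` data.frame: the input plus `depth_mt`,
#'   `depth_wt`, `index_mt`, `index_wt` (`NA` index at zero depth).
#' @export
compute_indices <- function(variants) {
  stopifnot(is.data.frame(variants))
  mt <- as.matrix(variants[, c("mt_ref_fwd", "mt_ref_rev", "mt_alt_fwd", "mt_alt_rev")])
  wt <- as.matrix(variants[, c("wt_ref_fwd", "wt_ref_rev", "wt_alt_fwd", "wt_alt_rev")])
  out <- variants
  out$depth_mt <- rowSums(mt)
  out$depth_wt <- rowSums(wt)
  out$index_mt <- snp_index(mt)
  out$index_wt <- snp_index(wt)
  class(out) <- c("snp_index_result", "data.frame")
  out
}

# F2 genotype classes: mutant-allele dosage 0/1/2 with frequencies 1:2:1
.f2_classes <- function() data.frame(dosage = 0:2, w = c(1, 2, 1))

#' Expected SNP-index per pool from the cross design
#'
#' Derives, exactly, the expected SNP-index at the causal locus in each
#' phenotype pool by enumerating F2 genotype classes (ratio 1:2:1)
#' conditional on pool membership. For a recessive mutation the MT pool
#' contains only `aa` individuals, so its expected index is 1; the WT pool
#' has `AA:Aa:aa = 1:2:0`, giving reference:alternative allele ratio 2:1 and
#' expected index 1/3.
#'
#' @param design a [cross_design()] (only the inheritance mode is used).
#' @return Named numeric vector `c(mt = ..., wt = ...)` of exact fractions.
#' @examples
#' expected_indices(cross_design("x", inheritance = "recessive"))
#' @export
expected_indices <- function(design) {
  stopifnot(inherits(design, "cross_design"))
  if (design$generation != "F2") stop("only F2 designs are supported")
  cl <- .f2_classes()
  pheno <- .phenotype_from_dosage(cl$dosage, design$inheritance)
  idx_for <- function(p) {
    keep <- pheno == p
    sum(cl$w[keep] * cl$dosage[keep] / 2) / sum(cl$w[keep])
  }
  c(mt = idx_for("mutant"), wt = idx_for("wild_type"))
}

#' Expected SNP-index at a linked marker
#'
#' Enumerates the 16 ordered pairs of F1 two-locus gamete haplotypes
#' (causal locus, marker at recombination fraction `r`; mutant alleles in
#' coupling) and conditions on pool phenotype at the causal locus to obtain
#' the expected marker-allele frequency in the pool. For the recessive MT
#' pool this is `1 - r`; at an unlinked marker (`r = 0.5`) both pools give
#' 0.5.
#'
#' @param design a [cross_design()].
#' @param r recombination fraction between marker and causal locus, in
#'   \[0, 0.5\].
#' @param pool `"mt"` or `"wt"`.
#' @return Expected marker SNP-index (scalar).
#' @examples
#' d <- cross_design("x")
#' expected_marker_index(d, r = 0.1, pool = "mt")  # 0.9
#' @export
expected_marker_index <- function(design, r, pool = c("mt", "wt")) {
  stopifnot(inherits(design, "cross_design"))
  pool <- match.arg(pool)
  if (!is.numeric(r) || r < 0 || r > 0.5) stop("r must be in [0, 0.5]")
  # gamete haplotypes (causal, marker), 1 = mutant allele
  hap <- expand.grid(c = 0:1, m = 0:1)
  hap$p <- ifelse(hap$c == hap$m, (1 - r) / 2, r / 2)
  target <- if (pool == "mt") "mutant" else "wild_type"
  num <- den <- 0
  for (i in seq_len(4L)) for (j in seq_len(4L)) {
    p <- hap$p[i] * hap$p[j]
    pheno <- .phenotype_from_dosage(hap$c[i] + hap$c[j], design$inheritance)
    if (pheno == target) {
      den <- den + p
      num <- num + p * (hap$m[i] + hap$m[j]) / 2
    }
  }
  if (den == 0) stop("pool '", pool, "' is empty under this design")
  num / den
}

#' Dual-pool screening criterion
#'
#' The screen retains sites fixed for the mutant allele in the MT pool
#' (SNP-index 1.0, i.e. zero reference reads at nonzero depth) whose WT-pool
#' index lies in a band around 0.3 (default halfwidth 0.1, endpoints
#' inclusive; the analytic expectation 1/3 lies inside). A relaxed MT
#' threshold `index >= 1 - mt_epsilon` is available because exact unity is
#' fragile under sequencing error; the default `mt_epsilon = 0` keeps the
#' strict count-level rule.
#'
#' @param mt_target expected MT-pool index (default 1).
#' @param wt_center centre of the WT-pool acceptance band (default 0.3).
#' @param wt_halfwidth halfwidth of the WT band (default 0.1).
#' @param min_depth minimum read depth required in each pool (default 10;
#'   an assumption, not a published value).
#' @param mt_epsilon relaxation of the MT criterion (default 0 = exact).
#' @return An object of class `screen_criterion`.
#' @export
screen_criterion <- function(mt_target = 1, wt_center = 0.3, wt_halfwidth = 0.1,
                             min_depth = 10, mt_epsilon = 0) {
  stopifnot(mt_target >= 0, mt_target <= 1, wt_center >= 0, wt_center <= 1,
            wt_halfwidth > 0, min_depth >= 0, mt_epsilon >= 0)
  structure(list(mt_target = mt_target, wt_center = wt_center,
                 wt_halfwidth = wt_halfwidth, min_depth = min_depth,
                 mt_epsilon = mt_epsilon),
            class = "screen_criterion")
}

#' Screen SNP sites with the dual-pool criterion
#'
#' Applies the screening rule to indexed variants: depth at least
#' `min_depth` in both pools, MT-pool index equal to the target (with
#' `mt_epsilon = 0` this is the count-level rule "zero reference reads,
#' nonzero depth"), and WT-pool index within `wt_center +/- wt_halfwidth`
#' (inclusive). Candidates are returned sorted by scaffold then position.
#'
#' @param results a `snp_index_result` from [compute_indices()].
#' @param criterion a [screen_criterion()].
#' @return The retained subset (possibly empty), same columns as `results`.
#' @export
screen_candidates <- function(results, criterion = screen_criterion()) {
  stopifnot(inherits(results, "data.frame"),
            inherits(criterion, "screen_criterion"))
  eps <- 1e-9  # guard against float noise in band-endpoint comparisons
  depth_ok <- results$depth_mt >= criterion$min_depth &
    results$depth_wt >= criterion$min_depth
  if (criterion$mt_epsilon == 0) {
    mt_ref <- results$mt_ref_fwd + results$mt_ref_rev
    mt_ok <- results$depth_mt > 0 & mt_ref == 0 &
      abs(criterion$mt_target - 1) < eps
    # a non-unit strict target falls back to exact index equality
    if (abs(criterion$mt_target - 1) >= eps)
      mt_ok <- !is.na(results$index_mt) &
        abs(results$index_mt - criterion$mt_target) <= eps
  } else {
    mt_ok <- !is.na(results$index_mt) &
      results$index_mt >= criterion$mt_target - criterion$mt_epsilon - eps
  }
  wt_ok <- !is.na(results$index_wt) &
    abs(results$index_wt - criterion$wt_center) <= criterion$wt_halfwidth + eps
  keep <- which(depth_ok & mt_ok & wt_ok)
  out <- results[keep, , drop = FALSE]
  out <- out[order(out$scaffold, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}
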