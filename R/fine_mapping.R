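#' Exclude candidate SNPs inconsistent with causality
#'
#' Tests each candidate SNP in a genotype table against the inheritance
#' model, individual by individual. Under recessive inheritance an
#' individual is inconsistent with a candidate being causal iff it has the
#' mutant phenotype without being `aa`, or the wild-type phenotype while
#' being `aa`. A candidate with at least one inconsistent individual is
#' excluded; one with no inconsistency among at least one informative
#' (non-missing) call is completely linked with the phenotype.
#'
#' @param table a [genotype_table()].
#' @param inheritance `"recessive"` (default) or `"dominant"`.
#' @return A `consistency_report` data.frame: per candidate locus,
#'   `n_informative`, `n_inconsistent`, `inconsistent_individuals`
#'   (comma-separated ids) and `status` in `completely_linked` /
#'   `excluded` / `undetermined`.
#' @examples
#' tab <- genotype_table(data.frame(
#'   id = c("#130", "#251"), phenotype = c("wild_type", "mutant"),
#'   locus_a = c("Aa", "aa"), locus_b = c("aa", "Aa")))
#' exclude_candidates(tab)
#' @export
exclude_candidates <- function(table, inheritance = c("recessive", "dominant")) {
  inheritance <- match.arg(inheritance)
  stopifnot(is.data.frame(table))
  loci <- setdiff(names(table), c("id", "phenotype"))
  res <- lapply(loci, function(l) {
    g <- table[[l]]
    informative <- !is.na(g)
    mutant <- table$phenotype == "mutant"
    bad <- if (inheritance == "recessive") {
      (mutant & g != "aa") | (!mutant & g == "aa")
    } else {
      (mutant & g == "AA") | (!mutant & g != "AA")
    }
    bad <- informative & bad
    status <- if (sum(informative) == 0L) {
      warning("candidate ", l, " has no informative individuals")
      "undetermined"
    } else if (any(bad)) "excluded" else "completely_linked"
    data.frame(locus = l,
               n_informative = sum(informative),
               n_inconsistent = sum(bad),
               inconsistent_individuals = paste(table$id[bad], collapse = ","),
               status = status, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("consistency_report", "data.frame")
  out
}

#' @export
print.consistency_report <- function(x, ...) {
  cat("Fine-mapping consistency report\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %s: %s (%d informative, %d inconsistent%s)\n",
                x$locus[i], x$status[i], x$n_informative[i], x$n_inconsistent[i],
                if (nzchar(x$inconsistent_individuals[i]))
                  paste0(": ", x$inconsistent_individuals[i]) else ""))
  }
  invisible(x)
}

#' Find recombinants between two candidate loci
#'
#' Flags individuals whose two-locus genotype pair is impossible without a
#' crossover between the loci. With both mutations inherited in coupling
#' from the mutant parent, a non-recombinant individual carries identical
#' genotype codes at the two loci; any differing pair (e.g. `aa`/`Aa`)
#' requires at least one recombinant gamete. An `Aa`/`Aa` pair could hide
#' two complementary recombinant gametes but cannot be resolved without
#' phase, so it is not flagged.
#'
#' @param table a [genotype_table()].
#' @param locus_a,locus_b column names of the two candidate SNPs.
#' @return Character vector of recombinant individual ids.
#' @export
find_recombinants <- function(table, locus_a, locus_b) {
  stopifnot(is.data.frame(table))
  if (!all(c(locus_a, locus_b) %in% names(table)))
    stop("both loci must be columns of the genotype table")
  ga <- table[[locus_a]]
  gb <- table[[locus_b]]
  rec <- !is.na(ga) & !is.na(gb) & ga != gb
  table$id[rec]
}

#' Build a genotype table from a simulated population
#'
#' Emulates amplicon genotyping of individual plants at candidate SNPs:
#' extracts error-free genotype codes for the given loci from an
#' `f2_population`.
#'
#' @param pop an `f2_population`.
#' @param loci SNP ids to genotype (default all).
#' @return A [genotype_table()].
#' @export
genotype_table_from_population <- function(pop, loci = colnames(pop$genotypes)) {
  codes <- genotype_codes(pop, loci)
  df <- data.frame(id = pop$id, phenotype = pop$phenotype,
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (j in seq_along(loci)) df[[loci[j]]] <- codes[, j]
  genotype_table(df)
}
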