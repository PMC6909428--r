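#' Define an F2 cross design
#'
#' Describes the mating scheme behind a bulked-segregant experiment: a
#' mutagenised line crossed to its wild-type parent, selfed to F2, with
#' progeny pooled by phenotype. The inheritance mode fixes how genotype at
#' the causal SNP maps to phenotype (recessive: mutant iff homozygous for
#' the mutant allele).
#'
#' @param causal_snp id of the causal SNP (must exist in the mutation set
#'   used for simulation).
#' @param inheritance `"recessive"` (default) or `"dominant"`.
#' @param n_progeny number of F2 individuals (default 280).
#' @param generation only `"F2"` is supported.
#' @return An object of class `cross_design`.
#' @examples
#' cross_design("scf01_12345")
#' @export
cross_design <- function(causal_snp, inheritance = c("recessive", "dominant"),
                         n_progeny = 280, generation = "F2") {
  inheritance <- match.arg(inheritance)
  generation <- match.arg(generation, "F2")
  stopifnot(is.character(causal_snp), length(causal_snp) == 1L)
  if (!is.numeric(n_progeny) || n_progeny < 0 || n_progeny != round(n_progeny))
    stop("n_progeny must be a non-negative integer")
  structure(
    list(causal_snp = causal_snp, inheritance = inheritance,
         n_progeny = as.integer(n_progeny), generation = generation,
         mt_pool_phenotype = "mutant", wt_pool_phenotype = "wild_type"),
    class = "cross_design"
  )
}

#' @export
print.cross_design <- function(x, ...) {
  cat(sprintf("F2 cross design: %s inheritance, causal SNP %s, %d progeny\n",
              x$inheritance, x$causal_snp, x$n_progeny))
  invisible(x)
}

# phenotype from alt-allele dosage (0/1/2) at the causal SNP
.phenotype_from_dosage <- function(dosage, inheritance) {
  mutant <- if (inheritance == "recessive") dosage == 2L else dosage >= 1L
  ifelse(mutant, "mutant", "wild_type")
}

# Simulate n gametes from an F1 heterozygous at all SNPs on one scaffold.
# SNP positions must be sorted. Returns an n x m 0/1 matrix (1 = mutant
# allele). Inter-SNP switch probabilities are the Haldane recombination
# fractions, which is exactly the interference-free Poisson crossover model.
.simulate_gametes <- function(n, pos, recomb_rate) {
  m <- length(pos)
  allele <- matrix(0L, n, m)
  if (m == 0L || n == 0L) return(allele)
  allele[, 1L] <- as.integer(runif(n) < 0.5)
  if (m > 1L) {
    r <- haldane_r(.genetic_dist(diff(pos), recomb_rate))
    for (j in 2:m) {
      switch_ <- runif(n) < r[j - 1L]
      allele[, j] <- ifelse(switch_, 1L - allele[, j - 1L], allele[, j - 1L])
    }
  }
  allele
}

#' Simulate an F2 population
#'
#' Builds each F2 individual from two independent F1 gametes. The F1 is
#' heterozygous at every mutation (mutant line x wild type), and gametes are
#' generated under the Haldane map function: crossovers follow a Poisson
#' process along each scaffold with rate set by the genome's recombination
#' rate, with no interference. Phenotype is a deterministic function of the
#' genotype at the causal SNP given the inheritance mode.
#'
#' @param design a [cross_design()]; its `causal_snp` must be present in
#'   `mutations`.
#' @param mutations a `mutation_set` from [simulate_ems_mutations()].
#' @param genome the [genome_model()].
#' @param seed optional integer seed.
#' @return An `f2_population`: list with `id`, `genotypes` (individuals x
#'   SNPs integer matrix of mutant-allele dosage 0/1/2, columns named by SNP
#'   id), `phenotype`, plus the design and mutation table.
#' @examples
#' g <- genome_model(c(scf01 = 1e6))
#' mu <- simulate_ems_mutations(g, 20, seed = 1)
#' d <- cross_design(mu$id[1], n_progeny = 50)
#' pop <- simulate_f2_population(d, mu, g, seed = 2)
#' table(pop$phenotype)
#' @export
simulate_f2_population <- function(design, mutations, genome, seed = NULL) {
  stopifnot(inherits(design, "cross_design"), inherits(genome, "genome_model"))
  if (!design$causal_snp %in% mutations$id)
    stop("causal SNP '", design$causal_snp, "' is missing from the mutation set")
  if (!is.null(seed)) set.seed(seed)

  n <- design$n_progeny
  m <- nrow(mutations)
  geno <- matrix(0L, n, m, dimnames = list(NULL, mutations$id))
  for (sc in unique(mutations$scaffold)) {
    j <- which(mutations$scaffold == sc)
    pos <- mutations$pos[j]
    g1 <- .simulate_gametes(n, pos, genome$recomb_rate)
    g2 <- .simulate_gametes(n, pos, genome$recomb_rate)
    geno[, j] <- g1 + g2
  }
  dosage_causal <- if (n > 0L) geno[, design$causal_snp] else integer(0)
  structure(
    list(id = if (n > 0L) sprintf("F2_%03d", seq_len(n)) else character(0),
         genotypes = geno,
         phenotype = .phenotype_from_dosage(dosage_causal, design$inheritance),
         design = design, mutations = mutations),
    class = "f2_population"
  )
}

#' @export
print.f2_population <- function(x, ...) {
  cat(sprintf("F2 population: %d individuals, %d SNPs (%d mutant / %d wild type)\n",
              length(x$id), ncol(x$genotypes),
              sum(x$phenotype == "mutant"), sum(x$phenotype == "wild_type")))
  invisible(x)
}

#' Subset an F2 population by individual
#'
#' @param pop an `f2_population`.
#' @param idx integer or logical index over individuals.
#' @return The subsetted `f2_population`.
#' @export
subset_individuals <- function(pop, idx) {
  stopifnot(inherits(pop, "f2_population"))
  pop$id <- pop$id[idx]
  pop$genotypes <- pop$genotypes[idx, , drop = FALSE]
  pop$phenotype <- pop$phenotype[idx]
  pop
}

#' Partition an F2 population into phenotype pools
#'
#' Splits the population into the mutant-phenotype (MT) and
#' wild-type-phenotype (WT) pools used for pooled sequencing. Pool sizes sum
#' to the population size; an empty pool is flagged with a warning.
#'
#' @param population an `f2_population`.
#' @param design the [cross_design()] (pool phenotypes; kept for interface
#'   symmetry, pooling is by the recorded phenotype).
#' @return list with elements `mt` and `wt`, each an `f2_population`.
#' @export
pool_individuals <- function(population, design = population$design) {
  stopifnot(inherits(population, "f2_population"))
  mt <- subset_individuals(population, population$phenotype == design$mt_pool_phenotype)
  wt <- subset_individuals(population, population$phenotype == design$wt_pool_phenotype)
  if (length(mt$id) == 0L) warning("MT pool is empty (no mutant-phenotype individuals)")
  if (length(wt$id) == 0L) warning("WT pool is empty (no wild-type-phenotype individuals)")
  list(mt = mt, wt = wt)
}

#' Simulate pooled sequencing read counts
#'
#' Generates stranded DP4-style read counts at every SNP for one DNA pool.
#' Each pool member contributes DNA equally, so a read carries the mutant
#' allele with probability equal to the pool's mutant-allele frequency at
#' the site; sequencing error flips a read's allele with probability
#' `error_rate`. Realised depth per site is Poisson(`depth`); each read's
#' strand is assigned forward/reverse with probability 1/2.
#'
#' @param pool an `f2_population` (one phenotype pool).
#' @param mutations the `mutation_set` (defines SNP order).
#' @param depth mean reads per site (default 50).
#' @param error_rate per-base substitution probability, in \[0, 0.5).
#' @param seed optional integer seed.
#' @return A `pooled_read_counts` data.frame: `snp_id`, `ref_fwd`,
#'   `ref_rev`, `alt_fwd`, `alt_rev`.
#' @export
simulate_pooled_reads <- function(pool, mutations = pool$mutations, depth = 50,
                                  error_rate = 0, seed = NULL) {
  stopifnot(inherits(pool, "f2_population"))
  if (!is.numeric(depth) || depth < 0) stop("depth must be >= 0")
  if (!is.numeric(error_rate) || error_rate < 0 || error_rate >= 0.5)
    stop("error_rate must be in [0, 0.5)")
  n_ind <- length(pool$id)
  if (n_ind == 0L && depth > 0) stop("cannot sequence an empty pool at depth > 0")
  if (!is.null(seed)) set.seed(seed)

  ids <- mutations$id
  m <- length(ids)
  geno <- pool$genotypes[, ids, drop = FALSE]
  q <- if (n_ind > 0L) colSums(geno) / (2 * n_ind) else rep(0, m)
  p_alt <- q * (1 - error_rate) + (1 - q) * error_rate

  n_reads <- rpois(m, depth)
  alt <- rbinom(m, n_reads, p_alt)
  ref <- n_reads - alt
  ref_fwd <- rbinom(m, ref, 0.5)
  alt_fwd <- rbinom(m, alt, 0.5)
  res <- data.frame(snp_id = ids,
                    ref_fwd = ref_fwd, ref_rev = ref - ref_fwd,
                    alt_fwd = alt_fwd, alt_rev = alt - alt_fwd,
                    stringsAsFactors = FALSE)
  class(res) <- c("pooled_read_counts", "data.frame")
  attr(res, "n_individuals") <- n_ind
  res
}

#' Genotype codes for an F2 population
#'
#' Converts the internal dosage matrix to the `AA`/`Aa`/`aa` codes used in
#' genotype tables (`A` = reference/wild allele, `a` = mutant allele).
#'
#' @param pop an `f2_population`.
#' @param loci SNP ids to include (default all).
#' @return Character matrix (individuals x loci).
#' @export
genotype_codes <- function(pop, loci = colnames(pop$genotypes)) {
  stopifnot(inherits(pop, "f2_population"))
  d <- pop$genotypes[, loci, drop = FALSE]
  codes <- matrix(c("AA", "Aa", "aa")[d + 1L], nrow(d), ncol(d),
                  dimnames = dimnames(d))
  codes
}
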