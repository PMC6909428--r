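# Shared fixture builders: tiny hand-made mutation sets, populations and
# read-count tables so tests can exercise one operation in isolation.

make_mutations <- function(n = 3, scaffold = "scf01", spacing = 1000L,
                           ref = "C", alt = "T") {
  pos <- seq_len(n) * spacing
  df <- data.frame(id = paste0(scaffold, "_", pos), scaffold = scaffold,
                   pos = pos, ref = ref, alt = alt, stringsAsFactors = FALSE)
  class(df) <- c("mutation_set", "data.frame")
  df
}

# population from an explicit dosage matrix (individuals x SNPs, 0/1/2)
make_population <- function(dosage, mutations, causal = mutations$id[1],
                            inheritance = "recessive") {
  dosage <- as.matrix(dosage)
  colnames(dosage) <- mutations$id
  design <- cross_design(causal, inheritance = inheritance,
                         n_progeny = nrow(dosage))
  structure(
    list(id = sprintf("F2_%03d", seq_len(nrow(dosage))),
         genotypes = dosage,
         phenotype = ifelse(
           if (inheritance == "recessive") dosage[, causal] == 2
           else dosage[, causal] >= 1,
           "mutant", "wild_type"),
         design = design, mutations = mutations),
    class = "f2_population")
}

make_counts <- function(mutations, ref_fwd, ref_rev, alt_fwd, alt_rev) {
  df <- data.frame(snp_id = mutations$id, ref_fwd = ref_fwd, ref_rev = ref_rev,
                   alt_fwd = alt_fwd, alt_rev = alt_rev,
                   stringsAsFactors = FALSE)
  class(df) <- c("pooled_read_counts", "data.frame")
  df
}

# genome where the first SNP sits at `origin` bp and further SNPs sit at
# genetic distances giving the requested recombination fractions (Haldane
# inverse d = -log(1 - 2 r) / 2); r = 0.5 goes on a second scaffold
genome_for_r <- function(r_values, recomb_rate = 1) {
  stopifnot(all(r_values >= 0 & r_values <= 0.5))
  linked <- r_values[r_values < 0.5]
  d <- -log(1 - 2 * linked) / 2                       # Morgans
  bp <- round(d * 1e6 * 100 / recomb_rate)            # back to physical bp
  origin <- 1L
  pos1 <- origin + bp
  len1 <- max(c(origin, pos1)) + 1000
  sc <- c(scfA = len1)
  if (any(r_values == 0.5)) sc <- c(sc, scfB = 1e6)
  g <- genome_model(sc, recomb_rate = recomb_rate)
  mut <- data.frame(
    scaffold = c("scfA", rep("scfA", length(linked)),
                 rep("scfB", sum(r_values == 0.5))),
    pos = c(origin, pos1, rep(5e5, sum(r_values == 0.5))),
    ref = "C", alt = "T", stringsAsFactors = FALSE)
  # keep duplicate-position markers apart (r = 0 markers coincide with causal)
  dup <- duplicated(paste(mut$scaffold, mut$pos))
  mut$pos[dup] <- mut$pos[dup] + seq_len(sum(dup))
  mut <- mut[order(match(mut$scaffold, names(sc)), mut$pos), , drop = FALSE]
  mut <- data.frame(id = paste0(mut$scaffold, "_", mut$pos), mut,
                    stringsAsFactors = FALSE)
  rownames(mut) <- NULL
  class(mut) <- c("mutation_set", "data.frame")
  list(genome = g, mutations = mut,
       causal = paste0("scfA_", origin))
}

# Monte-Carlo oracle for the expected marker-allele frequency in a pool:
# simulate two-locus gamete pairs directly (no shared code with the
# enumeration in expected_marker_index)
mc_marker_freq <- function(r, inheritance, pool, n = 2e5) {
  c1 <- rbinom(n, 1, 0.5)
  c2 <- rbinom(n, 1, 0.5)
  m1 <- ifelse(rbinom(n, 1, r) == 1, 1 - c1, c1)
  m2 <- ifelse(rbinom(n, 1, r) == 1, 1 - c2, c2)
  dosage <- c1 + c2
  mutant <- if (inheritance == "recessive") dosage == 2 else dosage >= 1
  keep <- if (pool == "mt") mutant else !mutant
  mean((m1 + m2)[keep]) / 2
}
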