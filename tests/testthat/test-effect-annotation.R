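BASES <- c("A", "C", "G", "T")

# independent translate-and-compare oracle built on Biostrings::translate
oracle_consequence <- function(ref_codon, alt_codon) {
  aa <- function(c) as.character(Biostrings::translate(
    Biostrings::DNAString(c), no.init.codon = TRUE))
  r <- aa(ref_codon); a <- aa(alt_codon)
  if (r == a) "synonymous"
  else if (a == "*") "stop_gained"
  else if (r == "*") "stop_lost"
  else "missense"
}

test_that("worked codon substitutions classify correctly on both strands", {
  # plus strand: CAA (Gln) -> TAA at codon 2 position 1: nonsense
  g <- gene_model("g1", "s", "+", data.frame(start = 1, end = 9))
  eff <- annotate_effect(list(scaffold = "s", pos = 4, ref = "C", alt = "T"),
                         g, "ATGCAAGGA")
  expect_identical(eff$consequence, "stop_gained")
  expect_identical(eff$ref_codon, "CAA")
  expect_identical(eff$alt_codon, "TAA")
  expect_equal(eff$codon_index, 2L)

  # minus strand: coding TGG whose third base is genomic C; C->T gives TGA
  # coding strand ATG TGG -> genomic revcomp CCACAT; SNP at genomic pos 1
  gm <- gene_model("g2", "s", "-", data.frame(start = 1, end = 6))
  eff2 <- annotate_effect(list(scaffold = "s", pos = 1, ref = "C", alt = "T"),
                          gm, "CCACAT")
  expect_identical(eff2$ref_codon, "TGG")
  expect_identical(eff2$alt_codon, "TGA")
  expect_identical(eff2$consequence, "stop_gained")

  # plus strand: CTG -> TTG, Leu -> Leu synonymous
  g3 <- gene_model("g3", "s", "+", data.frame(start = 1, end = 6))
  eff3 <- annotate_effect(list(scaffold = "s", pos = 4, ref = "C", alt = "T"),
                          g3, "ATGCTG")
  expect_identical(eff3$consequence, "synonymous")

  # G->A at a degenerate third position: synonymous (EMS-type change)
  g4 <- gene_model("g4", "s", "+", data.frame(start = 1, end = 6))
  eff4 <- annotate_effect(list(scaffold = "s", pos = 6, ref = "G", alt = "A"),
                          g4, "ATGCCG")  # CCG -> CCA, both Pro
  expect_identical(eff4$consequence, "synonymous")

  # outside the CDS
  g5 <- gene_model("g5", "s", "+", data.frame(start = c(1, 10), end = c(6, 15)))
  seq5 <- "ATGCCGTTTAAACCCTTT"
  intr <- annotate_effect(list(scaffold = "s", pos = 8, ref = "T", alt = "A"), g5, seq5)
  expect_identical(intr$consequence, "non_coding")
  expect_identical(intr$region, "intronic")
  inter <- annotate_effect(list(scaffold = "s", pos = 17, ref = "T", alt = "A"), g5, seq5)
  expect_identical(inter$region, "intergenic")

  # reference mismatch is an error
  expect_error(
    annotate_effect(list(scaffold = "s", pos = 4, ref = "G", alt = "A"), g3, "ATGCTG"),
    "reference mismatch")
})

test_that("all 576 codon x substitution cases match the brute-force oracle", {
  codons <- apply(expand.grid(BASES, BASES, BASES), 1, paste, collapse = "")
  for (codon in codons) {
    for (p in 1:3) {
      ref <- substr(codon, p, p)
      for (alt in setdiff(BASES, ref)) {
        alt_codon <- codon
        substr(alt_codon, p, p) <- alt
        want <- oracle_consequence(codon, alt_codon)

        # plus strand: the codon is the whole CDS
        gp <- gene_model("p", "s", "+", data.frame(start = 1, end = 3))
        got_p <- annotate_effect(list(scaffold = "s", pos = p, ref = ref, alt = alt),
                                 gp, codon)
        expect_identical(got_p$consequence, want)
        expect_identical(got_p$alt_codon, alt_codon)

        # minus strand: same coding change seen from the other genomic strand
        gm <- gene_model("m", "s", "-", data.frame(start = 1, end = 3))
        rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(codon)))
        comp <- function(b) chartr("ACGT", "TGCA", b)
        got_m <- annotate_effect(
          list(scaffold = "s", pos = 4 - p, ref = comp(ref), alt = comp(alt)),
          gm, rc)
        expect_identical(got_m$consequence, want)
        expect_identical(got_m$ref_codon, codon)
        expect_identical(got_m$alt_codon, alt_codon)
      }
    }
  }
})

test_that("multi-exon minus-strand genes use transcription-order numbering", {
  # coding sequence ATG CAA GGA TAA split over two exons, minus strand:
  # genomic layout has exon 1 (transcription order) at the right
  cds <- "ATGCAAGGATAA"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  # genomic: positions 1..6 = revcomp of last 6 coding bases,
  #          positions 11..16 = revcomp of first 6 coding bases
  seq <- paste0(substr(rc, 1, 6), "GGGG", substr(rc, 7, 12))
  g <- gene_model("g", "s", "-",
                  data.frame(start = c(11, 1), end = c(16, 6)))
  # coding C at codon 2 position 1 (the C of CAA) = genomic G at pos 13
  expect_identical(substr(seq, 13, 13), "G")
  eff <- annotate_effect(list(scaffold = "s", pos = 13, ref = "G", alt = "A"),
                         g, seq)
  expect_identical(eff$ref_codon, "CAA")
  expect_identical(eff$alt_codon, "TAA")
  expect_identical(eff$consequence, "stop_gained")
  expect_equal(eff$exon, 1L)   # first exon in transcription order
  expect_equal(eff$codon_index, 2L)
})

test_that("gene models read from GFF3 annotate like hand-built ones", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  fa_seq <- c(s1 = "ATGCAAGGATAA")
  writeLines(c(
    "##gff-version 3",
    "s1\ttest\tgene\t1\t12\t.\t+\t.\tID=gene1",
    "s1\ttest\tmRNA\t1\t12\t.\t+\t.\tID=mrna1;Parent=gene1",
    "s1\ttest\tCDS\t1\t12\t.\t+\t0\tID=cds1;Parent=mrna1"), gff)
  models <- read_gene_models(gff)
  expect_length(models, 1L)
  eff <- annotate_effect(list(scaffold = "s1", pos = 4, ref = "C", alt = "T"),
                         models[[1]], fa_seq)
  expect_identical(eff$consequence, "stop_gained")

  # FASTA reference through Biostrings works the same way
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">s1", fa_seq), fa)
  ref <- Biostrings::readDNAStringSet(fa)
  names(ref) <- sub(" .*", "", names(ref))
  eff2 <- annotate_effect(list(scaffold = "s1", pos = 4, ref = "C", alt = "T"),
                          models[[1]], ref)
  expect_identical(eff2$consequence, eff$consequence)
})
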