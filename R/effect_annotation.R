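#' Strand-aware gene model for effect annotation
#'
#' A protein-coding gene as an ordered set of CDS exons on one scaffold.
#' Exons are 1-based closed genomic intervals listed in transcription order
#' (descending genomic coordinates for minus-strand genes); the reading
#' frame is anchored at the CDS start.
#'
#' @param gene_id gene/transcript identifier.
#' @param scaffold scaffold name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with columns `start`, `end` (genomic, closed),
#'   in transcription order.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, scaffold, strand, exons) {
  strand <- match.arg(strand, c("+", "-"))
  stopifnot(is.data.frame(exons), all(c("start", "end") %in% names(exons)),
            nrow(exons) >= 1L, all(exons$start <= exons$end))
  ord <- order(exons$start)
  starts <- exons$start[ord]
  ends <- exons$end[ord]
  if (any(starts[-1L] <= ends[-length(ends)]))
    stop("CDS exons overlap")
  expected <- if (strand == "+") order(exons$start) else order(-exons$start)
  if (!identical(expected, seq_len(nrow(exons))))
    stop("exons must be listed in transcription order for strand ", strand)
  cds_len <- sum(exons$end - exons$start + 1L)
  if (cds_len %% 3L != 0L)
    warning("CDS length of ", gene_id, " (", cds_len, ") is not divisible by 3")
  structure(list(gene_id = gene_id, scaffold = scaffold, strand = strand,
                 exons = exons[, c("start", "end")]),
            class = "gene_model")
}

#' Read gene models from GFF3
#'
#' Imports a GFF3 file and builds one [gene_model()] per transcript from
#' its CDS features (all other feature types are ignored), grouped by the
#' `Parent` attribute (falling back to `ID`).
#'
#' @param path GFF3 file.
#' @return Named list of `gene_model` objects.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == "CDS"]
  if (length(gr) == 0L) stop("no CDS features in ", path)
  parent <- as.character(S4Vectors::mcols(gr)$Parent)
  if (is.null(parent) || all(!nzchar(parent)) || anyNA(parent))
    parent <- as.character(S4Vectors::mcols(gr)$ID)
  groups <- split(seq_along(gr), parent)
  models <- lapply(names(groups), function(g) {
    i <- groups[[g]]
    strand <- as.character(BiocGenerics::strand(gr[i]))[1L]
    ex <- data.frame(start = BiocGenerics::start(gr[i]),
                     end = BiocGenerics::end(gr[i]))
    ex <- ex[order(if (strand == "+") ex$start else -ex$start), , drop = FALSE]
    gene_model(g, as.character(GenomeInfoDb::seqnames(gr[i]))[1L], strand, ex)
  })
  setNames(models, names(groups))
}

.complement <- function(x) chartr("ACGTacgt", "TGCAtgca", x)
.revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
.translate_codon <- function(codon) unname(Biostrings::GENETIC_CODE[codon])

# scaffold sequence as a plain character string
.scaffold_seq <- function(sequence, scaffold) {
  if (is.character(sequence) && length(sequence) == 1L && is.null(names(sequence)))
    return(sequence)
  if (is.character(sequence)) {
    if (!scaffold %in% names(sequence)) stop("no sequence for ", scaffold)
    return(sequence[[scaffold]])
  }
  if (methods::is(sequence, "DNAString")) return(as.character(sequence))
  if (methods::is(sequence, "DNAStringSet")) {
    if (!scaffold %in% names(sequence)) stop("no sequence for ", scaffold)
    return(as.character(sequence[[scaffold]]))
  }
  stop("unsupported sequence container")
}

#' Classify the coding consequence of a SNP
#'
#' Locates a SNP within a gene's CDS (transcription order), substitutes the
#' alternative allele into its codon — complementing the alleles first for
#' minus-strand genes — translates reference and alternative codons under
#' the standard genetic code, and classifies the change as synonymous,
#' missense, stop_gained or stop_lost. A SNP outside every CDS exon is
#' non_coding (intronic if inside the gene span, intergenic otherwise).
#'
#' @param snp list or one-row data.frame with `scaffold`, `pos`, `ref`,
#'   `alt` (plus-strand genomic alleles).
#' @param gene a [gene_model()].
#' @param sequence reference sequence of the scaffold: a character string,
#'   named character vector, `DNAString`, or named `DNAStringSet`.
#' @return A `snp_effect` list: `snp_id`, `gene_id`, `region`, `exon`
#'   (transcription-order index or NA), `codon_index`, `ref_codon`,
#'   `alt_codon`, `ref_aa`, `alt_aa`, `consequence`.
#' @examples
#' g <- gene_model("toy", "scf", "+", data.frame(start = 1, end = 9))
#' annotate_effect(list(scaffold = "scf", pos = 4, ref = "C", alt = "T"),
#'                 g, "ATGCAAGGA")  # CAA (Gln) -> TAA: stop_gained
#' @export
annotate_effect <- function(snp, gene, sequence) {
  stopifnot(inherits(gene, "gene_model"))
  snp <- as.list(snp)
  pos <- as.integer(snp$pos)
  out <- list(snp_id = if (!is.null(snp$id)) snp$id else
                paste0(snp$scaffold, "_", pos),
              gene_id = gene$gene_id, region = NA_character_,
              exon = NA_integer_, codon_index = NA_integer_,
              ref_codon = NA_character_, alt_codon = NA_character_,
              ref_aa = NA_character_, alt_aa = NA_character_,
              consequence = NA_character_)
  class(out) <- "snp_effect"

  if (snp$scaffold != gene$scaffold) {
    out$region <- "intergenic"; out$consequence <- "non_coding"; return(out)
  }
  ex <- gene$exons
  hit <- which(pos >= ex$start & pos <= ex$end)
  if (length(hit) == 0L) {
    span <- range(c(ex$start, ex$end))
    out$region <- if (pos >= span[1L] && pos <= span[2L]) "intronic" else "intergenic"
    out$consequence <- "non_coding"
    return(out)
  }

  seq <- toupper(.scaffold_seq(sequence, gene$scaffold))
  genomic_ref <- substr(seq, pos, pos)
  if (genomic_ref != toupper(snp$ref))
    stop("reference mismatch at ", gene$scaffold, ":", pos,
         ": sequence has ", genomic_ref, ", SNP claims ", snp$ref)

  # CDS coordinate of the SNP, in transcription order
  exon_lens <- ex$end - ex$start + 1L
  before <- if (hit > 1L) sum(exon_lens[seq_len(hit - 1L)]) else 0L
  offset <- if (gene$strand == "+") pos - ex$start[hit] + 1L else ex$end[hit] - pos + 1L
  cds_pos <- before + offset

  # CDS sequence in transcription order
  pieces <- substring(seq, ex$start, ex$end)
  if (gene$strand == "-") pieces <- vapply(pieces, .revcomp, character(1L))
  cds <- paste(pieces, collapse = "")

  codon_idx <- (cds_pos - 1L) %/% 3L + 1L
  pos_in_codon <- (cds_pos - 1L) %% 3L + 1L
  if (codon_idx * 3L > nchar(cds)) {
    warning("SNP falls in an incomplete trailing codon of ", gene$gene_id)
    out$region <- "exonic"; out$consequence <- "non_coding"; return(out)
  }
  ref_codon <- substr(cds, (codon_idx - 1L) * 3L + 1L, codon_idx * 3L)
  coding_alt <- if (gene$strand == "+") toupper(snp$alt) else .complement(toupper(snp$alt))
  alt_codon <- ref_codon
  substr(alt_codon, pos_in_codon, pos_in_codon) <- coding_alt

  ref_aa <- .translate_codon(ref_codon)
  alt_aa <- .translate_codon(alt_codon)
  out$region <- "exonic"
  out$exon <- hit
  out$codon_index <- codon_idx
  out$ref_codon <- ref_codon; out$alt_codon <- alt_codon
  out$ref_aa <- ref_aa; out$alt_aa <- alt_aa
  out$consequence <- if (ref_aa == alt_aa) "synonymous"
    else if (alt_aa == "*") "stop_gained"
    else if (ref_aa == "*") "stop_lost"
    else "missense"
  out
}

#' @export
print.snp_effect <- function(x, ...) {
  if (x$consequence == "non_coding") {
    cat(sprintf("%s in %s: %s (%s)\n", x$snp_id, x$gene_id, x$consequence, x$region))
  } else {
    cat(sprintf("%s in %s (exon %d, codon %d): %s->%s (%s->%s) %s\n",
                x$snp_id, x$gene_id, x$exon, x$codon_index,
                x$ref_codon, x$alt_codon, x$ref_aa, x$alt_aa, x$consequence))
  }
  invisible(x)
}
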