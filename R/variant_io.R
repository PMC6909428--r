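#' Assemble pooled variants from mutation set and per-pool counts
#'
#' Joins a `mutation_set` with the MT- and WT-pool read counts into the
#' `pooled_variants` table the index and screening steps consume.
#'
#' @param mutations a `mutation_set`.
#' @param counts_mt,counts_wt `pooled_read_counts` for the MT and WT pools
#'   (rows matched to `mutations$id`).
#' @return A `pooled_variants` data.frame: `snp_id`, `scaffold`, `pos`,
#'   `ref`, `alt`, then the eight stranded counts `mt_ref_fwd` ...
#'   `wt_alt_rev`.
#' @export
assemble_pooled_variants <- function(mutations, counts_mt, counts_wt) {
  stopifnot(is.data.frame(mutations), is.data.frame(counts_mt),
            is.data.frame(counts_wt))
  i_mt <- match(mutations$id, counts_mt$snp_id)
  i_wt <- match(mutations$id, counts_wt$snp_id)
  if (anyNA(i_mt) || anyNA(i_wt))
    stop("read counts missing for some SNPs in the mutation set")
  out <- data.frame(
    snp_id = mutations$id, scaffold = mutations$scaffold, pos = mutations$pos,
    ref = mutations$ref, alt = mutations$alt,
    mt_ref_fwd = counts_mt$ref_fwd[i_mt], mt_ref_rev = counts_mt$ref_rev[i_mt],
    mt_alt_fwd = counts_mt$alt_fwd[i_mt], mt_alt_rev = counts_mt$alt_rev[i_mt],
    wt_ref_fwd = counts_wt$ref_fwd[i_wt], wt_ref_rev = counts_wt$ref_rev[i_wt],
    wt_alt_fwd = counts_wt$alt_fwd[i_wt], wt_alt_rev = counts_wt$alt_rev[i_wt],
    stringsAsFactors = FALSE)
  class(out) <- c("pooled_variants", "data.frame")
  out
}

.dp4_string <- function(x, prefix) {
  paste(x[[paste0(prefix, "_ref_fwd")]], x[[paste0(prefix, "_ref_rev")]],
        x[[paste0(prefix, "_alt_fwd")]], x[[paste0(prefix, "_alt_rev")]],
        sep = ",")
}

#' Write pooled variants as VCF 4.2
#'
#' Two dialects are supported. `"format"` (default) writes one file with two
#' samples, `MT` and `WT`, carrying a 4-integer stranded-count `DP4` FORMAT
#' field (ref-fwd, ref-rev, alt-fwd, alt-rev). `"info"` writes one
#' single-pool file per path with a bcftools-style `INFO/DP4` key; `path`
#' must then name two files, MT first.
#'
#' @param x a `pooled_variants` data.frame.
#' @param path output file (length 1 for `"format"`, length 2 for
#'   `"info"`: MT file then WT file).
#' @param dialect `"format"` or `"info"`.
#' @param extra_header character vector of extra `##` header lines (e.g. a
#'   config hash).
#' @return Invisibly, `path`.
#' @export
write_pooled_vcf <- function(x, path, dialect = c("format", "info"),
                             extra_header = character()) {
  dialect <- match.arg(dialect)
  stopifnot(is.data.frame(x))
  contigs <- paste0("##contig=<ID=", unique(x$scaffold), ">")
  fixed <- function() cbind(x$scaffold, x$pos, x$snp_id, x$ref, x$alt, ".", "PASS")
  if (dialect == "format") {
    stopifnot(length(path) == 1L)
    hdr <- c("##fileformat=VCFv4.2",
             paste0("##FORMAT=<ID=DP4,Number=4,Type=Integer,Description=",
                    "\"Stranded read counts: ref-fwd,ref-rev,alt-fwd,alt-rev\">"),
             contigs, extra_header,
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "MT", "WT"), collapse = "\t"))
    body <- apply(cbind(fixed(), ".", "DP4",
                        .dp4_string(x, "mt"), .dp4_string(x, "wt")),
                  1L, paste, collapse = "\t")
    writeLines(c(hdr, if (nrow(x)) body), path)
  } else {
    stopifnot(length(path) == 2L)
    for (k in 1:2) {
      prefix <- c("mt", "wt")[k]
      hdr <- c("##fileformat=VCFv4.2",
               paste0("##INFO=<ID=DP4,Number=4,Type=Integer,Description=",
                      "\"Stranded read counts: ref-fwd,ref-rev,alt-fwd,alt-rev\">"),
               contigs, extra_header,
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO"), collapse = "\t"))
      body <- apply(cbind(fixed(), paste0("DP4=", .dp4_string(x, prefix))),
                    1L, paste, collapse = "\t")
      writeLines(c(hdr, if (nrow(x)) body), path[k])
    }
  }
  invisible(path)
}

.parse_dp4 <- function(s, where) {
  if (is.na(s) || !nzchar(s))
    stop("record ", where, " has no DP4 stranded-count field")
  v <- suppressWarnings(as.integer(strsplit(s, ",", fixed = TRUE)[[1L]]))
  if (length(v) != 4L || anyNA(v))
    stop("record ", where, " has a malformed DP4 field: '", s, "'")
  v
}

# read one VCF with vcfR; returns list(fix = matrix, vcf = vcfR object)
.read_vcf_fix <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix)))  # single-record files come back as a bare vector
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  list(vcf = vcf, fix = fix)
}

# drop multiallelic records and indels, warning per stated policy
.filter_biallelic_snps <- function(fix) {
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  indel <- nchar(fix[, "REF"]) != 1L | (nchar(fix[, "ALT"]) != 1L & !multi)
  if (any(multi))
    warning(sum(multi), " multiallelic record(s) skipped")
  if (any(indel))
    warning(sum(indel), " indel record(s) skipped")
  which(!multi & !indel)
}

#' Read pooled variants from VCF
#'
#' Inverse of [write_pooled_vcf()]. Multiallelic records and indels are
#' skipped with a warning; a biallelic SNP record lacking the DP4 field is
#' an error naming the record.
#'
#' @param path VCF path(s): length 1 for the `"format"` dialect, length 2
#'   (MT file, WT file) for `"info"`.
#' @param dialect `"format"` or `"info"`.
#' @return A `pooled_variants` data.frame.
#' @export
read_pooled_vcf <- function(path, dialect = c("format", "info")) {
  dialect <- match.arg(dialect)
  if (dialect == "format") {
    stopifnot(length(path) == 1L)
    x <- .read_vcf_fix(path)
    keep <- .filter_biallelic_snps(x$fix)
    gt <- x$vcf@gt
    samples <- colnames(gt)[-1L]
    cols <- if (all(c("MT", "WT") %in% samples)) c("MT", "WT") else samples[1:2]
    dp4 <- vcfR::extract.gt(x$vcf, element = "DP4")
    rows <- lapply(keep, function(i) {
      where <- paste0(x$fix[i, "CHROM"], ":", x$fix[i, "POS"])
      c(.parse_dp4(dp4[i, cols[1L]], where), .parse_dp4(dp4[i, cols[2L]], where))
    })
    counts <- do.call(rbind, rows)
    fix <- x$fix[keep, , drop = FALSE]
  } else {
    stopifnot(length(path) == 2L)
    parts <- lapply(path, function(p) {
      x <- .read_vcf_fix(p)
      keep <- .filter_biallelic_snps(x$fix)
      info <- vcfR::extract.info(x$vcf, element = "DP4")
      fix <- x$fix[keep, , drop = FALSE]
      dp4 <- t(vapply(seq_along(keep), function(j) {
        i <- keep[j]
        .parse_dp4(info[i], paste0(x$fix[i, "CHROM"], ":", x$fix[i, "POS"]))
      }, integer(4L)))
      list(fix = fix, dp4 = dp4,
           key = paste(fix[, "CHROM"], fix[, "POS"], fix[, "REF"], fix[, "ALT"]))
    })
    common <- intersect(parts[[1L]]$key, parts[[2L]]$key)
    dropped <- (length(parts[[1L]]$key) - length(common)) +
      (length(parts[[2L]]$key) - length(common))
    if (dropped > 0L)
      warning(dropped, " record(s) present in only one pool file dropped")
    i1 <- match(common, parts[[1L]]$key)
    i2 <- match(common, parts[[2L]]$key)
    fix <- parts[[1L]]$fix[i1, , drop = FALSE]
    counts <- cbind(parts[[1L]]$dp4[i1, , drop = FALSE],
                    parts[[2L]]$dp4[i2, , drop = FALSE])
  }
  if (is.null(counts)) counts <- matrix(integer(0), 0L, 8L)
  id <- fix[, "ID"]
  id[is.na(id) | id == "."] <- paste0(fix[, "CHROM"], "_", fix[, "POS"])[is.na(id) | id == "."]
  out <- data.frame(
    snp_id = id, scaffold = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"],
    mt_ref_fwd = counts[, 1L], mt_ref_rev = counts[, 2L],
    mt_alt_fwd = counts[, 3L], mt_alt_rev = counts[, 4L],
    wt_ref_fwd = counts[, 5L], wt_ref_rev = counts[, 6L],
    wt_alt_fwd = counts[, 7L], wt_alt_rev = counts[, 8L],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("pooled_variants", "data.frame")
  out
}

.gt_codes <- c("AA", "Aa", "aa")

#' Construct and validate a genotype table
#'
#' The per-individual genotype table used for fine-mapping: one row per F2
#' (or appended F3-derived) individual with its phenotype and its call at
#' each candidate SNP. Codes are `AA`, `Aa`, `aa` (`A` = reference allele),
#' with `NA`/`./.` for missing.
#'
#' @param df data.frame with columns `id`, `phenotype` and one column per
#'   candidate SNP.
#' @return A `genotype_table` data.frame.
#' @export
genotype_table <- function(df) {
  stopifnot(is.data.frame(df))
  if (!all(c("id", "phenotype") %in% names(df)))
    stop("genotype table needs 'id' and 'phenotype' columns")
  loci <- setdiff(names(df), c("id", "phenotype"))
  if (length(loci) == 0L) stop("genotype table needs at least one candidate SNP column")
  if (anyDuplicated(df$id)) stop("duplicate individual id(s): ",
                                 paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  if (!all(df$phenotype %in% c("mutant", "wild_type")))
    stop("phenotype must be 'mutant' or 'wild_type'")
  for (l in loci) {
    v <- as.character(df[[l]])
    v[v %in% c("./.", "NA", "")] <- NA_character_
    bad <- !is.na(v) & !v %in% .gt_codes
    if (any(bad)) stop("invalid genotype code(s) at ", l, ": ",
                       paste(unique(v[bad]), collapse = ", "))
    df[[l]] <- v
  }
  class(df) <- c("genotype_table", "data.frame")
  df
}

#' Read / write a genotype table (TSV)
#'
#' Tab-separated with a header (`id`, `phenotype`, one column per SNP);
#' lines starting `#` are comments. Missing calls may be written `./.` or
#' `NA`.
#'
#' @param path file path.
#' @return [read_genotype_table()] returns a validated `genotype_table`.
#' @export
read_genotype_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   colClasses = "character", check.names = FALSE,
                   na.strings = c("NA", "./."))
  genotype_table(df)
}

#' @rdname read_genotype_table
#' @param tab a `genotype_table`.
#' @param extra_header character vector of `#`-prefixed comment lines to
#'   prepend (e.g. a config hash).
#' @export
write_genotype_table <- function(tab, path, extra_header = character()) {
  stopifnot(is.data.frame(tab))
  con <- file(path, open = "w")
  on.exit(close(con))
  if (length(extra_header)) writeLines(extra_header, con)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "./.")
  invisible(path)
}

# write a generic TSV report with comment header lines
.write_tsv <- function(df, path, extra_header = character()) {
  con <- file(path, open = "w")
  on.exit(close(con))
  if (length(extra_header)) writeLines(extra_header, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}
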