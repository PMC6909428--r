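#' Build a pipeline run configuration
#'
#' Collects every stage parameter of the simulate -> index -> screen ->
#' fine-map pipeline plus a master seed. Stage seeds are split
#' deterministically from the master seed, so a stored config reproduces a
#' run bit-identically.
#'
#' @param scaffolds named numeric vector of scaffold lengths (bp). Default:
#'   five 2-Mb scaffolds.
#' @param recomb_rate recombination rate, cM/Mb.
#' @param density EMS mutations per Mb.
#' @param spectrum fraction of G:C-to-A:T transitions.
#' @param inheritance `"recessive"` or `"dominant"`.
#' @param n_progeny number of F2 individuals.
#' @param causal_snp SNP id, or `"auto"` to pick one simulated mutation at
#'   random.
#' @param depth mean pooled read depth per site per pool.
#' @param error_rate per-base sequencing error probability.
#' @param min_depth,wt_center,wt_halfwidth,mt_epsilon screen parameters,
#'   see [screen_criterion()].
#' @param seed master seed (integer).
#' @param out_dir output directory (created if needed).
#' @return A `run_config` list.
#' @export
run_config <- function(scaffolds = c(scf01 = 2e6, scf02 = 2e6, scf03 = 2e6,
                                     scf04 = 2e6, scf05 = 2e6),
                       recomb_rate = 3, density = 50, spectrum = 1,
                       inheritance = "recessive", n_progeny = 280,
                       causal_snp = "auto", depth = 50, error_rate = 0,
                       min_depth = 10, wt_center = 0.3, wt_halfwidth = 0.1,
                       mt_epsilon = 0, seed = 1,
                       out_dir = tempfile("mutmapr_run_")) {
  structure(
    list(scaffolds = as.list(scaffolds), recomb_rate = recomb_rate,
         density = density, spectrum = spectrum, inheritance = inheritance,
         n_progeny = n_progeny, causal_snp = causal_snp, depth = depth,
         error_rate = error_rate, min_depth = min_depth, wt_center = wt_center,
         wt_halfwidth = wt_halfwidth, mt_epsilon = mt_epsilon,
         seed = as.integer(seed), out_dir = out_dir),
    class = "run_config")
}

#' Read / write a run configuration (YAML)
#'
#' @param path YAML file.
#' @return [read_run_config()] returns a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  defaults <- run_config()
  known <- names(defaults)
  unknown <- setdiff(names(y), known)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  args <- utils::modifyList(defaults[setdiff(known, "scaffolds")], y[names(y) != "scaffolds"])
  if (!is.null(y$scaffolds)) args$scaffolds <- unlist(y$scaffolds)
  do.call(run_config, args)
}

#' @rdname read_run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# md5 of the canonical YAML serialisation of the scientific parameters
# (out_dir identifies where files land, not what was computed, so it is
# excluded: the same analysis hashes the same wherever it is written)
.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config)[setdiff(names(config), "out_dir")], tmp)
  unname(md5sum(tmp))
}

# run expr, prefixing any error with the pipeline stage name
.with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("[", stage, "] ", conditionMessage(e), call. = FALSE))
}

#' Run the full bulked-segregant pipeline on simulated data
#'
#' Executes simulate -> pool -> sequence -> SNP-index -> screen ->
#' segregation test -> fine-map as one seeded, reproducible run. Writes a
#' two-sample DP4 VCF, a truth table (TSV with each SNP's recombination
#' fraction to the causal locus), the screened candidates, the
#' per-individual genotype table at candidate loci, and the fine-mapping
#' consistency report; every output file carries the config md5 in a
#' comment/header line.
#'
#' @param config a [run_config()] (or path to a YAML config).
#' @return A `run_report` list with realised counts, the segregation test,
#'   candidate and fine-mapping tables, whether the causal SNP was
#'   recovered, and the output paths.
#' @export
run_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  hash <- .config_hash(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  vcf_hdr <- paste0("##config_md5=", hash)
  tsv_hdr <- paste0("# config_md5=", hash)

  set.seed(config$seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1L, 5L)

  genome <- .with_stage("genome", genome_model(unlist(config$scaffolds),
                                               recomb_rate = config$recomb_rate))
  mutations <- .with_stage("mutations",
    simulate_ems_mutations(genome, config$density, config$spectrum,
                           seed = stage_seeds[1L]))
  if (nrow(mutations) == 0L) stop("[mutations] no mutations simulated")

  causal <- config$causal_snp
  if (identical(causal, "auto")) {
    set.seed(stage_seeds[2L])
    causal <- mutations$id[sample.int(nrow(mutations), 1L)]
  }
  design <- .with_stage("design",
    cross_design(causal, inheritance = config$inheritance,
                 n_progeny = config$n_progeny))

  population <- .with_stage("population", {
    if (config$n_progeny <= 0L) stop("n_progeny must be positive for a pipeline run")
    simulate_f2_population(design, mutations, genome, seed = stage_seeds[3L])
  })
  pools <- .with_stage("pooling", pool_individuals(population, design))

  counts_mt <- .with_stage("sequencing",
    simulate_pooled_reads(pools$mt, mutations, config$depth, config$error_rate,
                          seed = stage_seeds[4L]))
  counts_wt <- .with_stage("sequencing",
    simulate_pooled_reads(pools$wt, mutations, config$depth, config$error_rate,
                          seed = stage_seeds[5L]))
  variants <- assemble_pooled_variants(mutations, counts_mt, counts_wt)

  paths <- list(
    config = file.path(config$out_dir, "config.yaml"),
    vcf = file.path(config$out_dir, "variants.vcf"),
    truth = file.path(config$out_dir, "truth.tsv"),
    candidates = file.path(config$out_dir, "candidates.tsv"),
    genotypes = file.path(config$out_dir, "genotypes.tsv"),
    consistency = file.path(config$out_dir, "consistency.tsv"),
    report = file.path(config$out_dir, "report.yaml"))

  write_run_config(config, paths$config)
  write_pooled_vcf(variants, paths$vcf, dialect = "format", extra_header = vcf_hdr)
  truth <- data.frame(
    snp_id = mutations$id, scaffold = mutations$scaffold, pos = mutations$pos,
    ref = mutations$ref, alt = mutations$alt,
    is_causal = mutations$id == causal,
    r_to_causal = recomb_fraction_to(mutations, genome, causal),
    stringsAsFactors = FALSE)
  .write_tsv(truth, paths$truth, tsv_hdr)

  indexed <- .with_stage("snp-index", compute_indices(variants))
  criterion <- screen_criterion(wt_center = config$wt_center,
                                wt_halfwidth = config$wt_halfwidth,
                                min_depth = config$min_depth,
                                mt_epsilon = config$mt_epsilon)
  candidates <- .with_stage("screen", screen_candidates(indexed, criterion))
  .write_tsv(candidates, paths$candidates, tsv_hdr)

  n_mt <- length(pools$mt$id)
  n_wt <- length(pools$wt$id)
  seg <- .with_stage("segregation", {
    ratio <- if (config$inheritance == "recessive") c(3, 1) else c(1, 3)
    chisq_segregation(c(n_wt, n_mt), ratio)
  })

  consistency <- NULL
  if (nrow(candidates) > 0L) {
    gt <- .with_stage("genotyping",
      genotype_table_from_population(population, candidates$snp_id))
    write_genotype_table(gt, paths$genotypes, tsv_hdr)
    consistency <- .with_stage("fine-mapping",
      exclude_candidates(gt, config$inheritance))
    .write_tsv(consistency, paths$consistency, tsv_hdr)
  }

  linked <- if (is.null(consistency)) character(0) else
    consistency$locus[consistency$status == "completely_linked"]
  report <- structure(
    list(config_hash = hash, causal_snp = causal,
         n_snps = nrow(mutations), n_mt = n_mt, n_wt = n_wt,
         segregation = seg, n_candidates = nrow(candidates),
         causal_retained = causal %in% candidates$snp_id,
         completely_linked = linked,
         causal_uniquely_linked = identical(linked, causal),
         candidates = candidates, consistency = consistency,
         paths = paths, config = config),
    class = "run_report")
  yaml::write_yaml(list(config_md5 = hash, causal_snp = causal,
                        n_snps = report$n_snps, pool_mt = n_mt, pool_wt = n_wt,
                        segregation_p = seg$p_value,
                        n_candidates = report$n_candidates,
                        causal_retained = report$causal_retained,
                        completely_linked = as.list(linked)),
                   paths$report)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Bulked-segregant pipeline run (config md5 ", x$config_hash, ")\n", sep = "")
  cat(sprintf("  %d SNPs simulated; pools: %d mutant / %d wild type\n",
              x$n_snps, x$n_mt, x$n_wt))
  cat(sprintf("  segregation vs %s ratio: p = %.3g\n",
              paste(x$segregation$ratio, collapse = ":"), x$segregation$p_value))
  cat(sprintf("  %d candidate(s) passed the dual-pool screen; causal %s retained\n",
              x$n_candidates, if (x$causal_retained) "SNP" else "SNP NOT"))
  cat(sprintf("  completely linked after fine-mapping: %s\n",
              if (length(x$completely_linked))
                paste(x$completely_linked, collapse = ", ") else "(none)"))
  invisible(x)
}
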