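#' Describe a genome for simulation
#'
#' A minimal genome model for the cross simulator: a set of scaffolds with
#' physical lengths plus a constant recombination rate used to convert
#' physical distance to genetic distance under the Haldane map function
#' (crossovers form a Poisson process along each scaffold, no interference).
#'
#' @param scaffolds data.frame with columns `name` and `length` (bp), or a
#'   named numeric vector of scaffold lengths.
#' @param recomb_rate recombination rate in centimorgan per megabase.
#'   Default 3 cM/Mb, a typical genome-wide figure for a legume genome.
#' @param map_function mapping function; only `"haldane"` is supported.
#' @return An object of class `genome_model`.
#' @examples
#' genome_model(c(scf01 = 2e6, scf02 = 2e6))
#' @export
genome_model <- function(scaffolds, recomb_rate = 3, map_function = "haldane") {
  if (is.numeric(scaffolds)) {
    if (is.null(names(scaffolds)) || anyNA(names(scaffolds)))
      stop("scaffold lengths given as a vector must be named")
    scaffolds <- data.frame(name = names(scaffolds),
                            length = as.numeric(scaffolds),
                            stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(scaffolds), all(c("name", "length") %in% names(scaffolds)))
  if (nrow(scaffolds) == 0L) stop("genome must contain at least one scaffold")
  if (any(scaffolds$length <= 0)) stop("scaffold lengths must be positive")
  if (anyDuplicated(scaffolds$name)) stop("scaffold names must be unique")
  map_function <- match.arg(map_function, "haldane")
  if (!is.numeric(recomb_rate) || length(recomb_rate) != 1L || recomb_rate < 0)
    stop("recomb_rate must be a single non-negative number (cM/Mb)")
  structure(
    list(scaffolds = scaffolds[, c("name", "length")],
         recomb_rate = recomb_rate,
         map_function = map_function),
    class = "genome_model"
  )
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("Genome model: %d scaffold(s), %.3g Mb total, %.3g cM/Mb (%s)\n",
              nrow(x$scaffolds), sum(x$scaffolds$length) / 1e6,
              x$recomb_rate, x$map_function))
  invisible(x)
}

#' Haldane map: recombination fraction from genetic distance
#'
#' Converts a genetic distance in Morgans to a recombination fraction under
#' the Haldane (no-interference) map function, r = (1 - exp(-2d)) / 2.
#'
#' @param d genetic distance in Morgans (vectorised).
#' @return Recombination fraction(s) in \[0, 0.5).
#' @export
haldane_r <- function(d) {
  stopifnot(all(d >= 0))
  (1 - exp(-2 * d)) / 2
}

# genetic distance (Morgans) between physical coordinates on one scaffold
.genetic_dist <- function(bp, recomb_rate) abs(bp) / 1e6 * recomb_rate / 100

#' Simulate an EMS mutation set
#'
#' Draws SNPs over the genome at a given density with the EMS substitution
#' spectrum. The number of mutations per scaffold is Poisson with mean
#' `length * density / 1e6`; positions are uniform without replacement. With
#' probability `spectrum` a mutation is a G:C-to-A:T transition (ref C with
#' alt T, or ref G with alt A, equiprobably); otherwise one of the ten other
#' single-base substitutions is drawn uniformly, so the realised fraction of
#' G:C-to-A:T changes estimates `spectrum`.
#'
#' @param genome a [genome_model()].
#' @param density mutations per megabase.
#' @param spectrum fraction of mutations that are G:C-to-A:T transitions
#'   (default 1, i.e. a pure EMS spectrum).
#' @param seed optional integer seed; given the seed the output is
#'   deterministic.
#' @return A `mutation_set`: data.frame with columns `id`, `scaffold`, `pos`
#'   (1-based), `ref`, `alt`, sorted by scaffold then position.
#' @examples
#' g <- genome_model(c(scf01 = 1e6))
#' simulate_ems_mutations(g, density = 20, seed = 1)
#' @export
simulate_ems_mutations <- function(genome, density, spectrum = 1, seed = NULL) {
  stopifnot(inherits(genome, "genome_model"))
  if (!is.numeric(density) || density < 0) stop("density must be >= 0")
  if (!is.numeric(spectrum) || spectrum < 0 || spectrum > 1)
    stop("spectrum must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)

  sc <- genome$scaffolds
  out <- vector("list", nrow(sc))
  # the ten substitutions outside the EMS G:C->A:T spectrum
  non_ems <- expand.grid(ref = c("A", "C", "G", "T"), alt = c("A", "C", "G", "T"),
                         stringsAsFactors = FALSE)
  non_ems <- non_ems[non_ems$ref != non_ems$alt, ]
  non_ems <- non_ems[!(non_ems$ref == "C" & non_ems$alt == "T") &
                       !(non_ems$ref == "G" & non_ems$alt == "A"), ]

  for (i in seq_len(nrow(sc))) {
    n <- rpois(1L, sc$length[i] * density / 1e6)
    n <- min(n, sc$length[i])  # cannot place more SNPs than bases
    if (n == 0L) {
      out[[i]] <- data.frame(scaffold = character(0), pos = integer(0),
                             ref = character(0), alt = character(0),
                             stringsAsFactors = FALSE)
      next
    }
    pos <- sort(sample.int(sc$length[i], n, replace = FALSE))
    is_ems <- runif(n) < spectrum
    ref <- alt <- character(n)
    gc <- runif(n) < 0.5
    ref[is_ems] <- ifelse(gc[is_ems], "C", "G")
    alt[is_ems] <- ifelse(gc[is_ems], "T", "A")
    if (any(!is_ems)) {
      k <- sample.int(nrow(non_ems), sum(!is_ems), replace = TRUE)
      ref[!is_ems] <- non_ems$ref[k]
      alt[!is_ems] <- non_ems$alt[k]
    }
    out[[i]] <- data.frame(scaffold = sc$name[i], pos = pos, ref = ref, alt = alt,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(match(res$scaffold, sc$name), res$pos), , drop = FALSE]
  res <- data.frame(id = if (nrow(res)) paste0(res$scaffold, "_", res$pos) else character(0),
                    res, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  class(res) <- c("mutation_set", "data.frame")
  res
}

#' Recombination fraction of every SNP to a focal SNP
#'
#' Computes the expected recombination fraction between each mutation and a
#' focal (typically causal) SNP: the Haldane fraction of their genetic
#' distance on a shared scaffold, 0.5 across scaffolds (unlinked).
#'
#' @param mutations a `mutation_set`.
#' @param genome the [genome_model()] the mutations were drawn on.
#' @param focal_id the `id` of the focal SNP.
#' @return Numeric vector of recombination fractions, one per mutation.
#' @export
recomb_fraction_to <- function(mutations, genome, focal_id) {
  stopifnot(inherits(genome, "genome_model"))
  i <- match(focal_id, mutations$id)
  if (is.na(i)) stop("focal SNP '", focal_id, "' not found in mutation set")
  same <- mutations$scaffold == mutations$scaffold[i]
  r <- rep(0.5, nrow(mutations))
  d <- .genetic_dist(mutations$pos[same] - mutations$pos[i], genome$recomb_rate)
  r[same] <- haldane_r(d)
  r
}
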