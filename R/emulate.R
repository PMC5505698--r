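# Sequencing/genotyping emulation layers over a screen simulation:
# reduced-representation read counts, SNP-array genotypes, WGS-style call
# sets. All are idealized: tag loci are an independent Bernoulli site sample,
# array genotypes are read straight off the diplotypes, WGS genotypes are
# error-free calls (read-level noise lives in the RAD layer).

#' Emulate reduced-representation (2b-RAD-like) read counts
#'
#' Samples a shared site set by independent Bernoulli inclusion of every
#' genome position, then draws per-site read depths Poisson(`mean_depth`) and
#' alternate-read counts Binomial(depth, p) with p = error, 1/2, 1 - error
#' for genotypes 0/1/2.
#'
#' @param sim A `screen_sim`.
#' @param individuals Ids to sequence (default: all pedigree members).
#' @param rad_fraction,mean_depth,seq_error Override the values in the
#'   simulation config.
#' @param seed Integer seed (default derived from the config seed).
#' @return A tibble with columns `chrom`, `pos` and matrix-columns `ref`,
#'   `alt` (one column per individual) of read counts.
#' @export
emulate_rad <- function(sim, individuals = NULL,
                        rad_fraction = NULL, mean_depth = NULL,
                        seq_error = NULL, seed = NULL) {
  cfg <- sim$config
  rad_fraction <- rad_fraction %||% cfg$rad_fraction
  mean_depth <- mean_depth %||% cfg$mean_depth
  seq_error <- seq_error %||% cfg$seq_error
  seed <- seed %||% stage_seed(cfg$seed, "rad")
  individuals <- individuals %||% sim$pedigree$id
  stopifnot(rad_fraction > 0, rad_fraction <= 1, mean_depth > 0)
  genome <- sim$genome
  with_seed(seed, {
    sites <- purrr::map_dfr(seq_len(nrow(genome$chromosomes)), function(i) {
      len <- genome$chromosomes$length[i]
      k <- rbinom(1, len, rad_fraction)
      tibble(chrom = genome$chromosomes$name[i],
             pos = if (k > 0) sort(sample.int(len, k)) else integer())
    })
    ns <- nrow(sites)
    ni <- length(individuals)
    if (ns == 0) {
      return(tibble(chrom = character(), pos = integer(),
                    ref = matrix(integer(), 0, ni,
                                 dimnames = list(NULL, individuals)),
                    alt = matrix(integer(), 0, ni,
                                 dimnames = list(NULL, individuals))))
    }
    # genotypes at sampled sites: 0 except where a tracked sequence variant
    # falls inside the site set
    p <- matrix(seq_error, ns, ni, dimnames = list(NULL, individuals))
    vloci <- which(sim$loci$kind %in% c("enu", "polymorphism"))
    if (length(vloci)) {
      key_sites <- paste(sites$chrom, sites$pos)
      hit <- match(paste(sim$loci$chrom[vloci], sim$loci$pos[vloci]),
                   key_sites)
      keep <- which(!is.na(hit))
      for (k in keep) {
        j <- vloci[k]
        row <- hit[k]
        for (ii in seq_along(individuals)) {
          g <- sum(sim$haplo[[individuals[ii]]][, j])
          if (g == 1L) p[row, ii] <- 0.5
          else if (g == 2L) p[row, ii] <- 1 - seq_error
        }
      }
    }
    depth <- matrix(rpois(ns * ni, mean_depth), ns, ni)
    alt <- matrix(rbinom(ns * ni, as.vector(depth), as.vector(p)), ns, ni,
                  dimnames = list(NULL, individuals))
    ref <- depth - alt
    dimnames(ref) <- list(NULL, individuals)
    out <- sites
    out$ref <- ref
    out$alt <- alt
    out
  })
}

#' Emulate SNP-array genotypes
#'
#' Marker loci (placed at uniform spacing per chromosome when the simulation
#' was configured) are read directly from the diplotypes; entries are set
#' missing independently at `missing_rate`.
#'
#' @param sim A `screen_sim` configured with `array_marker_count > 0`.
#' @param individuals Ids to genotype (default: all pedigree members).
#' @param missing_rate Override the config missingness.
#' @param seed Integer seed.
#' @return A genotype tibble: `chrom`, `pos`, `marker_id`, `freq`
#'   (founder allele frequency) plus one integer column per individual with
#'   genotype codes 0/1/2 and `NA` for missing.
#' @export
emulate_snp_array <- function(sim, individuals = NULL, missing_rate = NULL,
                              seed = NULL) {
  cfg <- sim$config
  missing_rate <- missing_rate %||% cfg$array_missing_rate
  seed <- seed %||% stage_seed(cfg$seed, "array")
  individuals <- individuals %||% sim$pedigree$id
  mk <- which(sim$loci$kind == "marker")
  if (length(mk) == 0) {
    abort("no marker loci tracked (array_marker_count was 0)",
          class = "enuscreen_error")
  }
  with_seed(seed, {
    out <- sim$loci[mk, c("chrom", "pos", "freq")] |>
      mutate(marker_id = sprintf("M%04d", seq_along(mk)), .after = "pos")
    for (id in individuals) {
      g <- colSums(sim$haplo[[id]][, mk, drop = FALSE])
      miss <- runif(length(g)) < missing_rate
      g[miss] <- NA_integer_
      out[[id]] <- as.integer(g)
    }
    out
  })
}

#' Emulate WGS-style variant call sets
#'
#' Returns the genotypes of the requested individuals at every tracked
#' sequence variant (planted induced mutations plus shared background
#' polymorphisms), together with the known-polymorphism list (the simulated
#' dbSNP stand-in), which by construction contains only the background
#' polymorphisms and never a planted induced mutation.
#'
#' @param sim A `screen_sim`.
#' @param individuals Ids to "sequence".
#' @return A list with `calls` (tibble `chrom`, `pos`, `ref`, `alt`, `origin`
#'   plus one genotype column `gt_<id>` per individual, retaining rows where
#'   at least one requested individual carries the alternate allele) and
#'   `known_snps` (tibble of the background polymorphisms).
#' @export
emulate_wgs_calls <- function(sim, individuals) {
  stopifnot(all(individuals %in% sim$pedigree$id))
  vloci <- which(sim$loci$kind %in% c("enu", "polymorphism"))
  calls <- sim$loci[vloci, c("chrom", "pos", "ref", "alt", "kind")] |>
    rename(origin = "kind")
  for (id in individuals) {
    calls[[paste0("gt_", id)]] <-
      as.integer(colSums(sim$haplo[[id]][, vloci, drop = FALSE]))
  }
  gt_cols <- paste0("gt_", individuals)
  any_alt <- rowSums(as.matrix(calls[gt_cols])) > 0
  list(calls = calls[any_alt, ],
       known_snps = sim$loci[sim$loci$kind == "polymorphism",
                             c("chrom", "pos", "ref", "alt", "freq")])
}
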