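# Synthetic-data generator: ENU mutagenesis of founder gametes, meiosis with
# recombination (Haldane, no interference), the G0 -> G1 -> G2 -> backcross-G3
# breeding scheme, phenotype assignment, and emulation of reduced-
# representation (2b-RAD-like) read counts, SNP-array genotypes and WGS-style
# call sets.

#' ENU mutation spectrum
#'
#' Probabilities over the six strand-collapsed substitution classes. The
#' default is transition-biased: 71.2% of mass on the two transition classes
#' (G:C>A:T 0.45, A:T>G:C 0.262) and the four transversion classes equal at
#' 0.072 each. Only the aggregate transition fraction is a measured
#' calibration; the within-group split is a package default.
#'
#' @param class_probs Named numeric vector over
#'   `c("A:T>G:C","G:C>A:T","A:T>C:G","A:T>T:A","G:C>C:G","G:C>T:A")`,
#'   summing to 1.
#' @return Object of class `mutation_spectrum`.
#' @export
mutation_spectrum <- function(class_probs = c(
  "A:T>G:C" = 0.262, "G:C>A:T" = 0.45, "A:T>C:G" = 0.072,
  "A:T>T:A" = 0.072, "G:C>C:G" = 0.072, "G:C>T:A" = 0.072)) {
  stopifnot(setequal(names(class_probs), spectrum_classes))
  class_probs <- class_probs[spectrum_classes]
  if (abs(sum(class_probs) - 1) > 1e-9) {
    abort("spectrum probabilities must sum to 1", class = "enuscreen_error")
  }
  structure(list(class_probs = class_probs,
                 transition_mass = sum(class_probs[transition_classes])),
            class = "mutation_spectrum")
}

#' Simulation configuration for a mutagenesis screen
#'
#' @param genome A `genome_model`.
#' @param dose Dose label (`"65"` or `"85"` mg/kg, mapped to the measured
#'   per-site rates) or an explicit per-site rate via `rate`.
#' @param rate Optional explicit per-site mutation rate (overrides `dose`).
#' @param spectrum A `mutation_spectrum`.
#' @param n_g1 Number of G1 offspring of the mutagenized G0 boar.
#' @param dams_per_g1 Wild-type sows mated to the tracked G1 boar (default 4).
#' @param g2_dams_backcrossed G2 daughters backcrossed to their G1 sire
#'   (default 4).
#' @param litter_size Offspring per mating.
#' @param litter_cap Maximum litters drawn while waiting for enough G2
#'   daughters before a breeding-structure error is raised.
#' @param phenotype_model `NULL` or a list with `mode`
#'   (`"dominant"`/`"recessive"`), `penetrance` in `[0,1]`, and optionally a
#'   `locus` row (`chrom`, `pos`, `ref`, `alt`); when `locus` is `NULL` a
#'   missense variant is planted in a random gene.
#' @param poly_rate Per-site density of standing background polymorphisms
#'   segregating in the (wild-type) founders.
#' @param rad_fraction Fraction of genome sites sampled by the
#'   reduced-representation assay.
#' @param mean_depth Mean sequencing depth at sampled sites.
#' @param seq_error Per-read base error rate.
#' @param array_marker_count Number of SNP-array markers.
#' @param array_missing_rate Genotype missingness of the array.
#' @param seed Integer seed fixing all downstream randomness.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(genome, dose = "85", rate = NULL,
                       spectrum = mutation_spectrum(),
                       n_g1 = 1, dams_per_g1 = 4, g2_dams_backcrossed = 4,
                       litter_size = 8, litter_cap = 20,
                       phenotype_model = NULL,
                       poly_rate = 1e-4,
                       rad_fraction = 0.02, mean_depth = 20, seq_error = 0.01,
                       array_marker_count = 500, array_missing_rate = 0.01,
                       seed = 1) {
  if (is.null(rate)) {
    consts <- screen_constants()
    dose <- as.character(dose)
    if (!dose %in% names(consts$dose_rates)) {
      abort("unknown dose label; supply `rate` explicitly",
            class = "enuscreen_error")
    }
    rate <- unname(consts$dose_rates[dose])
  }
  stopifnot(rate >= 0, rate <= 1e-3,
            rad_fraction >= 0, rad_fraction <= 1,
            seq_error > 0, seq_error < 0.5,
            array_missing_rate >= 0, array_missing_rate <= 1,
            n_g1 >= 1, litter_size >= 1)
  if (!is.null(phenotype_model)) {
    stopifnot(phenotype_model$mode %in% c("dominant", "recessive"),
              phenotype_model$penetrance >= 0, phenotype_model$penetrance <= 1)
  }
  structure(list(genome = genome, rate = rate, spectrum = spectrum,
                 n_g1 = n_g1, dams_per_g1 = dams_per_g1,
                 g2_dams_backcrossed = g2_dams_backcrossed,
                 litter_size = litter_size, litter_cap = litter_cap,
                 phenotype_model = phenotype_model, poly_rate = poly_rate,
                 rad_fraction = rad_fraction, mean_depth = mean_depth,
                 seq_error = seq_error,
                 array_marker_count = array_marker_count,
                 array_missing_rate = array_missing_rate, seed = seed),
            class = "sim_config")
}

# uniform positions without replacement over the whole genome; returns tibble
sample_genome_positions <- function(genome, n) {
  lens <- genome$chromosomes$length
  total <- sum(lens)
  idx <- sort(sample(total, n))
  chrom_i <- findInterval(idx - 1, cumsum(c(0, lens)), rightmost.closed = FALSE)
  offset <- idx - cumsum(c(0, lens))[chrom_i]
  tibble(chrom = genome$chromosomes$name[chrom_i], pos = as.integer(offset))
}

#' Draw the ENU mutations carried by one mutagenized gamete
#'
#' The number of induced point mutations is Binomial(genome size, rate);
#' positions are uniform without replacement. Where the genome carries
#' sequence the reference base is read from it and the substitution class is
#' drawn from the spectrum conditional on that base; elsewhere the class is
#' drawn from the full spectrum and a compatible reference base is recorded,
#' so the marginal class distribution equals the configured spectrum.
#'
#' @param genome A `genome_model`.
#' @param rate Per-site mutation probability, in `[0, 1e-3]`.
#' @param spectrum A `mutation_spectrum`.
#' @param seed Integer seed.
#' @return Tibble of variants: `chrom`, `pos`, `ref`, `alt`, `class`,
#'   `origin` (`"enu"`).
#' @export
mutate_gamete <- function(genome, rate, spectrum = mutation_spectrum(),
                          seed = 1) {
  if (rate < 0 || rate > 1e-3) {
    abort("rate must lie in [0, 1e-3]", class = "enuscreen_parameter_error")
  }
  with_seed(seed, {
    total <- sum(genome$chromosomes$length)
    n <- rbinom(1, total, rate)
    if (n == 0) {
      return(tibble(chrom = character(), pos = integer(), ref = character(),
                    alt = character(), class = character(),
                    origin = character()))
    }
    sites <- sample_genome_positions(genome, n)
    draw_substitutions(genome, sites, spectrum) |> mutate(origin = "enu")
  })
}

# assign ref/alt/class at given sites under a spectrum (uses current RNG)
draw_substitutions <- function(genome, sites, spectrum) {
  n <- nrow(sites)
  probs <- spectrum$class_probs
  ref <- rep(NA_character_, n)
  if (!is.null(genome$sequence)) {
    for (ch in intersect(unique(sites$chrom), names(genome$sequence))) {
      i <- which(sites$chrom == ch)
      ref[i] <- toupper(substring(genome$sequence[[ch]], sites$pos[i],
                                  sites$pos[i]))
    }
  } else if (!is.null(genome$genes) && "cds_seq" %in% names(genome$genes)) {
    # sequence is known only inside CDS; look up just the hits
    rt <- region_table(genome)
    rt <- rt[rt$type == "cds", ]
    in_cds <- rep(FALSE, n)
    for (j in seq_len(nrow(rt))) {
      in_cds <- in_cds | (sites$chrom == rt$chrom[j] &
                            sites$pos >= rt$start[j] & sites$pos <= rt$end[j])
    }
    for (i in which(in_cds)) {
      ref[i] <- ref_base_at(genome, sites$chrom[i], sites$pos[i])
    }
  }
  known <- !is.na(ref)
  cls <- character(n)
  alt <- character(n)
  if (any(!known)) {
    # class first, then a compatible reference base: marginal class
    # distribution is exactly the configured spectrum
    k <- sum(!known)
    cls[!known] <- sample(spectrum_classes, k, replace = TRUE, prob = probs)
    pick <- sample(c(1L, 2L), k, replace = TRUE)  # which strand representative
    rows <- match(cls[!known], class_pairs$class) + (pick - 1L)
    ref[!known] <- class_pairs$ref[rows]
    alt[!known] <- class_pairs$alt[rows]
  }
  if (any(known)) {
    for (i in which(known)) {
      ok <- class_pairs$ref == ref[i]
      p <- probs[class_pairs$class[ok]]
      row <- which(ok)[sample.int(sum(ok), 1, prob = p)]
      cls[i] <- class_pairs$class[row]
      alt[i] <- class_pairs$alt[row]
    }
  }
  bind_cols(sites, tibble(ref = ref, alt = alt, class = cls))
}

#' Simulate one meiosis over a set of tracked loci
#'
#' Produces a gamete haplotype from a parental diplotype by a crossover
#' process with inter-locus recombination probabilities from Haldane's map
#' function, theta = (1 - exp(-2d))/2, with d in Morgans taken from the
#' genome's uniform cM/Mb rate. Chromosomes assort independently.
#'
#' @param diplo 2 x L integer matrix of parental alleles (rows = the two
#'   haplotypes).
#' @param loci Tibble with `chrom`, `pos` for the L tracked loci, in the order
#'   of the diplotype columns.
#' @param genome A `genome_model`.
#' @param seed Optional integer seed (omit to use the current RNG stream).
#' @return Integer vector of length L: the transmitted haplotype.
#' @export
simulate_meiosis <- function(diplo, loci, genome, seed = NULL) {
  run <- function() meiosis_gamete(diplo, loci, genome)
  if (is.null(seed)) run() else with_seed(seed, run())
}

meiosis_gamete <- function(diplo, loci, genome) {
  L <- nrow(loci)
  if (ncol(diplo) != L) {
    abort("diplotype does not cover the tracked loci",
          class = "enuscreen_coordinate_error")
  }
  if (!all(loci$chrom %in% genome$chromosomes$name)) {
    abort("tracked loci off the genome", class = "enuscreen_coordinate_error")
  }
  h <- integer(L)
  for (ch in unique(loci$chrom)) {
    idx <- which(loci$chrom == ch)
    pos <- loci$pos[idx]           # loci are kept position-sorted
    d <- diff(pos) * genome$recomb_rate / 100 / 1e6   # Morgans
    theta <- 0.5 * (1 - exp(-2 * d))
    start <- sample(c(0L, 1L), 1L)
    switches <- if (length(theta)) rbinom(length(theta), 1L, theta) else integer()
    h[idx] <- (start + cumsum(c(0L, switches))) %% 2L + 1L
  }
  diplo[cbind(h, seq_len(L))]
}

#' Simulate the three-generation ENU screen
#'
#' Runs the breeding scheme: a mutagenized G0 boar produces `n_g1` G1 boars,
#' each from an independently mutagenized gamete (so no two G1 share an
#' induced mutation) and a wild-type G0 sow; the first G1 boar is mated to
#' `dams_per_g1` wild-type sows to give G2; `g2_dams_backcrossed` G2 daughters
#' are backcrossed to their G1 sire to give G3. Standing background
#' polymorphisms segregate in all wild-type founders; SNP-array marker loci
#' are transmitted alongside. When a phenotype model is configured, the
#' causative variant is planted in the first G1 boar's induced-mutation set
#' and phenotypes are assigned.
#'
#' @param config A `sim_config`.
#' @return A list of class `screen_sim`: `pedigree` (tibble `id`, `sire`,
#'   `dam`, `sex`, `generation`, `affected`), `loci` (tibble `chrom`, `pos`,
#'   `ref`, `alt`, `kind`, `freq`, `causative`), `haplo` (per-individual 2 x L
#'   matrices), `truth` (planted induced mutations with carrier ids), plus
#'   `genome` and `config`.
#' @export
breed_screen <- function(config) {
  genome <- config$genome
  with_seed(stage_seed(config$seed, "breed"), {
    # --- loci: ENU mutations per G1 gamete --------------------------------
    enu <- purrr::map(seq_len(config$n_g1), function(i) {
      mutate_gamete(genome, config$rate, config$spectrum,
                    seed = stage_seed(config$seed, paste0("gamete", i)))
    })
    pheno <- config$phenotype_model
    causative <- NULL
    if (!is.null(pheno)) {
      causative <- pheno$locus %||%
        plant_missense_variant(genome,
                               seed = stage_seed(config$seed, "causative"))
      causative <- as_tibble(causative)[, c("chrom", "pos", "ref", "alt")]
      enu[[1]] <- bind_rows(
        enu[[1]],
        mutate(causative,
               class = classify_substitution(causative$ref, causative$alt)$class,
               origin = "enu"))
    }
    enu_tab <- purrr::imap_dfr(enu, function(v, i)
      mutate(v, g1 = paste0("G1_", i)))

    # --- background polymorphisms and marker loci -------------------------
    total <- sum(genome$chromosomes$length)
    n_poly <- rbinom(1, total, config$poly_rate)
    polys <- if (n_poly > 0) {
      draw_substitutions(genome, sample_genome_positions(genome, n_poly),
                         mutation_spectrum(
                           setNames(rep(1 / 6, 6), spectrum_classes))) |>
        mutate(origin = "polymorphism", freq = runif(n_poly, 0.05, 0.5))
    } else NULL
    markers <- if (config$array_marker_count > 0) {
      place_markers(genome, config$array_marker_count) |>
        mutate(ref = "A", alt = "B", class = NA_character_,
               origin = "marker",
               freq = runif(config$array_marker_count, 0.05, 0.5))
    } else NULL

    loci <- bind_rows(
      mutate(enu_tab, freq = 0),
      polys, markers) |>
      mutate(kind = .data$origin,
             causative = FALSE) |>
      arrange(match(.data$chrom, genome$chromosomes$name), .data$pos) |>
      distinct(.data$chrom, .data$pos, .keep_all = TRUE)
    if (!is.null(causative)) {
      loci$causative <- loci$chrom == causative$chrom &
        loci$pos == causative$pos
    }
    L <- nrow(loci)
    enu_col <- function(g1_id) which(loci$kind == "enu" &
                                       !is.na(loci$g1) & loci$g1 == g1_id)

    founder_haplo <- function() {
      m <- matrix(0L, nrow = 2, ncol = L)
      seg <- which(loci$kind %in% c("polymorphism", "marker"))
      if (length(seg)) {
        m[1, seg] <- rbinom(length(seg), 1L, loci$freq[seg])
        m[2, seg] <- rbinom(length(seg), 1L, loci$freq[seg])
      }
      m
    }

    ped <- list()
    haplo <- list()
    add_ind <- function(id, sire, dam, sex, gen, hap) {
      ped[[length(ped) + 1]] <<- tibble(id = id, sire = sire, dam = dam,
                                        sex = sex, generation = gen)
      haplo[[id]] <<- hap
    }

    # founders: G0 boar (mutations live in his gametes, not his soma),
    # one G0 sow, wild-type sows for G2 matings
    add_ind("G0_1", NA, NA, "M", "G0", founder_haplo())
    add_ind("SOW_0", NA, NA, "F", "founder", founder_haplo())

    for (i in seq_len(config$n_g1)) {
      id <- paste0("G1_", i)
      pat <- meiosis_gamete(haplo[["G0_1"]], loci, genome)
      cols <- enu_col(id)
      pat[cols] <- 1L                      # the mutagenized gamete
      mat <- meiosis_gamete(haplo[["SOW_0"]], loci, genome)
      add_ind(id, "G0_1", "SOW_0", "M", "G1", rbind(pat, mat))
    }

    # --- G2: first G1 boar x wild-type sows -------------------------------
    g2_ids <- character(0)
    if (config$dams_per_g1 > 0) {
      sire <- "G1_1"
      litters <- 0L
      sow_i <- 0L
      g2_i <- 0L
      n_fem <- function() sum(vapply(g2_ids, function(x)
        ped_sex(ped, x) == "F", logical(1)))
      while (litters < config$dams_per_g1 ||
             (n_fem() < config$g2_dams_backcrossed &&
              litters < config$litter_cap)) {
        litters <- litters + 1L
        sow_i <- sow_i + 1L
        sow <- paste0("SOW_", sow_i)
        add_ind(sow, NA, NA, "F", "founder", founder_haplo())
        for (k in seq_len(config$litter_size)) {
          g2_i <- g2_i + 1L
          id <- sprintf("G2_%03d", g2_i)
          sex <- sample(c("M", "F"), 1L)
          add_ind(id, sire, sow, sex, "G2",
                  rbind(meiosis_gamete(haplo[[sire]], loci, genome),
                        meiosis_gamete(haplo[[sow]], loci, genome)))
          g2_ids <- c(g2_ids, id)
        }
      }
      g2_fem <- g2_ids[vapply(g2_ids, function(x)
        ped_sex(ped, x) == "F", logical(1))]
      if (config$g2_dams_backcrossed > 0) {
        if (length(g2_fem) < config$g2_dams_backcrossed) {
          abort(sprintf(
            "only %d G2 females after %d litters; %d needed for backcross",
            length(g2_fem), litters, config$g2_dams_backcrossed),
            class = "enuscreen_breeding_error")
        }
        dams <- g2_fem[seq_len(config$g2_dams_backcrossed)]
        g3_i <- 0L
        for (dam in dams) {
          for (k in seq_len(config$litter_size)) {
            g3_i <- g3_i + 1L
            id <- sprintf("G3_%03d", g3_i)
            add_ind(id, sire, dam, sample(c("M", "F"), 1L), "G3",
                    rbind(meiosis_gamete(haplo[[sire]], loci, genome),
                          meiosis_gamete(haplo[[dam]], loci, genome)))
          }
        }
      }
    }

    pedigree <- bind_rows(ped) |> mutate(affected = NA)
    # truth record: every planted induced mutation and its carriers
    enu_idx <- which(loci$kind == "enu")
    carriers <- purrr::map(enu_idx, function(j) {
      names(haplo)[vapply(haplo, function(h) sum(h[, j]) > 0, logical(1))]
    })
    truth <- loci[enu_idx, c("chrom", "pos", "ref", "alt", "class", "g1",
                             "causative")] |>
      mutate(carriers = carriers)

    sim <- structure(list(pedigree = pedigree, loci = loci, haplo = haplo,
                          truth = truth, genome = genome, config = config),
                     class = "screen_sim")
    if (!is.null(pheno)) {
      sim <- assign_phenotypes(sim, pheno,
                               seed = stage_seed(config$seed, "phenotype"))
    }
    sim
  })
}

ped_sex <- function(ped, id) {
  for (p in rev(ped)) if (p$id == id) return(p$sex)
  NA_character_
}

#' @export
print.screen_sim <- function(x, ...) {
  cat("<screen_sim> ", nrow(x$pedigree), " individuals (",
      paste(sprintf("%s:%d", names(table(x$pedigree$generation)),
                    as.integer(table(x$pedigree$generation))), collapse = ", "),
      "), ", nrow(x$loci), " tracked loci, ",
      sum(x$loci$kind == "enu"), " induced mutations\n", sep = "")
  invisible(x)
}

#' Assign affection status under a single-locus phenotype model
#'
#' Dominant: carriers of the causative allele are affected with probability
#' `penetrance`; recessive: alt-homozygotes are affected with probability
#' `penetrance`; all other individuals are unaffected.
#'
#' @param sim A `screen_sim`.
#' @param phenotype_model List with `mode` and `penetrance` (the causative
#'   locus is the one flagged in `sim$loci`).
#' @param seed Integer seed.
#' @return The `screen_sim` with `pedigree$affected` filled in.
#' @export
assign_phenotypes <- function(sim, phenotype_model, seed = 1) {
  j <- which(sim$loci$causative)
  if (length(j) != 1) {
    abort("no causative locus tracked in this simulation",
          class = "enuscreen_error")
  }
  with_seed(seed, {
    g <- vapply(sim$haplo, function(h) sum(h[, j]), integer(1))
    at_risk <- if (phenotype_model$mode == "dominant") g >= 1 else g == 2
    aff <- at_risk & runif(length(g)) < phenotype_model$penetrance
    sim$pedigree$affected <- unname(aff[sim$pedigree$id])
    sim
  })
}

# evenly spaced marker positions per chromosome (proportional allocation)
place_markers <- function(genome, n) {
  lens <- genome$chromosomes$length
  alloc <- pmax(1L, round(n * lens / sum(lens)))
  # trim/pad to exactly n
  while (sum(alloc) > n) alloc[which.max(alloc)] <- alloc[which.max(alloc)] - 1L
  while (sum(alloc) < n) alloc[which.max(lens / alloc)] <-
      alloc[which.max(lens / alloc)] + 1L
  purrr::map_dfr(seq_along(lens), function(i) {
    k <- alloc[i]
    tibble(chrom = genome$chromosomes$name[i],
           pos = as.integer(round(seq(1, lens[i], length.out = k + 2)[2:(k + 1)])))
  })
}

#' Plant a heterozygous missense variant in a random gene
#'
#' Chooses a CDS position whose single-base substitution yields a missense
#' change, for use as a fully tractable causative locus in simulations.
#'
#' @param genome A `genome_model` whose genes carry sequence.
#' @param seed Integer seed.
#' @param gene_id Optional gene to use (default: random).
#' @return One-row tibble `chrom`, `pos`, `ref`, `alt`.
#' @export
plant_missense_variant <- function(genome, seed = 1, gene_id = NULL) {
  genes <- genome$genes
  if (is.null(genes)) abort("genome has no genes", class = "enuscreen_error")
  with_seed(seed, {
    g <- if (is.null(gene_id)) genes[sample.int(nrow(genes), 1), ]
      else genes[genes$gene_id == gene_id, ]
    seq <- gene_cds_sequence(genome, g)
    code <- Biostrings::GENETIC_CODE
    for (try in 1:200) {
      cp <- sample.int(nchar(seq), 1)
      codon_i <- ceiling(cp / 3)
      codon <- toupper(substring(seq, 3 * codon_i - 2, 3 * codon_i))
      within <- cp - (3 * codon_i - 3)
      ref_cds <- substring(codon, within, within)
      for (alt_cds in sample(setdiff(c("A", "C", "G", "T"), ref_cds))) {
        alt_codon <- codon
        substring(alt_codon, within, within) <- alt_cds
        if (code[[alt_codon]] != code[[codon]] && code[[alt_codon]] != "*" &&
            code[[codon]] != "*") {
          pos <- genomic_position_of(g, cp)
          ref <- if (g$strand == "+") ref_cds else complement_base(ref_cds)
          alt <- if (g$strand == "+") alt_cds else complement_base(alt_cds)
          return(tibble(chrom = g$chrom, pos = pos, ref = ref, alt = alt))
        }
      }
    }
    abort("could not find a missense position", class = "enuscreen_error")
  })
}

# genomic coordinate of a 1-based spliced-CDS position (inverse of
# cds_position_of)
genomic_position_of <- function(g, cds_pos) {
  cds <- g$cds[[1]]
  total <- sum(cds$end - cds$start + 1)
  plus_off <- if (g$strand == "+") cds_pos else total - cds_pos + 1L
  cum <- cumsum(cds$end - cds$start + 1)
  iv <- which(plus_off <= cum)[1]
  before <- if (iv > 1) cum[iv - 1] else 0L
  as.integer(cds$start[iv] + (plus_off - before) - 1L)
}
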