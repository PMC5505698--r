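# End-to-end pipeline: simulate -> trio de novo calling -> spectrum ->
# linkage scan -> candidate filtering -> design report. All randomness flows
# from the config seed through per-stage derived seeds, so two runs with the
# same config produce identical results.

#' Subset a pedigree, re-foundering individuals whose parents are dropped
#'
#' Mapping pedigrees conventionally start at the mutant founder: a linkage
#' model without mutation cannot explain an affected individual born to two
#' unaffected parents under full penetrance, so the G0 generation is dropped
#' and the G1 carrier becomes a founder.
#'
#' @param pedigree Pedigree tibble.
#' @param ids Individuals to keep.
#' @return The subset with `sire`/`dam` set to `NA` where the parent is not
#'   kept.
#' @export
subset_pedigree <- function(pedigree, ids) {
  out <- pedigree[pedigree$id %in% ids, ]
  out$sire[!out$sire %in% out$id] <- NA
  out$dam[!out$dam %in% out$id] <- NA
  out
}

#' Run the full screen analysis pipeline on a simulated screen
#'
#' Simulates a screen under `config`, then runs every analysis stage:
#' reduced-representation trio de novo calling on the G0 family with
#' mutation-frequency estimation, substitution-spectrum summary of the calls,
#' marker QC and a genome-wide parametric LOD scan on the mapping pedigree,
#' linkage-region extraction, the five-criteria candidate cascade on
#' WGS-style call sets of two affected and one control animal, and the
#' burden-extrapolation report at the estimated rate.
#'
#' @param config A [sim_config()] with a `phenotype_model` (needed for the
#'   mapping stages).
#' @param out_dir Optional directory: when given, stage outputs are written
#'   as TSV/VCF/BED files together with a flat key-value manifest.
#' @param lod_threshold LOD threshold for region extraction.
#' @param scan_theta_grid Recombination-fraction grid used in the scan.
#' @return List of class `screen_pipeline` with elements `sim`, `denovo`,
#'   `frequency`, `spectrum`, `qc`, `profile`, `regions`, `cascade`,
#'   `burden`, `manifest`.
#' @export
run_screen_pipeline <- function(config, out_dir = NULL, lod_threshold = 3,
                                scan_theta_grid = seq(0, 0.5, by = 0.05)) {
  if (is.null(config$phenotype_model)) {
    abort("pipeline requires a phenotype model in the config",
          class = "enuscreen_error")
  }
  sim <- breed_screen(config)

  # trio de novo calling on the G0 family
  g1_ids <- sim$pedigree$id[sim$pedigree$generation == "G1"]
  trio_members <- c("G0_1", "SOW_0", g1_ids)
  counts <- emulate_rad(sim, individuals = trio_members)
  if (nrow(counts) == 0) {
    abort("no callable sites: reduced-representation sampling is empty",
          class = "enuscreen_error")
  }
  trios <- tibble(trio_id = paste0("trio_", seq_along(g1_ids)),
                  father = "G0_1", mother = "SOW_0", child = g1_ids)
  priors <- sim_trio_priors(config)
  dn <- call_denovo(counts, trios, priors = priors)
  alpha <- caller_sensitivity(counts, trios, priors = priors,
                              seed = stage_seed(config$seed, "sensitivity"))
  freq <- estimate_frequency(dn, sensitivity = alpha)
  calls_passing <- dn$calls[dn$calls$pass, ]
  spec_sum <- if (nrow(calls_passing) > 0) {
    truth_key <- paste(sim$loci$chrom, sim$loci$pos)
    idx <- match(paste(calls_passing$chrom, calls_passing$pos), truth_key)
    summarize_spectrum(sim$loci[idx[!is.na(idx)], c("ref", "alt")])
  } else summarize_spectrum(tibble(ref = character(), alt = character()))

  # linkage mapping on the G1 family (the mutant G1 boar is the pedigree
  # founder; see subset_pedigree)
  map_ids <- sim$pedigree$id[sim$pedigree$generation %in%
                               c("G1", "G2", "G3", "founder") &
                               sim$pedigree$id != "SOW_0"]
  map_ped <- subset_pedigree(sim$pedigree, map_ids)
  geno <- emulate_snp_array(sim, individuals = map_ids)
  qc <- qc_markers(geno)
  dmod <- disease_model(config$phenotype_model$mode)
  profile <- genome_scan(qc$genotypes, map_ped, dmod,
                         theta_grid = scan_theta_grid)
  regions <- extract_regions(
    profile, threshold = lod_threshold,
    chrom_lengths = setNames(sim$genome$chromosomes$length,
                             sim$genome$chromosomes$name))

  # candidate cascade on WGS call sets: two affected + one control
  aff_ids <- sim$pedigree$id[which(sim$pedigree$affected)]
  ctl_ids <- sim$pedigree$id[which(!sim$pedigree$affected &
                                     !sim$pedigree$generation %in% "G0")]
  cascade <- NULL
  if (length(aff_ids) >= 2 && length(ctl_ids) >= 1 && nrow(regions) > 0) {
    seq_ids <- c(aff_ids[1:2], ctl_ids[1])
    wgs <- emulate_wgs_calls(sim, sim$pedigree$id)
    cascade <- filter_cascade(
      wgs$calls, affected = aff_ids[1:2], controls = ctl_ids[1],
      mode = config$phenotype_model$mode, regions = regions,
      known_snps = wgs$known_snps, genome = sim$genome,
      pedigree = sim$pedigree)
  }

  burden <- burden_extrapolation(freq$rate)

  manifest <- c(seed = config$seed, rate = config$rate,
                n_g1 = config$n_g1, rad_fraction = config$rad_fraction,
                mean_depth = config$mean_depth,
                n_denovo_calls = sum(dn$calls$pass),
                estimated_rate = freq$rate,
                n_markers_post_qc = nrow(qc$genotypes),
                n_regions = nrow(regions),
                n_final_candidates = if (is.null(cascade)) NA
                  else nrow(cascade$final))

  res <- structure(list(sim = sim, denovo = dn, frequency = freq,
                        spectrum = spec_sum, qc = qc, profile = profile,
                        regions = regions, cascade = cascade,
                        burden = burden, manifest = manifest),
                   class = "screen_pipeline")
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

#' @export
print.screen_pipeline <- function(x, ...) {
  cat("<screen_pipeline>\n")
  print(x$frequency)
  cat("  regions: ", nrow(x$regions), "; final candidates: ",
      if (is.null(x$cascade)) "not run" else nrow(x$cascade$final),
      "\n", sep = "")
  invisible(x)
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(out_dir, f)
  write_pedigree(res$sim$pedigree, fp("pedigree.tsv"))
  calls <- res$denovo$calls[res$denovo$calls$pass, ]
  if (nrow(calls) > 0) {
    key <- paste(res$sim$loci$chrom, res$sim$loci$pos)
    idx <- match(paste(calls$chrom, calls$pos), key)
    vcf <- tibble(chrom = calls$chrom, pos = calls$pos,
                  ref = res$sim$loci$ref[idx], alt = res$sim$loci$alt[idx],
                  info = sprintf("PP_DNM=%.4g;PP_NULL=%.4g;TRIO_ID=%s",
                                 calls$pp_dnm, calls$pp_null, calls$trio_id))
    write_vcf(vcf, fp("denovo_calls.vcf"))
  }
  utils::write.table(tidy(res$frequency), fp("frequency.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(res$profile, fp("lod_profile.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (nrow(res$regions) > 0) write_bed(res$regions, fp("regions.bed"))
  if (!is.null(res$cascade)) {
    utils::write.table(res$cascade$stages, fp("cascade_stages.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(res$cascade$final) > 0) {
      write_vcf(res$cascade$final[, c("chrom", "pos", "ref", "alt")],
                fp("candidates.vcf"))
    }
  }
  mf <- res$manifest
  writeLines(paste(names(mf), unname(mf), sep = "="), fp("manifest.txt"))
  invisible(out_dir)
}
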