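# Synthetic-data generator: gamete mutagenesis, meiosis, breeding scheme,
# phenotype assignment and the sequencing/genotyping emulation layers.

test_that("mutate_gamete draws Binomial(genome, rate) mutations", {
  g <- genome_model(tibble::tibble(name = "chr1", length = 1e7))
  expect_equal(nrow(mutate_gamete(g, rate = 0, seed = 1)), 0)
  expect_error(mutate_gamete(g, rate = 0.01),
               class = "enuscreen_parameter_error")
  # mean count over seeded replicates within 3 SE of bases x rate
  n <- vapply(1:200, function(s) nrow(mutate_gamete(g, 5.86e-6, seed = s)),
              numeric(1))
  se <- sqrt(58.6 / 200)   # Poisson-scale SE of the mean
  expect_lt(abs(mean(n) - 58.6), 3 * se)
  # positions unique and on the genome
  v <- mutate_gamete(g, 5.86e-6, seed = 7)
  expect_equal(anyDuplicated(v$pos), 0)
  expect_true(all(v$pos >= 1 & v$pos <= 1e7))
})

test_that("full-scale burden arithmetic matches the mutagenesis rates", {
  sc <- screen_constants()
  expect_equal(floor(sc$genome_size * sc$dose_rates[["85"]]), 16466)
  expect_equal(floor(sc$genome_size * sc$dose_rates[["65"]]), 4580)
})

test_that("empirical transition fraction matches the configured mass", {
  g <- genome_model(tibble::tibble(name = "chr1", length = 1e8))
  v <- mutate_gamete(g, rate = 6e-4, seed = 3)   # ~60,000 draws
  expect_gt(nrow(v), 50000)
  s <- summarize_spectrum(v)
  se <- sqrt(0.712 * 0.288 / nrow(v))
  expect_lt(abs(s$transition_fraction - 0.712), 3 * se)
})

test_that("meiosis recombination follows Haldane's map function", {
  g <- genome_model(tibble::tibble(name = c("chr1", "chr2"),
                                   length = c(6e7, 6e7)), recomb_rate = 1)
  loci <- tibble::tibble(chrom = c("chr1", "chr1", "chr2"),
                         pos = c(1e6, 51e6, 1e6))
  diplo <- rbind(c(1L, 1L, 1L), c(0L, 0L, 0L))  # phase-known
  gam <- withr::with_seed(42, t(vapply(1:10000, function(i)
    simulate_meiosis(diplo, loci, g), integer(3))))
  # 50 Mb x 1 cM/Mb = 0.5 M -> theta = (1 - exp(-1))/2
  theta <- 0.5 * (1 - exp(-1))
  rec12 <- mean(gam[, 1] != gam[, 2])
  expect_lt(abs(rec12 - theta), 3 * sqrt(theta * (1 - theta) / 10000))
  # unlinked chromosomes assort independently
  rec13 <- mean(gam[, 1] != gam[, 3])
  expect_lt(abs(rec13 - 0.5), 3 * sqrt(0.25 / 10000))
  # zero distance -> always co-transmitted
  loci0 <- tibble::tibble(chrom = "chr1", pos = c(1e6, 1e6 + 1))
  gam0 <- withr::with_seed(1, t(vapply(1:200, function(i)
    simulate_meiosis(diplo[, 1:2], loci0, g), integer(2))))
  expect_true(all(gam0[, 1] == gam0[, 2]))
})

test_that("breed_screen realizes the three-generation structure", {
  g <- small_genome(seed = 4)
  cfg <- sim_config(g, rate = 1e-5, n_g1 = 1, dams_per_g1 = 4,
                    g2_dams_backcrossed = 4, litter_size = 8,
                    array_marker_count = 50, seed = 2)
  sim <- breed_screen(cfg)
  tab <- table(sim$pedigree$generation)
  expect_equal(unname(tab[["G0"]]), 1)
  expect_equal(unname(tab[["G1"]]), 1)
  expect_gte(unname(tab[["G2"]]), 32)
  expect_equal(unname(tab[["G3"]]), 32)
  # G3 offspring are sired by the G1 boar on G2 dams (the backcross loop)
  g3 <- sim$pedigree[sim$pedigree$generation == "G3", ]
  expect_true(all(g3$sire == "G1_1"))
  dams <- unique(g3$dam)
  expect_length(dams, 4)
  expect_true(all(sim$pedigree$generation[match(dams, sim$pedigree$id)] ==
                    "G2"))
  expect_true(all(sim$pedigree$sex[match(dams, sim$pedigree$id)] == "F"))
  # truth record covers all induced mutations
  expect_equal(nrow(sim$truth), sum(sim$loci$kind == "enu"))
})

test_that("no two G1 siblings share an induced mutation", {
  g <- small_genome(seed = 5)
  cfg <- trio_sim_config(g, rate = 2e-5, seed = 9)
  sim <- breed_screen(cfg)
  per_g1 <- table(sim$truth$g1)
  expect_length(per_g1, 5)
  expect_equal(anyDuplicated(paste(sim$truth$chrom, sim$truth$pos)), 0)
  # each G1 carries its own mutations heterozygously; siblings carry none
  for (i in seq_len(nrow(sim$truth))) {
    carriers <- sim$truth$carriers[[i]]
    expect_true(sim$truth$g1[i] %in% carriers)
    expect_false(any(setdiff(paste0("G1_", 1:5), sim$truth$g1[i]) %in%
                       carriers))
  }
})

test_that("identical seeds give identical simulations", {
  g <- small_genome(seed = 6)
  cfg <- sim_config(g, rate = 1e-5, n_g1 = 2, dams_per_g1 = 2,
                    g2_dams_backcrossed = 0, litter_size = 4,
                    array_marker_count = 20, seed = 33)
  s1 <- breed_screen(cfg)
  s2 <- breed_screen(cfg)
  expect_identical(s1$pedigree, s2$pedigree)
  expect_identical(s1$loci, s2$loci)
  expect_identical(s1$haplo, s2$haplo)
  expect_identical(emulate_rad(s1), emulate_rad(s2))
  expect_identical(emulate_snp_array(s1), emulate_snp_array(s2))
})

test_that("breeding errors surface when G2 daughters cannot be found", {
  g <- small_genome(seed = 7)
  cfg <- sim_config(g, rate = 1e-6, n_g1 = 1, dams_per_g1 = 1,
                    g2_dams_backcrossed = 6, litter_size = 1,
                    litter_cap = 3, array_marker_count = 0, seed = 1)
  expect_error(breed_screen(cfg), class = "enuscreen_breeding_error")
})

test_that("phenotype assignment follows the inheritance model", {
  g <- small_genome(seed = 8)
  # dominant, full penetrance: about half the G2 offspring are affected
  cfg <- sim_config(g, rate = 1e-5, n_g1 = 1, dams_per_g1 = 5,
                    g2_dams_backcrossed = 0, litter_size = 40,
                    phenotype_model = list(mode = "dominant", penetrance = 1),
                    array_marker_count = 0, seed = 14)
  sim <- breed_screen(cfg)
  g2 <- sim$pedigree[sim$pedigree$generation == "G2", ]
  frac <- mean(g2$affected)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / nrow(g2)))
  # penetrance 0: nobody is affected
  sim0 <- assign_phenotypes(sim, list(mode = "dominant", penetrance = 0),
                            seed = 1)
  expect_false(any(sim0$pedigree$affected))
  # recessive full penetrance: G3 of carrier G2 dams segregate 1:3
  cfg_r <- sim_config(g, rate = 1e-5, n_g1 = 1, dams_per_g1 = 6,
                      g2_dams_backcrossed = 6, litter_size = 25,
                      phenotype_model = list(mode = "recessive",
                                             penetrance = 1),
                      array_marker_count = 0, seed = 15)
  sim_r <- breed_screen(cfg_r)
  j <- which(sim_r$loci$causative)
  carrier_dams <- names(Filter(function(h) sum(h[, j]) > 0, sim_r$haplo))
  g3 <- sim_r$pedigree[sim_r$pedigree$generation == "G3" &
                         sim_r$pedigree$dam %in% carrier_dams, ]
  expect_gt(nrow(g3), 40)
  expect_lt(abs(mean(g3$affected) - 0.25),
            3 * sqrt(0.25 * 0.75 / nrow(g3)))
})

test_that("read-count emulation matches the genotype error model", {
  g <- small_genome(seed = 9)
  cfg <- trio_sim_config(g, rate = 5e-5, seed = 5, rad_fraction = 0.01)
  sim <- breed_screen(cfg)
  counts <- emulate_rad(sim, mean_depth = 20, seq_error = 0.01, seed = 77)
  depth <- counts$ref + counts$alt
  expect_lt(abs(mean(depth) - 20), 0.1)
  # hom-ref background sites have alt fraction ~ epsilon
  key <- paste(counts$chrom, counts$pos)
  vkey <- paste(sim$loci$chrom, sim$loci$pos)
  bg <- !key %in% vkey
  expect_lt(abs(sum(counts$alt[bg, ]) / sum(depth[bg, ]) - 0.01), 0.002)
  # het sites in carriers have alt fraction ~ 1/2
  vrows <- which(!bg)
  jv <- match(key[vrows], vkey)
  het_alt <- 0; het_depth <- 0; n_het <- 0
  for (k in seq_along(vrows)) {
    for (id in colnames(counts$ref)) {
      if (sum(sim$haplo[[id]][, jv[k]]) == 1L) {
        het_alt <- het_alt + counts$alt[vrows[k], id]
        het_depth <- het_depth + depth[vrows[k], id]
        n_het <- n_het + 1
      }
    }
  }
  expect_gt(n_het, 10)
  expect_lt(abs(het_alt / het_depth - 0.5), 3 * 0.5 / sqrt(het_depth))
})

test_that("SNP-array emulation respects spacing, inheritance, missingness", {
  g <- small_genome(seed = 10)
  cfg <- sim_config(g, rate = 1e-5, n_g1 = 1, dams_per_g1 = 2,
                    g2_dams_backcrossed = 0, litter_size = 5,
                    array_marker_count = 100, array_missing_rate = 0,
                    seed = 3)
  sim <- breed_screen(cfg)
  geno <- emulate_snp_array(sim)
  expect_equal(nrow(geno), 100)
  expect_true(all(geno$freq >= 0.05 & geno$freq <= 0.5))
  # missing_rate 0 -> complete call rate
  inds <- setdiff(names(geno), c("chrom", "pos", "marker_id", "freq"))
  expect_false(any(is.na(as.matrix(geno[inds]))))
  # missing_rate 1 -> everything missing
  geno1 <- emulate_snp_array(sim, missing_rate = 1)
  expect_true(all(is.na(as.matrix(geno1[inds]))))
  # child genotypes are consistent with parental transmission
  kid <- sim$pedigree$id[sim$pedigree$generation == "G2"][1]
  sire <- sim$pedigree$sire[sim$pedigree$id == kid]
  dam <- sim$pedigree$dam[sim$pedigree$id == kid]
  ok <- mapply(function(gc, gs, gd) {
    pa <- if (gs == 0) 0 else if (gs == 2) 1 else c(0, 1)
    ma <- if (gd == 0) 0 else if (gd == 2) 1 else c(0, 1)
    gc %in% outer(pa, ma, "+")
  }, geno[[kid]], geno[[sire]], geno[[dam]])
  expect_true(all(ok))
})

test_that("WGS-style call sets and the known-polymorphism list are coherent", {
  g <- small_genome(seed = 11)
  cfg <- sim_config(g, rate = 2e-5, n_g1 = 1, dams_per_g1 = 2,
                    g2_dams_backcrossed = 0, litter_size = 6,
                    phenotype_model = list(mode = "dominant", penetrance = 1),
                    poly_rate = 5e-5, array_marker_count = 0, seed = 6)
  sim <- breed_screen(cfg)
  wgs <- emulate_wgs_calls(sim, sim$pedigree$id)
  # the known-polymorphism list never contains a planted induced mutation
  expect_equal(nrow(dplyr::inner_join(
    wgs$known_snps[, c("chrom", "pos")],
    sim$truth[, c("chrom", "pos")], by = c("chrom", "pos"))), 0)
  # the causative variant is het in affected carriers, absent in the sow
  ca <- sim$truth[sim$truth$causative, ]
  row <- wgs$calls[wgs$calls$chrom == ca$chrom & wgs$calls$pos == ca$pos, ]
  aff <- sim$pedigree$id[which(sim$pedigree$affected)]
  for (id in aff) expect_equal(row[[paste0("gt_", id)]], 1L)
  expect_equal(row$gt_SOW_1, 0L)
  # poly_rate 0 leaves only planted mutations
  cfg0 <- sim_config(g, rate = 2e-5, n_g1 = 1, dams_per_g1 = 0,
                     g2_dams_backcrossed = 0, poly_rate = 0,
                     array_marker_count = 0, seed = 6)
  sim0 <- breed_screen(cfg0)
  wgs0 <- emulate_wgs_calls(sim0, sim0$pedigree$id)
  expect_equal(nrow(wgs0$known_snps), 0)
  expect_true(all(wgs0$calls$origin == "enu"))
})
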