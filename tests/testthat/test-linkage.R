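# Marker QC, exact two-point LOD (closed forms and a brute-force enumeration
# oracle over all diplotype configurations), region extraction and the
# allelic association test.

test_that("marker QC removes low call rate and low MAF markers", {
  inds <- paste0("I", 1:10)
  geno <- tibble::tibble(chrom = "chr1", pos = 1:4 * 1000L,
                         marker_id = paste0("M", 1:4))
  gm <- rbind(
    c(0, 1, 2, 0, 1, 2, 0, 1, NA, NA),  # call rate 0.8 -> removed
    rep(0, 10),                          # monomorphic -> removed
    c(0, 0, 0, 0, 0, 0, 0, 0, 0, 1),    # maf 0.05 -> kept (boundary)
    c(0, 1, 2, 0, 1, 2, 0, 1, 2, 0))    # clean -> kept
  for (i in seq_along(inds)) geno[[inds[i]]] <- as.integer(gm[, i])
  qc <- qc_markers(geno)
  expect_equal(qc$genotypes$marker_id, c("M3", "M4"))
  expect_equal(qc$report$reason[1:2], c("call_rate", "maf"))
  # fixture with planted failures: exactly the survivors remain
  set.seed(5)
  big <- tibble::tibble(chrom = "chr1", pos = 1:100 * 1000L,
                        marker_id = sprintf("M%03d", 1:100))
  G <- matrix(sample(0:2, 100 * 40, replace = TRUE), 100, 40)
  bad_cr <- 1:4; bad_maf <- 5:7
  G[bad_cr, 1:20] <- NA
  G[bad_maf, ] <- 0L
  for (i in 1:40) big[[paste0("I", i)]] <- as.integer(G[, i])
  qc2 <- qc_markers(big)
  expect_equal(nrow(qc2$genotypes), 93)
  expect_equal(which(qc2$report$removed), 1:7)
})

test_that("LOD closed forms: 10 phase-known meioses and theta = 0.5", {
  ped <- tibble::tibble(
    id = c("GF", "GM", "SIRE", "DAM", paste0("C", 1:10)),
    sire = c(NA, NA, "GF", NA, rep("SIRE", 10)),
    dam = c(NA, NA, "GM", NA, rep("DAM", 10)),
    affected = c(TRUE, FALSE, TRUE, FALSE, rep(c(TRUE, FALSE), 5)))
  g <- c(GF = 2L, GM = 0L, SIRE = 1L, DAM = 0L,
         stats::setNames(rep(c(1L, 0L), 5), paste0("C", 1:10)))
  dm <- disease_model("dominant", q = 1e-6)
  tl <- two_point_lod(ped, g, dm, marker_freq = 0.3)
  expect_equal(tl$max_lod, 10 * log10(2), tolerance = 1e-4)
  expect_equal(tl$theta_max, 0)
  expect_equal(tl$lod$lod[tl$lod$theta == 0.5], 0, tolerance = 1e-10)
  # one recombinant: closed form at theta = 0.1, sentinel at theta = 0
  g2 <- g; g2["C10"] <- 1L
  tl2 <- two_point_lod(ped, g2, dm, marker_freq = 0.3)
  expect_equal(tl2$lod$lod[tl2$lod$theta == 0.1],
               log10(0.1 * 0.9^9 / 0.5^10), tolerance = 1e-4)
  expect_equal(tl2$lod$lod[tl2$lod$theta == 0], -99)
})

test_that("two_point_lod equals brute-force enumeration on random pedigrees", {
  cases <- 0
  for (seed in 1:90) {
    n_extra <- 1 + seed %% 3           # pedigrees of 3-5 individuals
    bc <- seed %% 4 == 0 && n_extra >= 2
    mode <- if (seed %% 2 == 0) "dominant" else "recessive"
    fx <- random_test_pedigree(n_extra, seed = 1000 + seed, mode = mode,
                               backcross = bc)
    thetas <- c(0.05, 0.2, 0.4)
    got <- enuscreen:::lik_grid(fx$ped, as.list(fx$g), fx$dmodel, fx$p,
                                thetas)
    want <- vapply(thetas, function(th)
      oracle_pedigree_lik(fx$ped, as.list(fx$g), fx$dmodel, fx$p, th),
      numeric(1))
    expect_equal(10^got, want, tolerance = 1e-10)
    cases <- cases + length(thetas)
  }
  # a couple of 6-individual pedigrees with the backcross loop
  for (seed in c(7, 19)) {
    fx <- random_test_pedigree(3, seed = 2000 + seed, backcross = TRUE)
    got <- enuscreen:::lik_grid(fx$ped, as.list(fx$g), fx$dmodel, fx$p, 0.15)
    want <- oracle_pedigree_lik(fx$ped, as.list(fx$g), fx$dmodel, fx$p, 0.15)
    expect_equal(10^got, want, tolerance = 1e-10)
    cases <- cases + 1
  }
  expect_gte(cases, 200)
})

test_that("LOD is invariant under marker allele relabeling", {
  fx <- random_test_pedigree(3, seed = 77)
  tl1 <- two_point_lod(fx$ped, fx$g, fx$dmodel, marker_freq = fx$p)
  g_swapped <- 2 - fx$g
  tl2 <- two_point_lod(fx$ped, g_swapped, fx$dmodel, marker_freq = 1 - fx$p)
  expect_equal(tl1$lod$lod, tl2$lod$lod, tolerance = 1e-10)
})

test_that("unsupported pedigree structures raise structural errors", {
  # full-sib mating loop (not the sire-daughter backcross)
  ped <- tibble::tibble(
    id = c("S", "D", "C1", "C2", "X"),
    sire = c(NA, NA, "S", "S", "C1"),
    dam = c(NA, NA, "D", "D", "C2"),
    affected = c(NA, NA, NA, NA, TRUE))
  g <- c(S = 1L, D = 1L, C1 = 1L, C2 = 1L, X = 2L)
  expect_error(two_point_lod(ped, g, disease_model("dominant")),
               class = "enuscreen_structure_error")
  # one parent recorded without the other
  ped2 <- tibble::tibble(id = c("S", "C"), sire = c(NA, "S"),
                         dam = c(NA, NA), affected = c(NA, TRUE))
  expect_error(two_point_lod(ped2, c(S = 1L, C = 1L),
                             disease_model("dominant")),
               class = "enuscreen_structure_error")
})

test_that("region extraction merges runs and spans flanking markers", {
  prof <- tibble::tibble(
    chrom = rep("chr1", 10), pos = 1:10 * 1e6L,
    marker_id = sprintf("M%02d", 1:10),
    lod = c(0.1, 3.5, 0.2, 3.2, 4.0, 0.1, 0.2, 0.1, 3.1, 0.3),
    theta = 0)
  class(prof) <- c("lod_profile", class(prof))
  reg <- extract_regions(prof, threshold = 3, merge_gap_markers = 2)
  # markers 2,4,5 merge (one below-threshold gap); marker 9 is separate
  expect_equal(nrow(reg), 2)
  expect_equal(reg$start[1], 1e6)   # flanking below-threshold marker
  expect_equal(reg$end[1], 6e6)
  expect_equal(reg$peak_lod[1], 4.0)
  expect_equal(reg$start[2], 8e6)
  expect_equal(reg$end[2], 10e6)
  # threshold above the maximum: nothing
  expect_equal(nrow(extract_regions(prof, threshold = 10)), 0)
  # single above-threshold marker spans its informative flanks
  prof1 <- prof; prof1$lod <- c(0.1, 5, 0.1, rep(0.1, 7))
  reg1 <- extract_regions(prof1)
  expect_equal(c(reg1$start, reg1$end), c(1e6, 3e6))
  # exactly-uninformative markers (LOD 0) do not break a run
  prof2 <- prof
  prof2$lod <- c(0.2, 3.5, 0, 0, 0, 0, 3.4, 3.6, 0.2, 0.1)
  reg2 <- extract_regions(prof2, threshold = 3, merge_gap_markers = 2)
  expect_equal(nrow(reg2), 1)
  expect_equal(c(reg2$start, reg2$end), c(1e6, 9e6))
})

test_that("allelic association reproduces hand-computed chi-squared values", {
  # identical allele frequencies -> 0
  a0 <- allelic_association(c(0, 1, 2, 1), c(0, 1, 2, 1))
  expect_equal(a0$chisq, 0)
  # complete separation of 40 vs 40 alleles -> chi-squared 80
  a1 <- allelic_association(rep(2L, 20), rep(0L, 20))
  expect_equal(a1$chisq, 80)
  expect_lt(a1$p_value, 1e-6)
  # agreement with the stats implementation on a random table
  ca <- c(rep(2, 8), rep(1, 6), rep(0, 6))
  co <- c(rep(2, 2), rep(1, 8), rep(0, 10))
  got <- allelic_association(ca, co)
  tab <- rbind(c(sum(ca), 2 * length(ca) - sum(ca)),
               c(sum(co), 2 * length(co) - sum(co)))
  want <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  expect_equal(got$chisq, unname(want$statistic))
  expect_equal(got$p_value, unname(want$p.value))
  # zero margin flagged
  z <- allelic_association(c(0, 0), c(0, 0))
  expect_true(is.na(z$chisq))
  expect_equal(z$flag, "zero margin")
  expect_error(allelic_association(numeric(0), c(1)),
               class = "enuscreen_error")
})
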