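# The five-criteria filtering cascade and co-segregation checking.

# A hand-built family with a planted causative missense variant: sire and two
# affected offspring carry it het; controls do not. Extra variants exercise
# each filter stage.
cascade_fixture <- function(mode = "dominant") {
  seq1 <- withr::with_seed(21, paste(
    sample(c("A", "C", "G", "T"), 999, replace = TRUE), collapse = ""))
  substring(seq1, 301, 303) <- "AGG"   # codon 101, missense target
  substring(seq1, 307, 309) <- "TTT"   # codon 103, synonymous target
  genes <- tibble::tibble(
    gene_id = "g1", chrom = "chr1", strand = "+",
    cds = list(tibble::tibble(start = 5001, end = 5999)),
    utr5 = list(NULL), utr3 = list(NULL), cds_seq = seq1)
  genome <- genome_model(tibble::tibble(name = c("chr1", "chr2"),
                                        length = c(1e6, 1e6)), genes)
  hom <- if (mode == "recessive") 2L else 1L
  variants <- tibble::tribble(
    ~chrom, ~pos,    ~ref, ~alt, ~why,
    "chr1", 5301L,   "A",  "T",  "causative missense",
    "chr1", 5309L,   "T",  "C",  "synonymous in region",
    "chr1", 400000L, "G",  "A",  "intergenic in region",
    "chr1", 5310L,   "C",  "A",  "known polymorphism in region",
    "chr2", 1000L,   "G",  "A",  "right pattern, wrong chromosome",
    "chr1", 8000L,   "C",  "T",  "fails inheritance")
  # fix refs to match the gene sequence where applicable
  variants$ref[1] <- substring(seq1, 301, 301)
  variants$ref[2] <- substring(seq1, 309, 309)
  variants$ref[4] <- substring(seq1, 310, 310)
  calls <- variants[, c("chrom", "pos", "ref", "alt")]
  carrier <- c(1, 1, 1, 1, 1, 0)
  calls$gt_A1 <- as.integer(carrier * hom)
  calls$gt_A2 <- as.integer(carrier * hom)
  calls$gt_A2[6] <- hom                       # A1/A2 disagree at variant 6
  calls$gt_CTRL <- 0L
  calls$gt_SIRE <- as.integer(carrier * 1L)
  calls$gt_U1 <- 0L
  regions <- tibble::tibble(chrom = "chr1", start = 1000L, end = 500000L,
                            peak_lod = 5, peak_marker = "M1", n_markers = 3L)
  known <- tibble::tibble(chrom = "chr1", pos = 5310L,
                          ref = variants$ref[4], alt = "A")
  aff_sire <- mode == "dominant"
  pedigree <- tibble::tibble(
    id = c("SIRE", "A1", "A2", "CTRL", "U1"),
    affected = c(aff_sire, TRUE, TRUE, FALSE, FALSE))
  if (mode == "recessive") calls$gt_SIRE <- as.integer(carrier * 1L)
  list(genome = genome, calls = calls, regions = regions, known = known,
       pedigree = pedigree)
}

test_that("the cascade isolates the planted causative missense variant", {
  fx <- cascade_fixture("dominant")
  cs <- filter_cascade(fx$calls, affected = c("A1", "A2"), controls = "CTRL",
                       mode = "dominant", regions = fx$regions,
                       known_snps = fx$known, genome = fx$genome,
                       pedigree = fx$pedigree)
  expect_equal(nrow(cs$final), 1)
  expect_equal(cs$final$pos, 5301L)
  expect_equal(cs$final$class, "missense")
  expect_equal(cs$stages$criterion[4],
               "protein-disrupting (missense/nonsense)")
  expect_true(all(diff(c(cs$stages$n_before[1], cs$stages$n_after)) <= 0))
  # stage audit: inheritance removes the discordant variant, region the
  # off-chromosome one, known-SNP the polymorphism, consequence the
  # synonymous and intergenic ones
  expect_equal(cs$stages$n_after, c(5L, 4L, 3L, 1L, 1L))
})

test_that("a causative variant present in the known list is filtered out", {
  fx <- cascade_fixture("dominant")
  known2 <- dplyr::bind_rows(fx$known,
                             tibble::tibble(chrom = "chr1", pos = 5301L,
                                            ref = "Z", alt = "T"))
  cs <- filter_cascade(fx$calls, c("A1", "A2"), "CTRL", "dominant",
                       fx$regions, known2, fx$genome, fx$pedigree)
  expect_equal(nrow(cs$final), 0)
  # matching ignores the reference encoding (chrom + pos + alt)
  expect_equal(cs$stages$n_after[3], 2L)
})

test_that("the recessive mode requires homozygous-alternate affecteds", {
  fx <- cascade_fixture("recessive")
  cs <- filter_cascade(fx$calls, c("A1", "A2"), "CTRL", "recessive",
                       fx$regions, fx$known, fx$genome, fx$pedigree)
  expect_equal(nrow(cs$final), 1)
  expect_equal(cs$final$pos, 5301L)
  # het affecteds fail recessive stage 1
  calls_het <- fx$calls
  calls_het$gt_A1 <- pmin(calls_het$gt_A1, 1L)
  cs2 <- filter_cascade(calls_het, c("A1", "A2"), "CTRL", "recessive",
                        fx$regions, fx$known, fx$genome, fx$pedigree)
  expect_equal(cs2$stages$n_after[1], 0L)
})

test_that("stage order does not change the final set", {
  fx <- cascade_fixture("dominant")
  cs <- filter_cascade(fx$calls, c("A1", "A2"), "CTRL", "dominant",
                       fx$regions, fx$known, fx$genome, fx$pedigree)
  # recompute each criterion independently and intersect in reverse order
  calls <- fx$calls
  ann <- consequence_annotate(calls[, c("chrom", "pos", "ref", "alt")],
                              fx$genome, strict_ref = FALSE)
  crit <- list(
    coseg = vapply(seq_len(nrow(calls)), function(i) {
      gvec <- stats::setNames(
        c(calls$gt_SIRE[i], calls$gt_A1[i], calls$gt_A2[i], calls$gt_CTRL[i],
          calls$gt_U1[i]), fx$pedigree$id)
      isTRUE(cosegregation_check(gvec,
        stats::setNames(fx$pedigree$affected, fx$pedigree$id),
        "dominant")$consistent)
    }, logical(1)),
    cons = ann$class %in% c("missense", "nonsense"),
    novel = !paste(calls$chrom, calls$pos, calls$alt) %in%
      paste(fx$known$chrom, fx$known$pos, fx$known$alt),
    region = calls$chrom == "chr1" & calls$pos >= 1000 &
      calls$pos <= 500000,
    inherit = calls$gt_A1 == 1L & calls$gt_A2 == 1L & calls$gt_CTRL == 0L)
  keep <- Reduce(`&`, crit)
  expect_equal(calls$pos[keep], cs$final$pos)
})

test_that("co-segregation checking counts discordances", {
  ids <- c("S", paste0("O", 1:134))
  aff <- stats::setNames(c(TRUE, rep(c(TRUE, FALSE), 67)), ids)
  g <- stats::setNames(c(1L, rep(c(1L, 0L), 67)), ids)
  cc <- cosegregation_check(g, aff, "dominant")
  expect_true(cc$consistent)
  expect_equal(cc$n_discordant, 0L)
  expect_gt(cc$n_informative, 0)
  # one unaffected carrier breaks it
  g2 <- g; g2[["O2"]] <- 1L
  cc2 <- cosegregation_check(g2, aff, "dominant")
  expect_false(cc2$consistent)
  expect_equal(cc2$n_discordant, 1L)
  # vacuous case: all unaffected non-carriers
  cc3 <- cosegregation_check(stats::setNames(c(0L, 0L), c("a", "b")),
                             stats::setNames(c(FALSE, FALSE), c("a", "b")),
                             "dominant")
  expect_true(cc3$consistent)
  expect_equal(cc3$n_informative, 0L)
  # all statuses unknown: uninformative flag
  cc4 <- cosegregation_check(stats::setNames(c(1L, 0L), c("a", "b")),
                             stats::setNames(c(NA, NA), c("a", "b")),
                             "dominant")
  expect_true(cc4$uninformative)
})

test_that("cascade input validation", {
  fx <- cascade_fixture("dominant")
  expect_error(filter_cascade(fx$calls, "A1", "CTRL", "dominant",
                              fx$regions, fx$known, fx$genome, fx$pedigree),
               class = "enuscreen_error")
  expect_error(filter_cascade(fx$calls, c("A1", "A2"), "CTRL", "dominant",
                              fx$regions[0, ], fx$known, fx$genome,
                              fx$pedigree),
               class = "enuscreen_error")
})
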