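# Causative-variant identification: the five-criteria filtering cascade over
# WGS-style call sets of affected and control animals, and full-pedigree
# co-segregation checking.

#' Five-criteria causative-variant filtering cascade
#'
#' Filters candidate variants in order: (1) inheritance pattern (dominant:
#' heterozygous in every affected and absent from every control; recessive:
#' homozygous-alternate in every affected and not homozygous-alternate in any
#' control); (2) position within a linkage region; (3) absence from the
#' known-polymorphism list (matched on chromosome, position and alternate
#' allele, tolerant of reference-encoding dialects); (4) protein-disrupting
#' consequence (missense or nonsense; UTR and near-splice variants are kept
#' in an advisory secondary list, not the final set); (5) complete
#' co-segregation with the phenotype over the full genotyped pedigree.
#' Because every stage is a pure intersection, the final set is independent
#' of stage order; the printed order is kept for the per-stage audit counts.
#'
#' @param calls Call-set tibble: `chrom`, `pos`, `ref`, `alt` plus genotype
#'   columns `gt_<id>` (0/1/2), as from [emulate_wgs_calls()].
#' @param affected,controls Ids of the sequenced affected (at least 2) and
#'   control (at least 1) individuals.
#' @param mode `"dominant"` or `"recessive"`.
#' @param regions Linkage-region tibble from [extract_regions()].
#' @param known_snps Known-polymorphism tibble (`chrom`, `pos`, `alt`).
#' @param genome A `genome_model` carrying sequence for consequence
#'   annotation.
#' @param pedigree Pedigree tibble with `id` and `affected` for the
#'   co-segregation stage; genotypes are taken from the `gt_<id>` columns
#'   present in `calls` (individuals without a column are treated as
#'   ungenotyped).
#' @return List of class `candidate_set`: `stages` (tibble `stage`,
#'   `criterion`, `n_before`, `n_after`), `final` (annotated tibble),
#'   `advisory` (UTR / near-splice variants surviving stages 1-3).
#' @export
filter_cascade <- function(calls, affected, controls,
                           mode = c("dominant", "recessive"),
                           regions, known_snps, genome, pedigree) {
  mode <- match.arg(mode)
  if (length(affected) < 2) {
    abort("need call sets for at least two affected individuals",
          class = "enuscreen_error")
  }
  if (length(controls) < 1) {
    abort("need at least one control call set", class = "enuscreen_error")
  }
  if (nrow(regions) == 0) {
    abort("no linkage regions supplied", class = "enuscreen_error")
  }
  gt <- function(id) calls[[paste0("gt_", id)]]
  stages <- list()
  note <- function(name, before, after) {
    stages[[length(stages) + 1]] <<- tibble(
      stage = length(stages) + 1L, criterion = name,
      n_before = before, n_after = after)
  }

  cur <- calls
  # stage 1: inheritance pattern among sequenced animals
  aff_gt <- do.call(cbind, lapply(affected, function(id) gt(id)))
  ctl_gt <- do.call(cbind, lapply(controls, function(id) gt(id)))
  ok <- if (mode == "dominant") {
    rowSums(aff_gt == 1L) == length(affected) & rowSums(ctl_gt == 0L) ==
      length(controls)
  } else {
    rowSums(aff_gt == 2L) == length(affected) & rowSums(ctl_gt == 2L) == 0L
  }
  nxt <- cur[ok, ]
  note(paste0("inheritance (", mode, ")"), nrow(cur), nrow(nxt))
  cur <- nxt

  # stage 2: inside a linkage region
  in_region <- vapply(seq_len(nrow(cur)), function(i)
    any(regions$chrom == cur$chrom[i] & cur$pos[i] >= regions$start &
          cur$pos[i] <= regions$end), logical(1))
  nxt <- cur[in_region, ]
  note("within linkage interval", nrow(cur), nrow(nxt))
  cur <- nxt

  # stage 3: not a known polymorphism (chrom + pos + alt)
  if (nrow(cur) > 0 && nrow(known_snps) > 0) {
    known_key <- paste(known_snps$chrom, known_snps$pos, known_snps$alt)
    novel <- !paste(cur$chrom, cur$pos, cur$alt) %in% known_key
  } else novel <- rep(TRUE, nrow(cur))
  nxt <- cur[novel, ]
  note("absent from known polymorphisms", nrow(cur), nrow(nxt))
  cur <- nxt

  # stage 4: protein-disrupting consequence
  ann <- consequence_annotate(cur[, c("chrom", "pos", "ref", "alt")],
                              genome, strict_ref = FALSE)
  disrupt <- ann$class %in% c("missense", "nonsense")
  advisory_pool <- cur[ann$class %in% c("utr5", "utr3") |
                         (ann$class == "intronic" & ann$near_splice), ]
  nxt <- cur[disrupt, ]
  ann_kept <- ann[disrupt, ]
  note("protein-disrupting (missense/nonsense)", nrow(cur), nrow(nxt))
  cur <- nxt

  # stage 5: complete co-segregation over the genotyped pedigree
  coseg <- vapply(seq_len(nrow(cur)), function(i) {
    gvec <- genotype_row_for(calls, cur$chrom[i], cur$pos[i], pedigree$id)
    cosegregation_check(gvec, setNames(pedigree$affected, pedigree$id),
                        mode)$consistent
  }, logical(1))
  final <- cur[coseg, ]
  note("complete co-segregation", nrow(cur), nrow(final))

  final_ann <- if (nrow(final) > 0) {
    left_join(final, ann_kept[coseg, setdiff(names(ann_kept),
                                             c("ref", "alt"))],
              by = c("chrom", "pos"))
  } else final
  structure(list(stages = bind_rows(stages), final = final_ann,
                 advisory = advisory_pool, mode = mode),
            class = "candidate_set")
}

# genotype vector at one site for the requested individuals (NA when
# the individual has no gt_ column)
genotype_row_for <- function(calls, chrom, pos, ids) {
  row <- which(calls$chrom == chrom & calls$pos == pos)[1]
  vapply(ids, function(id) {
    col <- paste0("gt_", id)
    if (col %in% names(calls)) as.integer(calls[[col]][row]) else NA_integer_
  }, integer(1))
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("<candidate_set> ", nrow(x$final), " final candidate(s), mode ",
      x$mode, "\n", sep = "")
  print(x$stages)
  invisible(x)
}

#' @rdname filter_cascade
#' @param x A `candidate_set`.
#' @param ... Unused.
#' @export
tidy.candidate_set <- function(x, ...) x$stages

#' @rdname filter_cascade
#' @export
glance.candidate_set <- function(x, ...) {
  tibble(n_input = x$stages$n_before[1], n_final = nrow(x$final),
         mode = x$mode)
}

#' Co-segregation of one variant with affection status
#'
#' Dominant: consistent iff every affected individual carries at least one
#' alternate allele and every unaffected carries none. Recessive: consistent
#' iff every affected is alternate-homozygous and no unaffected is.
#' Individuals with unknown status or missing genotype are uninformative.
#'
#' @param genotypes Named integer vector of genotypes (0/1/2, NA =
#'   ungenotyped).
#' @param affected Named logical vector of affection status (NA = unknown).
#' @param mode `"dominant"` or `"recessive"`.
#' @return Tibble: `consistent`, `n_informative`, `n_discordant`,
#'   `uninformative` (TRUE when no phenotyped+genotyped carrier information
#'   exists at all).
#' @export
cosegregation_check <- function(genotypes, affected,
                                mode = c("dominant", "recessive")) {
  mode <- match.arg(mode)
  ids <- intersect(names(genotypes), names(affected))
  if (length(ids) < 2) {
    abort("need genotypes for at least two phenotyped individuals",
          class = "enuscreen_error")
  }
  g <- genotypes[ids]
  a <- affected[ids]
  informative <- !is.na(g) & !is.na(a)
  if (!any(informative)) {
    return(tibble(consistent = NA, n_informative = 0L, n_discordant = 0L,
                  uninformative = TRUE))
  }
  g <- g[informative]; a <- a[informative]
  expected_carrier <- if (mode == "dominant") g >= 1 else g == 2
  discordant <- expected_carrier != a
  # n_informative counts individuals that actually constrain the test:
  # carriers or affecteds
  n_inf <- sum(expected_carrier | a)
  tibble(consistent = !any(discordant), n_informative = n_inf,
         n_discordant = sum(discordant), uninformative = FALSE)
}
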