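# Family-based parametric linkage analysis: marker QC, exact two-point LOD
# on screen pedigrees (including the sire-daughter backcross loop), region
# extraction, and a case-control allelic association test.
#
# The two-locus model tracks 4 haplotypes (marker allele x disease allele)
# and 16 ordered diplotypes per individual. Founder priors are
# linkage-equilibrium products of the marker allele frequency and the disease
# allele frequency q; transmission recombines with probability theta;
# penetrance applies to the disease genotype; marker genotypes are observed
# with missing entries summed over. The pedigree likelihood is computed by
# recursive conditioning on parental genotypes, the sire first, so the
# backcross loop (a G1 male who sires both a G2 female and her G3 offspring)
# is handled exactly.

#' Parametric disease model
#'
#' @param mode `"dominant"` or `"recessive"`; sets default penetrances
#'   (0,1,1) or (0,0,1).
#' @param penetrances Length-3 numeric (f0, f1, f2): probability of being
#'   affected with 0/1/2 copies of the disease allele.
#' @param q Disease allele frequency.
#' @return List of class `disease_model`.
#' @export
disease_model <- function(mode = c("dominant", "recessive"),
                          penetrances = NULL, q = 1e-4) {
  mode <- match.arg(mode)
  penetrances <- penetrances %||%
    if (mode == "dominant") c(0, 1, 1) else c(0, 0, 1)
  stopifnot(length(penetrances) == 3, all(penetrances >= 0),
            all(penetrances <= 1), q > 0, q < 1)
  structure(list(mode = mode, penetrances = penetrances, q = q),
            class = "disease_model")
}

# ---- two-locus state machinery -------------------------------------------
# haplotype h in 1:4: marker allele m = (h-1) %% 2, disease allele
# d = (h-1) %/% 2. state s in 1:16: paternal hap hp = (s-1) %/% 4 + 1,
# maternal hap hm = (s-1) %% 4 + 1.
HP <- rep(1:4, each = 4)
HM <- rep(1:4, times = 4)
M_OF_H <- (0:3) %% 2
D_OF_H <- (0:3) %/% 2
MG <- M_OF_H[HP] + M_OF_H[HM]   # marker genotype per state
DG <- D_OF_H[HP] + D_OF_H[HM]   # disease genotype per state

# gamete probability matrix: 16 states x 4 gametes at recombination theta
gamete_probs <- function(theta) {
  GP <- matrix(0, 16, 4)
  for (s in 1:16) {
    haps <- c(HP[s], HM[s])
    for (i in 1:2) for (j in 1:2) {
      g <- 1L + M_OF_H[haps[i]] + 2L * D_OF_H[haps[j]]
      GP[s, g] <- GP[s, g] + if (i == j) (1 - theta) / 2 else theta / 2
    }
  }
  GP
}

founder_prior <- function(p, q) {
  hf <- c((1 - p) * (1 - q), p * (1 - q), (1 - p) * q, p * q)
  hf[HP] * hf[HM]
}

# observation vector over the 16 states for one individual
obs_vector <- function(g, affected, pen) {
  v <- if (is.na(g)) rep(1, 16) else as.numeric(MG == g)
  if (!is.na(affected)) {
    v <- v * if (affected) pen[DG + 1] else 1 - pen[DG + 1]
  }
  v
}

# ---- exact pedigree likelihood -------------------------------------------

# Structural plan: a state-independent assignment of every nuclear family to
# the evaluation context that handles it. Each family is handled either by
# summing over an unbound founder spouse ("founder" mode, at the other
# parent) or with both parents already scalar-bound ("rel" mode, at the
# later-bound parent). Children who are themselves parents trigger recursive
# sub-plans. Unassignable families mean an unsupported pedigree structure.
plan_pedigree <- function(ped) {
  if (any(xor(is.na(ped$sire), is.na(ped$dam)))) {
    abort("individuals must have both parents or neither",
          class = "enuscreen_structure_error")
  }
  ids <- ped$id
  is_founder <- setNames(is.na(ped$sire), ids)
  nonf <- which(!is.na(ped$sire))
  fam_key <- paste(ped$sire[nonf], ped$dam[nonf])
  fams <- lapply(unique(fam_key), function(k) {
    rows <- nonf[fam_key == k]
    list(sire = ped$sire[rows[1]], dam = ped$dam[rows[1]],
         children = ped$id[rows])
  })
  pf <- lapply(setNames(ids, ids), function(id)
    which(vapply(fams, function(f) id %in% c(f$sire, f$dam), logical(1))))
  is_parent <- vapply(pf, function(x) length(x) > 0, logical(1))

  assigned <- rep(NA_integer_, length(fams))   # index of handler step
  steps <- list()
  spouse_summed <- character()

  plan_ind <- function(id, bound) {
    my_steps <- list()
    for (fi in pf[[id]]) {
      if (!is.na(assigned[fi])) next
      f <- fams[[fi]]
      other <- if (f$sire == id) f$dam else f$sire
      child_plans <- list()
      if (other %in% bound) {
        mode <- "rel"
      } else if (is_founder[[other]]) {
        mode <- "founder"
        if (other %in% spouse_summed) {
          abort("pedigree structure not supported (shared founder spouse)",
                class = "enuscreen_structure_error")
        }
        spouse_summed <<- c(spouse_summed, other)
      } else {
        next  # deferred: will be planned from `other`
      }
      assigned[fi] <<- 1L
      for (ch in f$children) {
        if (is_parent[[ch]]) {
          if (mode == "rel") {
            abort("pedigree structure not supported (nested loop)",
                  class = "enuscreen_structure_error")
          }
          child_plans[[ch]] <- plan_ind(ch, c(bound, id))
        }
      }
      my_steps[[length(my_steps) + 1]] <-
        list(fam = f, mode = mode, other = other,
             id_is_sire = f$sire == id, child_plans = child_plans)
    }
    my_steps
  }

  roots <- list()
  repeat {
    todo <- which(is.na(assigned))
    if (length(todo) == 0) break
    cand <- unique(unlist(lapply(fams[todo], function(f) c(f$sire, f$dam))))
    cand <- cand[is_founder[cand]]
    cand <- setdiff(cand, spouse_summed)
    if (length(cand) == 0) {
      abort("unsupported pedigree structure (no founder root for a loop)",
            class = "enuscreen_structure_error")
    }
    root <- cand[which.max(vapply(cand, function(x) length(pf[[x]]),
                                  numeric(1)))]
    n_before <- sum(is.na(assigned))
    steps_root <- plan_ind(root, character())
    if (sum(is.na(assigned)) == n_before) {
      abort("unsupported pedigree structure (unreachable family)",
            class = "enuscreen_structure_error")
    }
    roots[[root]] <- steps_root
  }
  lone <- ids[is_founder & !is_parent]
  list(roots = roots, lone = lone, ids = ids)
}

# ped: tibble id, sire, dam, affected; g: named list of genotypes (0/1/2/NA).
# Evaluates log10 likelihood over a whole theta grid, hoisting everything
# theta-independent: per-individual observation vectors are deduplicated into
# (genotype, affection) classes whose transmission-observation kernels
# M = GP W GP' are computed once per theta, and leaf children of a family are
# grouped by class (elementwise kernel powers).
lik_grid <- function(ped, g, dmodel, p_marker, thetas, plan = NULL) {
  plan <- plan %||% plan_pedigree(ped)
  pen <- dmodel$penetrances
  ids <- ped$id
  gvals <- vapply(ids, function(id) {
    x <- g[[id]] %||% NA_integer_
    if (is.null(x) || is.na(x)) NA_integer_ else as.integer(x)
  }, integer(1))
  affs <- ped$affected
  keys <- paste(gvals, affs)
  ukeys <- unique(keys)
  cls <- match(keys, ukeys)
  names(cls) <- ids
  obs_cls <- lapply(which(!duplicated(keys)), function(i)
    obs_vector(gvals[i], affs[i], pen))
  obs <- function(id) obs_cls[[cls[[id]]]]
  W_cls <- lapply(obs_cls, function(w) {
    W <- matrix(0, 4, 4)
    W[cbind(HP, HM)] <- w
    W
  })
  prior <- founder_prior(p_marker, dmodel$q)

  # group each planned family's leaf children by class once; each distinct
  # (class, count) pair becomes one precomputed elementwise kernel power
  pow_keys <- character(0)
  pow_cls <- integer(0)
  pow_cnt <- integer(0)
  reg_pow <- function(ci, n) {
    key <- paste0(ci, "_", n)
    i <- match(key, pow_keys)
    if (is.na(i)) {
      pow_keys <<- c(pow_keys, key)
      pow_cls <<- c(pow_cls, ci)
      pow_cnt <<- c(pow_cnt, n)
      i <- length(pow_keys)
    }
    i
  }
  group_steps <- function(steps) {
    lapply(steps, function(st) {
      leaf <- setdiff(st$fam$children, names(st$child_plans))
      lg <- table(cls[leaf])
      st$pow_idx <- if (length(lg)) {
        vapply(seq_along(lg), function(k)
          reg_pow(as.integer(names(lg)[k]), as.integer(lg[k])), integer(1))
      } else integer(0)
      st$nonleaf <- intersect(st$fam$children, names(st$child_plans))
      if (length(st$child_plans)) {
        st$child_plans <- lapply(st$child_plans, group_steps)
      }
      st
    })
  }
  roots <- lapply(plan$roots, group_steps)

  vapply(thetas, function(theta) {
    GP <- gamete_probs(theta)
    tGP <- t(GP)
    M_cls <- lapply(W_cls, function(W) GP %*% W %*% tGP) # [sire, dam]
    make_M <- function(w) {
      W <- matrix(0, 4, 4)
      W[cbind(HP, HM)] <- w
      GP %*% W %*% tGP
    }
    # elementwise kernel powers, one per registered (class, count) pair
    Mp <- lapply(seq_along(pow_cls), function(k)
      M_cls[[pow_cls[k]]]^pow_cnt[k])

    eval_down <- function(steps, id, bound_states) {
      if (all(vapply(steps, function(st) st$mode == "rel", logical(1)))) {
        v <- rep(1, 16)
        for (st in steps) {
          os <- bound_states[[st$other]]
          for (k in st$pow_idx) {
            M <- Mp[[k]]
            v <- v * (if (st$id_is_sire) M[, os] else M[os, ])
          }
        }
        v
      } else {
        vapply(1:16, function(s) eval_steps(steps, s, id, bound_states),
               numeric(1))
      }
    }

    eval_steps <- function(steps, s_id, id, bound_states) {
      res <- 1
      for (st in steps) {
        if (st$mode == "rel") {
          os <- bound_states[[st$other]]
          ss <- if (st$id_is_sire) s_id else os
          ds <- if (st$id_is_sire) os else s_id
          for (k in st$pow_idx) res <- res * Mp[[k]][ss, ds]
        } else {
          po <- prior * obs(st$other)
          rowprod <- rep(1, 16)
          for (k in st$pow_idx) {
            M <- Mp[[k]]
            rowprod <- rowprod * (if (st$id_is_sire) M[s_id, ] else M[, s_id])
          }
          for (ch in st$nonleaf) {
            dvec <- eval_down(st$child_plans[[ch]], ch,
                              c(bound_states, setNames(s_id, id)))
            M <- make_M(obs(ch) * dvec)
            rowprod <- rowprod * (if (st$id_is_sire) M[s_id, ] else M[, s_id])
          }
          res <- res * sum(po * rowprod)
        }
      }
      res
    }

    total <- 1
    for (root in names(roots)) {
      po <- prior * obs(root)
      comp <- sum(vapply(1:16, function(s)
        po[s] * eval_steps(roots[[root]], s, root, numeric(0)),
        numeric(1)))
      total <- total * comp
    }
    for (id in plan$lone) total <- total * sum(prior * obs(id))
    if (total <= 0) -Inf else log10(total)
  }, numeric(1))
}

# single-theta convenience wrapper
pedigree_log10_lik <- function(ped, g, dmodel, p_marker, theta, plan = NULL) {
  lik_grid(ped, g, dmodel, p_marker, theta, plan)
}

#' Exact two-point parametric LOD score at one marker
#'
#' LOD(theta) = log10 L(theta) / L(0.5), with L the exact joint likelihood of
#' the marker genotypes and affection status over the pedigree under the
#' disease model. Configurations incompatible with the data at a given theta
#' get the large negative sentinel -99.
#'
#' @param pedigree Tibble with columns `id`, `sire`, `dam` (NA for founders)
#'   and `affected` (logical; NA = unknown, contributing no penetrance
#'   factor).
#' @param genotypes Named integer vector (0/1/2/NA) of marker genotypes by
#'   individual id.
#' @param dmodel A [disease_model()].
#' @param marker_freq Population frequency of the counted marker allele; when
#'   `NULL`, estimated from the sample (clamped to \[0.01, 0.99\]).
#' @param theta_grid Recombination fractions to evaluate.
#' @param plan Optional precomputed pedigree evaluation plan (internal; reused
#'   across markers by [genome_scan()]).
#' @return List of class `two_point_lod`: `lod` (tibble `theta`, `lod`),
#'   `max_lod`, `theta_max`.
#' @export
two_point_lod <- function(pedigree, genotypes, dmodel,
                          marker_freq = NULL,
                          theta_grid = seq(0, 0.5, by = 0.01),
                          plan = NULL) {
  pedigree <- as_tibble(pedigree)
  plan <- plan %||% plan_pedigree(pedigree)
  if (is.null(marker_freq)) {
    gg <- unlist(genotypes)
    marker_freq <- mean(gg, na.rm = TRUE) / 2
    if (!is.finite(marker_freq)) marker_freq <- 0.5
    marker_freq <- min(max(marker_freq, 0.01), 0.99)
  }
  g <- as.list(genotypes)
  ll <- lik_grid(pedigree, g, dmodel, marker_freq, c(theta_grid, 0.5), plan)
  l_half <- ll[length(ll)]
  lods <- ifelse(is.finite(ll[-length(ll)]), ll[-length(ll)] - l_half, -99)
  i <- which.max(lods)
  structure(list(lod = tibble(theta = theta_grid, lod = lods),
                 max_lod = lods[i], theta_max = theta_grid[i],
                 marker_freq = marker_freq),
            class = "two_point_lod")
}

#' @export
print.two_point_lod <- function(x, ...) {
  cat(sprintf("<two_point_lod> max LOD %.3f at theta = %.2f\n",
              x$max_lod, x$theta_max))
  invisible(x)
}

#' Marker quality control
#'
#' Keeps a marker iff its observed call rate is at least `call_rate_min` and
#' its sample minor allele frequency at least `maf_min`.
#'
#' @param genotypes Genotype tibble as produced by [emulate_snp_array()] or
#'   [read_pedmap()]: meta columns `chrom`, `pos`, `marker_id` (and optional
#'   `freq`) plus one 0/1/2/NA column per individual.
#' @param call_rate_min,maf_min QC thresholds.
#' @return List with `genotypes` (filtered tibble) and `report` (tibble
#'   `marker_id`, `call_rate`, `maf`, `removed`, `reason`).
#' @export
qc_markers <- function(genotypes, call_rate_min = 0.90, maf_min = 0.05) {
  meta <- intersect(c("chrom", "pos", "marker_id", "freq"), names(genotypes))
  inds <- setdiff(names(genotypes), meta)
  if (nrow(genotypes) == 0) abort("empty marker table",
                                  class = "enuscreen_error")
  G <- as.matrix(genotypes[inds])
  cr <- rowMeans(!is.na(G))
  p <- rowMeans(G, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  keep <- cr >= call_rate_min & maf >= maf_min
  reason <- dplyr::case_when(
    cr < call_rate_min & maf < maf_min ~ "call_rate+maf",
    cr < call_rate_min ~ "call_rate",
    maf < maf_min ~ "maf",
    TRUE ~ NA_character_)
  report <- tibble(marker_id = genotypes$marker_id, call_rate = cr,
                   maf = maf, removed = !keep, reason = reason)
  if (!any(keep)) warn("marker QC removed every marker")
  list(genotypes = genotypes[keep, ], report = report)
}

#' Genome-wide two-point LOD scan
#'
#' Runs [two_point_lod()] at every marker of a QC'd genotype table.
#'
#' @inheritParams qc_markers
#' @inheritParams two_point_lod
#' @return Tibble of class `lod_profile`: `chrom`, `pos`, `marker_id`, `lod`
#'   (max over theta), `theta` (argmax).
#' @export
genome_scan <- function(genotypes, pedigree, dmodel,
                        theta_grid = seq(0, 0.5, by = 0.01)) {
  meta <- intersect(c("chrom", "pos", "marker_id", "freq"), names(genotypes))
  inds <- setdiff(names(genotypes), meta)
  inds <- intersect(inds, pedigree$id)
  pedigree <- as_tibble(pedigree)
  plan <- plan_pedigree(pedigree)
  res <- purrr::map_dfr(seq_len(nrow(genotypes)), function(i) {
    g <- setNames(as.integer(genotypes[i, inds]), inds)
    fr <- if ("freq" %in% meta) genotypes$freq[i] else NULL
    tl <- two_point_lod(pedigree, g, dmodel, marker_freq = fr,
                        theta_grid = theta_grid, plan = plan)
    tibble(chrom = genotypes$chrom[i], pos = genotypes$pos[i],
           marker_id = genotypes$marker_id[i],
           lod = tl$max_lod, theta = tl$theta_max)
  })
  class(res) <- c("lod_profile", class(res))
  res
}

#' Extract linkage regions from a LOD profile
#'
#' Maximal runs of markers with LOD at or above `threshold`, allowing up to
#' `merge_gap_markers` below-threshold markers inside a run. Region bounds
#' are the positions of the outermost flanking below-threshold markers (a
#' conservative support interval); when a run reaches the first or last
#' informative marker of a chromosome without such a flank, the bound
#' extends to the chromosome boundary (from `chrom_lengths` when supplied,
#' else position 1 / the outermost marker). Markers whose LOD is exactly
#' zero across the theta grid are uninformative for the mapping family (a
#' homozygous transmitting parent): they carry no evidence for or against
#' linkage, so by default they neither extend nor break a run.
#'
#' @param profile A `lod_profile` from [genome_scan()].
#' @param threshold LOD threshold declaring linkage (conventionally 3).
#' @param merge_gap_markers Below-threshold markers tolerated inside a run.
#' @param drop_uninformative Ignore markers with max LOD exactly 0 when
#'   finding runs (default TRUE).
#' @param chrom_lengths Optional named vector of chromosome lengths used for
#'   the unflanked-edge bound.
#' @return Tibble: `chrom`, `start`, `end`, `peak_lod`, `peak_marker`,
#'   `n_markers`.
#' @export
extract_regions <- function(profile, threshold = 3.0, merge_gap_markers = 2,
                            drop_uninformative = TRUE,
                            chrom_lengths = NULL) {
  purrr::map_dfr(unique(profile$chrom), function(ch) {
    d_all <- profile[profile$chrom == ch, ] |> arrange(.data$pos)
    d <- d_all
    if (drop_uninformative) d <- d[abs(d$lod) > 1e-9, ]
    if (nrow(d) == 0) return(NULL)
    above <- which(d$lod >= threshold)
    if (length(above) == 0) return(NULL)
    chrom_end <- if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths))
      chrom_lengths[[ch]] else max(d_all$pos)
    grp <- cumsum(c(1, diff(above) > merge_gap_markers + 1))
    purrr::map_dfr(split(above, grp), function(run) {
      lo <- min(run); hi <- max(run)
      start <- if (lo > 1) d$pos[lo - 1] else 1
      end <- if (hi < nrow(d)) d$pos[hi + 1] else chrom_end
      peak <- run[which.max(d$lod[run])]
      tibble(chrom = ch, start = start, end = end,
             peak_lod = d$lod[peak], peak_marker = d$marker_id[peak],
             n_markers = length(run))
    })
  })
}

#' Case-control allelic association at one marker
#'
#' Pearson chi-squared (1 df, no continuity correction) on the 2x2 table of
#' allele counts.
#'
#' @param case_genotypes,control_genotypes Integer 0/1/2 genotype vectors
#'   (NA dropped).
#' @return Tibble: `chisq`, `df`, `p_value`, allele counts, plus a `flag`
#'   when a zero margin makes the statistic undefined.
#' @export
allelic_association <- function(case_genotypes, control_genotypes) {
  ca <- case_genotypes[!is.na(case_genotypes)]
  co <- control_genotypes[!is.na(control_genotypes)]
  if (length(ca) < 1 || length(co) < 1) {
    abort("need at least one case and one control",
          class = "enuscreen_error")
  }
  tab <- rbind(case = c(alt = sum(ca), ref = 2 * length(ca) - sum(ca)),
               control = c(alt = sum(co), ref = 2 * length(co) - sum(co)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(tibble(chisq = NA_real_, df = 1L, p_value = NA_real_,
                  case_alt = tab[1, 1], case_ref = tab[1, 2],
                  control_alt = tab[2, 1], control_ref = tab[2, 2],
                  flag = "zero margin"))
  }
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chisq <- sum((tab - E)^2 / E)
  tibble(chisq = chisq, df = 1L, p_value = pchisq(chisq, 1, lower.tail = FALSE),
         case_alt = tab[1, 1], case_ref = tab[1, 2],
         control_alt = tab[2, 1], control_ref = tab[2, 2],
         flag = NA_character_)
}

#' LOD profile plot
#'
#' @param object A `lod_profile`.
#' @param threshold Horizontal reference line (default 3).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lod_profile <- function(object, threshold = 3, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$pos / 1e6, y = .data$lod)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2,
                        colour = "firebrick") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "LOD") +
    ggplot2::theme_minimal()
}
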