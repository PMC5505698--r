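# Independent oracles and small fixtures used across the test files.

# ---- trio model oracle ----------------------------------------------------
# Full enumeration at allele granularity: each parent's genotype is an
# explicit allele pair; a transmitted allele is one of the two (probability
# 1/2 each) and flips with probability mu. This enumerates 2 (allele choice)
# x 2 (flip) per parent = 16 transmission paths per parental genotype pair,
# a finer grain than the implementation's per-genotype weights.
oracle_trio_posteriors <- function(Lf, Lm, Lc, mu, f) {
  hw <- c((1 - f)^2, 2 * f * (1 - f), f^2)
  pairs <- list(c(0, 0), c(0, 1), c(1, 1))  # allele pairs per genotype
  total <- 0; dnm <- 0; null <- 0
  # first pass: mutation-free reachability per (gf, gm, gc)
  reach0 <- array(FALSE, c(3, 3, 3))
  for (gf in 0:2) for (gm in 0:2) {
    fp <- pairs[[gf + 1]]; mp <- pairs[[gm + 1]]
    for (i in 1:2) for (j in 1:2) {
      reach0[gf + 1, gm + 1, fp[i] + mp[j] + 1] <- TRUE
    }
  }
  for (gf in 0:2) for (gm in 0:2) {
    fp <- pairs[[gf + 1]]; mp <- pairs[[gm + 1]]
    for (i in 1:2) for (fflip in 0:1) for (j in 1:2) for (mflip in 0:1) {
      pa <- 0.5 * (if (fflip) mu else 1 - mu)
      pb <- 0.5 * (if (mflip) mu else 1 - mu)
      fa <- if (fflip) 1 - fp[i] else fp[i]
      ma <- if (mflip) 1 - mp[j] else mp[j]
      gc <- fa + ma
      w <- hw[gf + 1] * hw[gm + 1] * pa * pb *
        Lf[gf + 1] * Lm[gm + 1] * Lc[gc + 1]
      total <- total + w
      if (!reach0[gf + 1, gm + 1, gc + 1]) dnm <- dnm + w
      if (fflip + mflip == 0 && gc >= 1) null <- null + w
    }
  }
  c(pp_dnm = unname(dnm / total), pp_null = unname(null / total))
}

# ---- two-locus pedigree likelihood oracle ---------------------------------
# Brute-force sum over all individuals' unordered two-locus diplotypes
# (10 states each). Haplotypes 1:4 encode (marker allele, disease allele);
# states are unordered pairs.
oracle_states <- local({
  s <- expand.grid(h1 = 1:4, h2 = 1:4)
  s[s$h1 <= s$h2, ]
})

oracle_pedigree_lik <- function(ped, g, dmodel, p, theta) {
  m_of <- (0:3) %% 2
  d_of <- (0:3) %/% 2
  hf <- c((1 - p) * (1 - dmodel$q), p * (1 - dmodel$q),
          (1 - p) * dmodel$q, p * dmodel$q)
  st <- oracle_states
  ns <- nrow(st)
  founder_pr <- hf[st$h1] * hf[st$h2] * ifelse(st$h1 == st$h2, 1, 2)
  gam <- matrix(0, ns, 4)  # gamete distribution per state
  for (k in seq_len(ns)) {
    haps <- c(st$h1[k], st$h2[k])
    for (i in 1:2) for (j in 1:2) {
      hg <- 1 + m_of[haps[i]] + 2 * d_of[haps[j]]
      gam[k, hg] <- gam[k, hg] + if (i == j) (1 - theta) / 2 else theta / 2
    }
  }
  # transmission array P(child state | sire state, dam state), precomputed
  Tarr <- array(0, c(ns, ns, ns))
  for (kc in seq_len(ns)) {
    x <- st$h1[kc]; y <- st$h2[kc]
    pr <- outer(gam[, x], gam[, y])
    if (x != y) pr <- pr + outer(gam[, y], gam[, x])
    Tarr[, , kc] <- pr
  }
  obs1 <- function(k, gobs, aff) {
    mg <- m_of[st$h1[k]] + m_of[st$h2[k]]
    dg <- d_of[st$h1[k]] + d_of[st$h2[k]]
    v <- if (is.na(gobs)) 1 else as.numeric(mg == gobs)
    if (!is.na(aff)) {
      pen <- dmodel$penetrances[dg + 1]
      v <- v * if (aff) pen else 1 - pen
    }
    v
  }
  ids <- ped$id
  n <- length(ids)
  grid <- do.call(expand.grid, rep(list(seq_len(ns)), n))
  names(grid) <- ids
  lik <- rep(1, nrow(grid))
  for (i in seq_len(n)) {
    k <- grid[[i]]
    gobs <- if (ids[i] %in% names(g)) g[[ids[i]]] else NA
    ov <- vapply(seq_len(ns), obs1, numeric(1), gobs = gobs,
                 aff = ped$affected[i])
    if (is.na(ped$sire[i])) {
      lik <- lik * founder_pr[k] * ov[k]
    } else {
      ks <- grid[[ped$sire[i]]]
      kd <- grid[[ped$dam[i]]]
      lik <- lik * Tarr[cbind(ks, kd, k)] * ov[k]
    }
  }
  sum(lik)
}

oracle_lod <- function(ped, g, dmodel, p, theta) {
  l1 <- oracle_pedigree_lik(ped, g, dmodel, p, theta)
  l0 <- oracle_pedigree_lik(ped, g, dmodel, p, 0.5)
  if (l1 <= 0) -99 else log10(l1) - log10(l0)
}

# random pedigree in the supported structural class, with genotypes
# and affection simulated by gene dropping (so data are always compatible)
random_test_pedigree <- function(n_extra, seed, mode = "dominant",
                                 backcross = FALSE) {
  withr::with_seed(seed, {
    p <- 0.3 + runif(1) * 0.4
    dmodel <- disease_model(mode, q = 0.05)
    theta_true <- runif(1, 0, 0.5)
    ids <- c("S", "D")
    ped <- tibble::tibble(id = ids, sire = NA_character_,
                          dam = NA_character_)
    # founders' haplotypes: (marker allele, disease allele)
    hap <- function() c(m = rbinom(1, 1, p), d = rbinom(1, 1, 0.2))
    haplo <- list(S = list(hap(), hap()), D = list(hap(), hap()))
    gamete <- function(par) {
      h <- haplo[[par]]
      i <- sample(1:2, 1)
      j <- if (runif(1) < theta_true) 3 - i else i
      c(m = h[[i]][["m"]], d = h[[j]][["d"]])
    }
    kids <- character(0)
    for (k in seq_len(n_extra)) {
      id <- paste0("C", k)
      haplo[[id]] <- list(gamete("S"), gamete("D"))
      ped <- dplyr::bind_rows(ped, tibble::tibble(id = id, sire = "S",
                                                  dam = "D"))
      kids <- c(kids, id)
    }
    if (backcross && n_extra >= 2) {
      # last child backcrossed to the founder sire
      bdam <- kids[length(kids)]
      id <- "B1"
      haplo[[id]] <- list(gamete("S"), gamete(bdam))
      ped <- dplyr::bind_rows(ped, tibble::tibble(id = id, sire = "S",
                                                  dam = bdam))
    }
    g <- vapply(ped$id, function(i)
      haplo[[i]][[1]][["m"]] + haplo[[i]][[2]][["m"]], numeric(1))
    dg <- vapply(ped$id, function(i)
      haplo[[i]][[1]][["d"]] + haplo[[i]][[2]][["d"]], numeric(1))
    ped$affected <- runif(nrow(ped)) < dmodel$penetrances[dg + 1]
    # hide some genotypes/phenotypes
    g[runif(length(g)) < 0.15] <- NA
    ped$affected[runif(nrow(ped)) < 0.15] <- NA
    list(ped = ped, g = g, dmodel = dmodel, p = p)
  })
}

# ---- small simulation fixtures --------------------------------------------
small_genome <- function(seed = 1, n_chrom = 2, len = 5e6, genes = 5) {
  toy_genome(n_chrom = n_chrom, chrom_length = len, genes_per_chrom = genes,
             seed = seed)
}

trio_sim_config <- function(genome, rate = 5.86e-6, seed = 1,
                            rad_fraction = 0.05) {
  sim_config(genome, rate = rate, n_g1 = 5, dams_per_g1 = 0,
             g2_dams_backcrossed = 0, rad_fraction = rad_fraction,
             poly_rate = 1e-4, array_marker_count = 0, seed = seed)
}

g1_trios <- function(sim) {
  g1 <- sim$pedigree$id[sim$pedigree$generation == "G1"]
  tibble::tibble(trio_id = paste0("trio_", seq_along(g1)),
                 father = "G0_1", mother = "SOW_0", child = g1)
}
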