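# Screen-design calculators: mutation-burden extrapolation, Mendelian
# segregation testing, recessive detection power, screen-yield tallies, and
# the physiological reference-range / deviant-flagging rules used in
# clinical-biochemistry and growth screening.

#' Extrapolate the genome-wide mutation burden from a per-site rate
#'
#' Scales a measured per-site induced-mutation rate to the genome-wide,
#' coding and amino-acid-changing mutation counts per G1 animal, the fold
#' increase over the spontaneous rate, and the number of G1 animals needed to
#' hit a given gene with one functional mutation. Rounding conventions are
#' chosen to reproduce the published arithmetic: burden counts are floored,
#' the per-gene animal count is rounded to the nearest ten, and the fold
#' increase is reported unrounded.
#'
#' @param rate Per-site per-gamete mutation rate (e.g. 1.63e-6 or 5.86e-6).
#' @param constants A [screen_constants()].
#' @return List of class `burden_estimate`: `rate`, `genome_mutations`,
#'   `coding_mutations`, `functional_mutations`, `fold_over_spontaneous`,
#'   `g1_per_gene` (NA with a flag when no functional mutations are
#'   expected).
#' @export
burden_extrapolation <- function(rate, constants = screen_constants()) {
  if (rate < 0) abort("rate must be >= 0", class = "enuscreen_error")
  genome_mut <- floor(rate * constants$genome_size)
  coding_mut <- floor(rate * constants$n_genes * constants$mean_cds)
  functional_mut <- floor(coding_mut * constants$aa_change_fraction)
  fold <- rate / constants$spontaneous_rate
  g1 <- if (functional_mut > 0) {
    round(constants$n_genes / functional_mut / 10) * 10
  } else NA_real_
  structure(list(rate = rate, genome_mutations = genome_mut,
                 coding_mutations = coding_mut,
                 functional_mutations = functional_mut,
                 fold_over_spontaneous = fold, g1_per_gene = g1,
                 undefined_g1 = functional_mut == 0),
            class = "burden_estimate")
}

#' @export
print.burden_estimate <- function(x, ...) {
  cat(sprintf(paste0(
    "<burden_estimate> rate %.3g /site\n",
    "  genome-wide mutations per G1: %s\n",
    "  coding mutations:             %d\n",
    "  amino-acid-changing:          %d\n",
    "  fold over spontaneous:        %.0f\n",
    "  G1 animals per gene hit:      %s\n"),
    x$rate, format(x$genome_mutations, big.mark = ","),
    x$coding_mutations, x$functional_mutations, x$fold_over_spontaneous,
    if (x$undefined_g1) "undefined" else format(x$g1_per_gene)))
  invisible(x)
}

#' @rdname burden_extrapolation
#' @param x A `burden_estimate`.
#' @param ... Unused.
#' @export
tidy.burden_estimate <- function(x, ...) {
  tibble(rate = x$rate, genome_mutations = x$genome_mutations,
         coding_mutations = x$coding_mutations,
         functional_mutations = x$functional_mutations,
         fold_over_spontaneous = x$fold_over_spontaneous,
         g1_per_gene = x$g1_per_gene)
}

#' Chi-squared test of a Mendelian segregation ratio
#'
#' Pearson chi-squared (1 df) of an observed affected count against an
#' expected segregation ratio (1/2 for a dominant outcross, 1/4 for a
#' recessive backcross intercross).
#'
#' @param n_affected,n_total Observed counts.
#' @param expected_ratio Expected affected fraction, in (0, 1).
#' @return Tibble: `chisq`, `df`, `p_value`, `observed_ratio`.
#' @export
segregation_chi2 <- function(n_affected, n_total, expected_ratio) {
  stopifnot(expected_ratio > 0, expected_ratio < 1)
  if (n_total <= 0) abort("n_total must be positive",
                          class = "enuscreen_error")
  if (n_affected < 0 || n_affected > n_total) {
    abort("n_affected must lie in [0, n_total]", class = "enuscreen_error")
  }
  obs <- c(n_affected, n_total - n_affected)
  exp <- n_total * c(expected_ratio, 1 - expected_ratio)
  chisq <- sum((obs - exp)^2 / exp)
  tibble(chisq = chisq, df = 1L,
         p_value = pchisq(chisq, 1, lower.tail = FALSE),
         observed_ratio = n_affected / n_total)
}

#' Detection power of the backcross design for a recessive mutation
#'
#' Each G2 dam inherits the G1 sire's variant with probability 1/2; each
#' backcross offspring of a carrier dam is affected with probability
#' penetrance/4. The screen detects the mutation iff at least one affected
#' G3 appears, so
#' P(detect) = 1 - \[1/2 + 1/2 (1 - penetrance/4)^offspring\]^dams.
#'
#' @param n_backcrossed_dams Number of G2 dams backcrossed to the G1 sire.
#' @param offspring_per_dam G3 offspring per dam.
#' @param penetrance Penetrance of the homozygous phenotype.
#' @return Detection probability.
#' @export
recessive_power <- function(n_backcrossed_dams, offspring_per_dam,
                            penetrance = 1) {
  stopifnot(n_backcrossed_dams >= 0, offspring_per_dam >= 0,
            penetrance >= 0, penetrance <= 1)
  per_dam_miss <- 0.5 + 0.5 * (1 - penetrance / 4)^offspring_per_dam
  1 - per_dam_miss^n_backcrossed_dams
}

#' Tally screen yield
#'
#' Summarises a screen's mutant-line table: lines per pedigree, the dominant
#' mutant frequency among screened G1, and the confirmed fraction. Display
#' values are rounded to one decimal (rate) and one decimal percent
#' (frequencies); exact ratios are returned alongside.
#'
#' @param lines Tibble with one row per mutant line; optional logical column
#'   `confirmed`.
#' @param n_pedigrees Number of pedigrees screened.
#' @param n_g1_screened Optional count of screened G1 animals (for the
#'   dominant frequency).
#' @return Tibble with exact and display-rounded summary columns.
#' @export
screen_tally <- function(lines, n_pedigrees, n_g1_screened = NULL) {
  if (n_pedigrees <= 0) abort("n_pedigrees must be positive",
                              class = "enuscreen_error")
  n_lines <- nrow(lines)
  rate <- n_lines / n_pedigrees
  confirmed <- if ("confirmed" %in% names(lines)) sum(lines$confirmed) else NA
  conf_frac <- if (!is.na(confirmed) && n_lines > 0) confirmed / n_lines
    else NA_real_
  dom_freq <- if (!is.null(n_g1_screened)) n_lines / n_g1_screened
    else NA_real_
  tibble(
    n_lines = n_lines, n_pedigrees = n_pedigrees,
    lines_per_pedigree = rate,
    lines_per_pedigree_display = round(rate, 1),
    n_confirmed = confirmed,
    confirmed_fraction = conf_frac,
    confirmed_pct_display = if (is.na(conf_frac)) NA_real_
      else round(100 * conf_frac, 1),
    dominant_frequency = dom_freq,
    dominant_pct_display = if (is.na(dom_freq)) NA_real_
      else round(100 * dom_freq, 1)
  )
}

#' Physiological reference range of a clinical parameter
#'
#' Eliminates outliers (iteratively beyond 3 SD until stable, or by the
#' 1.5 IQR rule), then reports the trimmed mean and SD, the 95% physiological
#' range (2.5th-97.5th percentile of retained values) and the deviant cut-off
#' at mean +/- 2 SD.
#'
#' @param values Numeric measurements from at least 10 animals of one
#'   sex/generation stratum.
#' @param parameter Parameter label.
#' @param trim Outlier-elimination strategy: `"sd3"` (default) or `"iqr"`.
#' @return List of class `reference_range`: `parameter`, `n`, `n_trimmed`,
#'   `mean`, `sd`, `low`, `high` (95% range), `cutoff_low`, `cutoff_high`
#'   (mean +/- 2 SD), `degenerate` flag when SD is 0.
#' @export
reference_range <- function(values, parameter = "parameter",
                            trim = c("sd3", "iqr")) {
  trim <- match.arg(trim)
  values <- values[!is.na(values)]
  if (length(values) < 10) {
    abort("need at least 10 values to build a reference range",
          class = "enuscreen_error")
  }
  kept <- values
  if (trim == "sd3") {
    repeat {
      m <- mean(kept); s <- sd(kept)
      if (s == 0) break
      keep <- abs(kept - m) <= 3 * s
      if (all(keep)) break
      kept <- kept[keep]
    }
  } else {
    qs <- quantile(kept, c(0.25, 0.75), names = FALSE)
    iqr <- qs[2] - qs[1]
    kept <- kept[kept >= qs[1] - 1.5 * iqr & kept <= qs[2] + 1.5 * iqr]
  }
  m <- mean(kept); s <- sd(kept)
  rng <- quantile(kept, c(0.025, 0.975), names = FALSE)
  structure(list(parameter = parameter, n = length(values),
                 n_trimmed = length(values) - length(kept),
                 mean = m, sd = s, low = rng[1], high = rng[2],
                 cutoff_low = m - 2 * s, cutoff_high = m + 2 * s,
                 degenerate = s == 0),
            class = "reference_range")
}

#' @export
print.reference_range <- function(x, ...) {
  cat(sprintf(
    "<reference_range> %s: n=%d (%d trimmed), mean %.3g, sd %.3g, 95%% range [%.3g, %.3g], cutoff mean+/-2SD [%.3g, %.3g]%s\n",
    x$parameter, x$n, x$n_trimmed, x$mean, x$sd, x$low, x$high,
    x$cutoff_low, x$cutoff_high,
    if (x$degenerate) " [degenerate: sd = 0]" else ""))
  invisible(x)
}

#' Flag phenotypic deviants against a reference range
#'
#' An individual is flagged deviant iff its first measurement deviates from
#' the trimmed mean by strictly more than 2 SD and at least `n_confirm - 1`
#' repeat measurements do too (mirroring the repeat-confirmation rule of the
#' screening pipeline). A degenerate range (SD 0) flags nobody.
#'
#' @param measurements Tibble with columns `id`, `value` and optional
#'   `repeat_values` (list-column of repeat measurements per individual).
#' @param range A [reference_range()].
#' @param n_confirm Total number of deviating measurements required
#'   (first + repeats).
#' @return The input with logical columns `first_deviant`, `confirmed`.
#' @export
flag_deviants <- function(measurements, range, n_confirm = 3) {
  measurements <- as_tibble(measurements)
  # strict exceedance; the relative guard keeps a value computed as exactly
  # mean + 2 SD on the non-deviant side of the boundary
  dev <- function(v) !range$degenerate &
    abs(v - range$mean) > 2 * range$sd * (1 + 1e-9)
  first <- dev(measurements$value)
  confirmed <- vapply(seq_len(nrow(measurements)), function(i) {
    if (!first[i]) return(FALSE)
    reps <- if ("repeat_values" %in% names(measurements))
      measurements$repeat_values[[i]] else numeric(0)
    sum(dev(reps)) >= n_confirm - 1
  }, logical(1))
  measurements$first_deviant <- first
  measurements$confirmed <- confirmed
  measurements
}

#' Mutant-vs-control comparison helper
#'
#' Reports a mutant group mean as a percentage of the control mean (e.g.
#' blood glucose of hyperglycemic mutants vs wild-type).
#'
#' @param mutant,control Numeric vectors (or scalars) of measurements.
#' @return Tibble: `mutant_mean`, `control_mean`, `ratio_pct`.
#' @export
compare_to_reference <- function(mutant, control) {
  mm <- mean(mutant); cm <- mean(control)
  tibble(mutant_mean = mm, control_mean = cm, ratio_pct = 100 * mm / cm)
}
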