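# Substitution-spectrum classification and summaries.
#
# Substitutions are reported in the strand-collapsed six-class representation
# (complementary changes share a class, e.g. G>A and C>T are both G:C>A:T);
# transitions are the purine<->purine / pyrimidine<->pyrimidine classes.

#' Classify a single-base substitution
#'
#' @param ref,alt Reference and alternate bases (vectors of single characters
#'   in A/C/G/T; recycled to common length).
#' @return A tibble with columns `class` (strand-collapsed, one of the six
#'   substitution classes) and `is_transition`.
#' @export
classify_substitution <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (any(!ref %in% c("A", "C", "G", "T")) ||
      any(!alt %in% c("A", "C", "G", "T"))) {
    abort("ref and alt must be single bases in {A,C,G,T}",
          class = "enuscreen_error")
  }
  if (any(ref == alt)) {
    abort("ref and alt must differ", class = "enuscreen_error")
  }
  # collapse onto the A/G reference representative
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  flip <- ref %in% c("C", "T")
  r <- ifelse(flip, comp[ref], ref)
  a <- ifelse(flip, comp[alt], alt)
  cls <- dplyr::case_when(
    r == "A" & a == "G" ~ "A:T>G:C",
    r == "G" & a == "A" ~ "G:C>A:T",
    r == "A" & a == "C" ~ "A:T>C:G",
    r == "A" & a == "T" ~ "A:T>T:A",
    r == "G" & a == "C" ~ "G:C>C:G",
    r == "G" & a == "T" ~ "G:C>T:A"
  )
  tibble(class = cls, is_transition = cls %in% transition_classes)
}

#' Summarise the substitution spectrum of a variant set
#'
#' Counts variants by strand-collapsed substitution class and, when a genome
#' with gene models is supplied, by genomic region (exon = any CDS consequence,
#' plus UTRs, introns and intergenic space).
#'
#' @param variants Data frame with `ref`, `alt` columns (and `chrom`, `pos`
#'   when region annotation is requested).
#' @param genome Optional `genome_model` for region annotation.
#' @return A list of class `spectrum_summary` with elements `class_counts`
#'   (tibble class/count/fraction), `transition_fraction`,
#'   `transversion_fraction`, `n`, and `region_counts` (tibble or `NULL`).
#' @export
summarize_spectrum <- function(variants, genome = NULL) {
  variants <- as_tibble(variants)
  n <- nrow(variants)
  if (n == 0) {
    cc <- tibble(class = spectrum_classes, count = 0L, fraction = NA_real_)
    res <- list(class_counts = cc, transition_fraction = NA_real_,
                transversion_fraction = NA_real_, n = 0L,
                region_counts = NULL, degenerate = TRUE)
    return(structure(res, class = "spectrum_summary"))
  }
  cls <- classify_substitution(variants$ref, variants$alt)
  tab <- table(factor(cls$class, levels = spectrum_classes))
  cc <- tibble(class = spectrum_classes, count = as.integer(tab)) |>
    mutate(fraction = .data$count / n)
  ts <- sum(cc$count[cc$class %in% transition_classes]) / n
  region_counts <- NULL
  if (!is.null(genome) && !is.null(genome$genes)) {
    ann <- consequence_annotate(variants, genome, strict_ref = FALSE)
    region <- dplyr::case_when(
      ann$class %in% c("synonymous", "missense", "nonsense") ~ "exon",
      ann$class == "intronic" ~ "intron",
      TRUE ~ ann$class
    )
    lev <- c("intergenic", "intron", "exon", "utr5", "utr3")
    tab <- as.integer(table(factor(region, lev)))
    region_counts <- tibble(region = lev, count = tab)
  }
  structure(list(class_counts = cc, transition_fraction = ts,
                 transversion_fraction = 1 - ts, n = n,
                 region_counts = region_counts, degenerate = FALSE),
            class = "spectrum_summary")
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat("<spectrum_summary> n =", x$n, "\n")
  if (x$n > 0) {
    cat(sprintf("  transitions %.1f%% / transversions %.1f%%\n",
                100 * x$transition_fraction, 100 * x$transversion_fraction))
  }
  print(x$class_counts)
  if (!is.null(x$region_counts)) print(x$region_counts)
  invisible(x)
}

#' @rdname summarize_spectrum
#' @param x A `spectrum_summary`.
#' @param ... Unused.
#' @export
tidy.spectrum_summary <- function(x, ...) x$class_counts

#' @rdname summarize_spectrum
#' @export
glance.spectrum_summary <- function(x, ...) {
  tibble(n = x$n, transition_fraction = x$transition_fraction,
         transversion_fraction = x$transversion_fraction)
}

#' Bar plot of a substitution spectrum
#'
#' @param object A `spectrum_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spectrum_summary <- function(object, ...) {
  ggplot2::ggplot(object$class_counts,
                  ggplot2::aes(x = .data$class, y = .data$fraction,
                               fill = .data$class %in% transition_classes)) +
    ggplot2::geom_col(show.legend = TRUE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "grey40"),
                               name = "transition") +
    ggplot2::labs(x = NULL, y = "fraction of mutations") +
    ggplot2::theme_minimal()
}
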