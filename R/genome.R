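#' Build a genome model
#'
#' A genome model bundles everything the simulator and the annotator need to
#' know about the (toy or full-scale) genome: chromosome sizes, gene models,
#' a uniform recombination rate, and optionally sequence. Sequence can be
#' supplied either as full chromosome strings or as per-gene spliced CDS
#' strings; consequence annotation works with either.
#'
#' @param chromosomes Data frame with columns `name` and `length` (bp).
#' @param genes Optional data frame of gene models with columns `gene_id`,
#'   `chrom`, `strand` (`"+"`/`"-"`), and a list-column `cds` of two-column
#'   data frames (`start`, `end`; 1-based inclusive, sorted, non-overlapping;
#'   always in genomic, i.e. ascending, coordinate order regardless of
#'   strand). Optional list-columns `utr5`, `utr3` in the same shape and an
#'   optional character column `cds_seq` holding the spliced CDS in
#'   transcription order (5'->3' on the coding strand).
#' @param recomb_rate Uniform recombination rate in centimorgan per megabase.
#' @param sequence Optional named character vector of full chromosome
#'   sequences (names matching chromosome names).
#'
#' @return An object of class `genome_model`.
#' @export
genome_model <- function(chromosomes, genes = NULL, recomb_rate = 1,
                         sequence = NULL) {
  chromosomes <- as_tibble(chromosomes)
  stopifnot(all(c("name", "length") %in% names(chromosomes)))
  chromosomes$name <- as.character(chromosomes$name)
  if (any(chromosomes$length <= 0)) {
    abort("chromosome lengths must be > 0", class = "enuscreen_error")
  }
  if (anyDuplicated(chromosomes$name)) {
    abort("duplicated chromosome names", class = "enuscreen_error")
  }
  if (!is.null(genes)) {
    genes <- as_tibble(genes)
    stopifnot(all(c("gene_id", "chrom", "strand", "cds") %in% names(genes)))
    for (col in c("utr5", "utr3")) {
      if (!col %in% names(genes)) genes[[col]] <- rep(list(NULL), nrow(genes))
    }
    chrom_len <- setNames(chromosomes$length, chromosomes$name)
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      if (!g$chrom %in% names(chrom_len)) {
        abort(paste0("gene ", g$gene_id, " on unknown chromosome ", g$chrom),
              class = "enuscreen_coordinate_error")
      }
      cds <- g$cds[[1]]
      stopifnot(is.data.frame(cds), all(c("start", "end") %in% names(cds)))
      if (is.unsorted(cds$start, strictly = TRUE) && nrow(cds) > 1) {
        abort(paste0("gene ", g$gene_id, ": CDS intervals must be sorted"),
              class = "enuscreen_error")
      }
      if (any(cds$end < cds$start) ||
          (nrow(cds) > 1 && any(cds$start[-1] <= cds$end[-nrow(cds)]))) {
        abort(paste0("gene ", g$gene_id, ": CDS intervals overlap or are inverted"),
              class = "enuscreen_error")
      }
      span <- gene_span(g)
      if (span[1] < 1 || span[2] > chrom_len[[g$chrom]]) {
        abort(paste0("gene ", g$gene_id, " outside chromosome ", g$chrom),
              class = "enuscreen_coordinate_error")
      }
      cds_len <- sum(cds$end - cds$start + 1)
      has_seq <- (!is.null(sequence) && g$chrom %in% names(sequence)) ||
        ("cds_seq" %in% names(genes) && !is.na(g$cds_seq))
      if (has_seq && cds_len %% 3 != 0) {
        abort(paste0("gene ", g$gene_id, ": CDS length ", cds_len,
                     " is not a multiple of 3"), class = "enuscreen_error")
      }
      if ("cds_seq" %in% names(genes) && !is.na(g$cds_seq) &&
          nchar(g$cds_seq) != cds_len) {
        abort(paste0("gene ", g$gene_id, ": cds_seq length disagrees with intervals"),
              class = "enuscreen_error")
      }
    }
  }
  structure(
    list(chromosomes = chromosomes, genes = genes,
         recomb_rate = recomb_rate, sequence = sequence),
    class = "genome_model"
  )
}

#' @export
print.genome_model <- function(x, ...) {
  cat("<genome_model> ", nrow(x$chromosomes), " chromosome(s), ",
      sum(x$chromosomes$length), " bp, ",
      if (is.null(x$genes)) 0L else nrow(x$genes), " gene(s), ",
      x$recomb_rate, " cM/Mb\n", sep = "")
  invisible(x)
}

# total genomic span of a gene row (min/max over all annotated intervals)
gene_span <- function(g) {
  ivs <- bind_rows(g$cds[[1]], g$utr5[[1]], g$utr3[[1]])
  c(min(ivs$start), max(ivs$end))
}

#' Fixed biological constants of the screen arithmetic
#'
#' Container for the constants used by the burden-extrapolation model: genome
#' size, number of coding genes, mean CDS length, the fraction of coding
#' mutations that change an amino acid, the spontaneous per-site per-generation
#' mutation rate, and the per-site induced-mutation rates measured at the two
#' ENU doses.
#'
#' @param genome_size Genome size in bp.
#' @param n_genes Number of protein-coding genes.
#' @param mean_cds Mean coding sequence length per gene, bp.
#' @param aa_change_fraction Fraction of coding mutations changing an amino
#'   acid; in (0, 1].
#' @param spontaneous_rate Spontaneous mutation rate per site per generation.
#' @param dose_rates Named numeric vector mapping dose labels (mg/kg) to
#'   per-site induced mutation rates.
#' @return A list of class `screen_constants`.
#' @export
screen_constants <- function(genome_size = 2.81e9,
                             n_genes = 2.2e4,
                             mean_cds = 1.6e3,
                             aa_change_fraction = 0.55,
                             spontaneous_rate = 1.2e-8,
                             dose_rates = c("65" = 1.63e-6, "85" = 5.86e-6)) {
  vals <- c(genome_size, n_genes, mean_cds, aa_change_fraction,
            spontaneous_rate, dose_rates)
  if (any(vals <= 0)) abort("screen constants must be strictly positive",
                            class = "enuscreen_error")
  if (aa_change_fraction > 1) abort("aa_change_fraction must be in (0, 1]",
                                    class = "enuscreen_error")
  structure(list(genome_size = genome_size, n_genes = n_genes,
                 mean_cds = mean_cds, aa_change_fraction = aa_change_fraction,
                 spontaneous_rate = spontaneous_rate, dose_rates = dose_rates),
            class = "screen_constants")
}

#' Generate a toy genome for simulation
#'
#' Builds a small multi-chromosome genome with randomly placed,
#' non-overlapping genes. Each gene gets a random spliced CDS sequence (so
#' that coding consequences can be annotated without carrying full chromosome
#' sequence) split over one to three exons.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Length of every chromosome, bp.
#' @param genes_per_chrom Genes placed per chromosome.
#' @param cds_length Total CDS length per gene, bp (multiple of 3).
#' @param recomb_rate Recombination rate, cM/Mb.
#' @param seed Integer seed.
#' @return A `genome_model`.
#' @export
toy_genome <- function(n_chrom = 5, chrom_length = 2e7, genes_per_chrom = 20,
                       cds_length = 999, recomb_rate = 1, seed = 1) {
  stopifnot(cds_length %% 3 == 0)
  chroms <- tibble(name = paste0("chr", seq_len(n_chrom)),
                   length = rep(chrom_length, n_chrom))
  genes <- with_seed(seed, {
    purrr::map_dfr(chroms$name, function(ch) {
      # lay genes on a grid so they never overlap
      slot <- floor(chrom_length / genes_per_chrom)
      purrr::map_dfr(seq_len(genes_per_chrom), function(i) {
        g_start <- (i - 1L) * slot +
          sample.int(slot - cds_length - 2000L, 1L) + 1000L
        n_exon <- sample(1:3, 1L)
        exon_len <- diff(round(seq(0, cds_length, length.out = n_exon + 1)))
        # keep each exon a sensible size and total exact
        starts <- g_start + cumsum(c(0L, head(exon_len, -1) + 500L))
        cds <- tibble(start = starts, end = starts + exon_len - 1L)
        tibble(
          gene_id = sprintf("%s_g%02d", ch, i),
          chrom = ch,
          strand = sample(c("+", "-"), 1L),
          cds = list(cds),
          utr5 = list(NULL), utr3 = list(NULL),
          cds_seq = paste(sample(c("A", "C", "G", "T"), cds_length,
                                 replace = TRUE), collapse = "")
        )
      })
    })
  })
  genome_model(chroms, genes, recomb_rate = recomb_rate)
}
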