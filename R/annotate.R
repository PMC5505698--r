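# Codon-aware consequence annotation.
#
# Coordinates are 1-based inclusive throughout (matching c.-notation and
# VCF/GFF3); variants are always expressed on the plus strand. Precedence when
# a position carries several annotations: CDS > UTR > intron > intergenic;
# among overlapping genes the alphabetically first gene_id is reported and all
# hits are kept in `other_genes`.

# flattened interval table: one row per (gene, feature interval), introns
# derived as the gaps between annotated intervals inside the gene span
region_table <- function(genome) {
  genes <- genome$genes
  if (is.null(genes) || nrow(genes) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  gene_id = character(), type = character()))
  }
  purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    ivs <- bind_rows(
      mutate(g$cds[[1]], type = "cds"),
      if (!is.null(g$utr5[[1]])) mutate(g$utr5[[1]], type = "utr5"),
      if (!is.null(g$utr3[[1]])) mutate(g$utr3[[1]], type = "utr3")
    ) |> arrange(.data$start)
    introns <- NULL
    if (nrow(ivs) > 1) {
      gap_start <- ivs$end[-nrow(ivs)] + 1
      gap_end <- ivs$start[-1] - 1
      keep <- gap_end >= gap_start
      if (any(keep)) {
        introns <- tibble(start = gap_start[keep], end = gap_end[keep],
                          type = "intron")
      }
    }
    bind_rows(ivs, introns) |>
      mutate(chrom = g$chrom, gene_id = g$gene_id) |>
      select("chrom", "start", "end", "gene_id", "type")
  })
}

type_precedence <- c(cds = 1, utr5 = 2, utr3 = 2, intron = 3)

# spliced CDS of one gene row, 5'->3' on the coding strand
gene_cds_sequence <- function(genome, g) {
  if (!is.null(genome$sequence) && g$chrom %in% names(genome$sequence)) {
    chrseq <- genome$sequence[[g$chrom]]
    cds <- g$cds[[1]]
    s <- paste(substring(chrseq, cds$start, cds$end), collapse = "")
    if (g$strand == "-") s <- revcomp(s)
    return(s)
  }
  if ("cds_seq" %in% names(genome$genes) && !is.na(g$cds_seq)) return(g$cds_seq)
  NULL
}

revcomp <- function(s) {
  chartr("ACGTacgt", "TGCAtgca",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

complement_base <- function(b) chartr("ACGT", "TGCA", b)

# 1-based position in the spliced CDS of a genomic position (strand-aware)
cds_position_of <- function(g, pos) {
  cds <- g$cds[[1]]
  inside <- which(pos >= cds$start & pos <= cds$end)
  if (length(inside) == 0) return(NA_integer_)
  before <- if (inside > 1) sum(cds$end[seq_len(inside - 1)] -
                                  cds$start[seq_len(inside - 1)] + 1) else 0L
  plus_off <- before + (pos - cds$start[inside] + 1L)
  total <- sum(cds$end - cds$start + 1)
  if (g$strand == "+") as.integer(plus_off) else as.integer(total - plus_off + 1L)
}

#' Reference base of the genome at a position, if known
#'
#' Returns the plus-strand base from the chromosome sequence when present,
#' else from a covering gene's spliced CDS sequence, else `NA`.
#'
#' @param genome A `genome_model`.
#' @param chrom,pos Position (1-based).
#' @return Single character or `NA`.
#' @export
ref_base_at <- function(genome, chrom, pos) {
  if (!is.null(genome$sequence) && chrom %in% names(genome$sequence)) {
    return(toupper(substring(genome$sequence[[chrom]], pos, pos)))
  }
  genes <- genome$genes
  if (is.null(genes) || !"cds_seq" %in% names(genes)) return(NA_character_)
  on_chr <- genes[genes$chrom == chrom, ]
  for (i in seq_len(nrow(on_chr))) {
    g <- on_chr[i, ]
    if (is.na(g$cds_seq)) next
    cp <- cds_position_of(g, pos)
    if (!is.na(cp)) {
      b <- toupper(substring(g$cds_seq, cp, cp))
      return(if (g$strand == "+") b else complement_base(b))
    }
  }
  NA_character_
}

#' Annotate variant consequences against a genome model
#'
#' Assigns each single-nucleotide variant a consequence class
#' (`intergenic`, `intronic`, `utr5`, `utr3`, `synonymous`, `missense`,
#' `nonsense`) and, for coding classes, the CDS position, protein position and
#' amino-acid change under the standard genetic code. Stop-gains are reported
#' as `nonsense`; stop-losses fold into `missense`. Intronic positions within
#' 2 bp of a CDS edge are flagged `near_splice` rather than given a separate
#' splice class.
#'
#' @param variants Data frame with columns `chrom`, `pos`, `ref`, `alt`
#'   (plus-strand single bases).
#' @param genome A `genome_model`; coding calls require sequence (chromosome
#'   sequence or per-gene `cds_seq`).
#' @param strict_ref If `TRUE` (default), a `ref` that contradicts known
#'   sequence raises a reference-inconsistency error.
#' @return The input tibble with columns `class`, `gene_id`, `cds_position`,
#'   `protein_position`, `ref_aa`, `alt_aa`, `near_splice`, `other_genes`
#'   appended.
#' @export
consequence_annotate <- function(variants, genome, strict_ref = TRUE) {
  variants <- as_tibble(variants)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(variants)))
  chrom_len <- setNames(genome$chromosomes$length, genome$chromosomes$name)
  bad <- !variants$chrom %in% names(chrom_len) |
    variants$pos < 1 | variants$pos > chrom_len[variants$chrom]
  if (any(bad)) {
    abort(paste0(sum(bad), " variant(s) outside any chromosome"),
          class = "enuscreen_coordinate_error")
  }
  n <- nrow(variants)
  out <- variants
  out$class <- rep("intergenic", n)
  out$gene_id <- NA_character_
  out$cds_position <- NA_integer_
  out$protein_position <- NA_integer_
  out$ref_aa <- NA_character_
  out$alt_aa <- NA_character_
  out$near_splice <- FALSE
  out$other_genes <- rep(list(character()), n)
  if (n == 0) return(out)

  rt <- region_table(genome)
  if (nrow(rt) == 0) return(out)

  # all (variant, interval) hits: loop over intervals, vectorised over variants
  hits <- purrr::map_dfr(seq_len(nrow(rt)), function(j) {
    iv <- rt[j, ]
    idx <- which(variants$chrom == iv$chrom &
                   variants$pos >= iv$start & variants$pos <= iv$end)
    if (length(idx) == 0) return(NULL)
    tibble(vidx = idx, gene_id = iv$gene_id, type = iv$type,
           start = iv$start, end = iv$end)
  })
  if (nrow(hits) == 0) return(out)

  best <- hits |>
    mutate(prio = type_precedence[.data$type]) |>
    arrange(.data$vidx, .data$prio, .data$gene_id) |>
    group_by(.data$vidx) |>
    summarise(gene_id = first(.data$gene_id), type = first(.data$type),
              all_genes = list(unique(.data$gene_id)), .groups = "drop")

  genes_by_id <- genome$genes
  code <- Biostrings::GENETIC_CODE
  for (k in seq_len(nrow(best))) {
    i <- best$vidx[k]
    g <- genes_by_id[genes_by_id$gene_id == best$gene_id[k], ][1, ]
    out$gene_id[i] <- g$gene_id
    out$other_genes[[i]] <- setdiff(best$all_genes[[k]], g$gene_id)
    type <- best$type[k]
    if (type %in% c("utr5", "utr3")) {
      out$class[i] <- type
      next
    }
    if (type == "intron") {
      out$class[i] <- "intronic"
      cds <- g$cds[[1]]
      d <- min(abs(variants$pos[i] - c(cds$start, cds$end)))
      out$near_splice[i] <- d <= 2
      next
    }
    # coding
    cp <- cds_position_of(g, variants$pos[i])
    out$cds_position[i] <- cp
    out$protein_position[i] <- as.integer(ceiling(cp / 3))
    seq <- gene_cds_sequence(genome, g)
    if (is.null(seq)) {
      abort(paste0("gene ", g$gene_id,
                   " carries no sequence; cannot annotate coding consequence"),
            class = "enuscreen_error")
    }
    ref_cds <- if (g$strand == "+") toupper(variants$ref[i]) else
      complement_base(toupper(variants$ref[i]))
    alt_cds <- if (g$strand == "+") toupper(variants$alt[i]) else
      complement_base(toupper(variants$alt[i]))
    have <- toupper(substring(seq, cp, cp))
    if (have != ref_cds) {
      if (strict_ref) {
        abort(sprintf(
          "reference inconsistency at %s:%d (variant ref %s, genome %s)",
          variants$chrom[i], variants$pos[i], variants$ref[i],
          if (g$strand == "+") have else complement_base(have)),
          class = "enuscreen_ref_mismatch")
      }
    }
    codon_i <- out$protein_position[i]
    codon <- toupper(substring(seq, 3 * codon_i - 2, 3 * codon_i))
    within <- cp - (3 * codon_i - 3)
    alt_codon <- codon
    substring(alt_codon, within, within) <- alt_cds
    ref_aa <- unname(code[[codon]])
    alt_aa <- unname(code[[alt_codon]])
    out$ref_aa[i] <- ref_aa
    out$alt_aa[i] <- alt_aa
    out$class[i] <- if (ref_aa == alt_aa) "synonymous"
      else if (alt_aa == "*") "nonsense"
      else "missense"
  }
  out
}
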