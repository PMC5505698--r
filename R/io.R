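# File formats. Coordinate dialects: VCF/PED/MAP and everything internal are
# 1-based inclusive; BED output is 0-based half-open. The VCF dialect is
# deliberately minimal (SNV-only, GT/AD genotype fields) and round-trips
# byte-identically on files this package writes.

#' Read a minimal VCF (v4.2, SNV-only)
#'
#' @param path VCF file path (plain text).
#' @return Tibble: `chrom`, `pos`, `id`, `ref`, `alt`, `qual`, `filter`,
#'   `info` plus, when samples are present, genotype columns `gt_<sample>`
#'   (0/1/2, NA for `./.`) and, when the AD field is present, matrix-columns
#'   `ref_count`/`alt_count`.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1) {
    abort(paste0("malformed VCF (no #CHROM header line): ", path),
          class = "enuscreen_parse_error")
  }
  cols <- strsplit(sub("^#", "", lines[hdr]), "\t")[[1]]
  samples <- if (length(cols) > 9) cols[-(1:9)] else character()
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  if (length(body) == 0) {
    out <- tibble(chrom = character(), pos = integer(), id = character(),
                  ref = character(), alt = character(), qual = character(),
                  filter = character(), info = character())
    return(out)
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != length(cols))) {
    abort(sprintf("malformed VCF record at line %d",
                  hdr + which(nf != length(cols))[1]),
          class = "enuscreen_parse_error")
  }
  m <- do.call(rbind, fields)
  bad <- !grepl("^[ACGT]$", m[, 4]) | !grepl("^[ACGT]$", m[, 5])
  if (any(bad)) {
    abort(sprintf("only single-base SNVs supported (line %d: %s>%s)",
                  hdr + which(bad)[1], m[which(bad)[1], 4],
                  m[which(bad)[1], 5]),
          class = "enuscreen_parse_error")
  }
  out <- tibble(chrom = m[, 1], pos = as.integer(m[, 2]), id = m[, 3],
                ref = m[, 4], alt = m[, 5], qual = m[, 6], filter = m[, 7],
                info = m[, 8])
  if (length(samples) > 0) {
    fmt <- strsplit(m[, 9], ":", fixed = TRUE)
    gt_i <- vapply(fmt, function(f) match("GT", f), integer(1))
    ad_i <- vapply(fmt, function(f) match("AD", f), integer(1))
    has_ad <- all(!is.na(ad_i))
    rc <- ac <- if (has_ad) matrix(NA_integer_, nrow(out), length(samples),
                                   dimnames = list(NULL, samples))
    for (j in seq_along(samples)) {
      sf <- strsplit(m[, 9 + j], ":", fixed = TRUE)
      gts <- vapply(seq_along(sf), function(i) sf[[i]][gt_i[i]], character(1))
      gts <- gsub("|", "/", gts, fixed = TRUE)
      out[[paste0("gt_", samples[j])]] <- dplyr::case_when(
        gts == "0/0" ~ 0L, gts %in% c("0/1", "1/0") ~ 1L, gts == "1/1" ~ 2L,
        TRUE ~ NA_integer_)
      if (has_ad) {
        ads <- vapply(seq_along(sf), function(i) sf[[i]][ad_i[i]],
                      character(1))
        sp <- strsplit(ads, ",", fixed = TRUE)
        rc[, j] <- as.integer(vapply(sp, `[`, character(1), 1))
        ac[, j] <- as.integer(vapply(sp, function(x)
          if (length(x) > 1) x[2] else "0", character(1)))
      }
    }
    if (has_ad) {
      out$ref_count <- rc
      out$alt_count <- ac
    }
  }
  out
}

#' Write a minimal VCF
#'
#' @param variants Tibble with `chrom`, `pos`, `ref`, `alt`; optional `id`,
#'   `qual`, `filter`, `info` and genotype columns `gt_<sample>` (0/1/2/NA).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path) {
  v <- as_tibble(variants)
  gt_cols <- grep("^gt_", names(v), value = TRUE)
  samples <- sub("^gt_", "", gt_cols)
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", if (length(samples)) c("FORMAT", samples)),
                 collapse = "\t"))
  gt_str <- c("0/0", "0/1", "1/1")
  rows <- vapply(seq_len(nrow(v)), function(i) {
    base <- c(v$chrom[i], format(v$pos[i], scientific = FALSE, trim = TRUE),
              if ("id" %in% names(v)) v$id[i] else ".",
              v$ref[i], v$alt[i],
              if ("qual" %in% names(v)) v$qual[i] else ".",
              if ("filter" %in% names(v)) v$filter[i] else ".",
              if ("info" %in% names(v)) v$info[i] else ".")
    if (length(samples)) {
      g <- vapply(gt_cols, function(cn) {
        gg <- v[[cn]][i]
        if (is.na(gg)) "./." else gt_str[gg + 1]
      }, character(1))
      base <- c(base, "GT", g)
    }
    paste(base, collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read PLINK-text PED/MAP files
#'
#' PED columns: family, id, sire, dam, sex (1 = male, 2 = female), phenotype
#' (1 = unaffected, 2 = affected, 0/-9 = unknown), then two allele columns
#' per marker (`0 0` = missing). Genotypes are coded as the count of the
#' `2`/`B` allele.
#'
#' @param ped_path,map_path File paths.
#' @return List with `pedigree` (tibble `id`, `sire`, `dam`, `sex`,
#'   `affected`) and `genotypes` (tibble `chrom`, `pos`, `marker_id` + one
#'   column per individual).
#' @export
read_pedmap <- function(ped_path, map_path) {
  map <- utils::read.table(map_path, header = FALSE,
                           col.names = c("chrom", "marker_id", "cm", "pos"),
                           colClasses = c("character", "character", "numeric",
                                          "integer"))
  ped_rows <- strsplit(trimws(readLines(ped_path)), "[ \t]+")
  ped_rows <- ped_rows[lengths(ped_rows) > 0]
  nmark <- nrow(map)
  exp_len <- 6 + 2 * nmark
  if (any(lengths(ped_rows) != exp_len)) {
    abort(sprintf("PED/MAP mismatch: expected %d fields per PED row, got %d",
                  exp_len, lengths(ped_rows)[lengths(ped_rows) != exp_len][1]),
          class = "enuscreen_structure_error")
  }
  m <- do.call(rbind, ped_rows)
  pedigree <- tibble(
    id = m[, 2],
    sire = ifelse(m[, 3] == "0", NA_character_, m[, 3]),
    dam = ifelse(m[, 4] == "0", NA_character_, m[, 4]),
    sex = dplyr::case_when(m[, 5] == "1" ~ "M", m[, 5] == "2" ~ "F",
                           TRUE ~ NA_character_),
    affected = dplyr::case_when(m[, 6] == "2" ~ TRUE, m[, 6] == "1" ~ FALSE,
                                TRUE ~ NA))
  geno <- tibble(chrom = map$chrom, pos = map$pos, marker_id = map$marker_id)
  is_b <- function(a) a %in% c("2", "B")
  for (i in seq_len(nrow(m))) {
    a1 <- m[i, 6 + 2 * seq_len(nmark) - 1]
    a2 <- m[i, 6 + 2 * seq_len(nmark)]
    g <- is_b(a1) + is_b(a2)
    g[a1 == "0" | a2 == "0"] <- NA_integer_
    geno[[pedigree$id[i]]] <- as.integer(g)
  }
  list(pedigree = pedigree, genotypes = geno)
}

#' Write PLINK-text PED/MAP files
#'
#' @param pedigree Tibble `id`, `sire`, `dam`, `sex`, `affected`.
#' @param genotypes Genotype tibble (`chrom`, `pos`, `marker_id` + individual
#'   columns).
#' @param ped_path,map_path Output paths.
#' @param family Family id written to the first PED column.
#' @return Invisibly, the two paths.
#' @export
write_pedmap <- function(pedigree, genotypes, ped_path, map_path,
                         family = "FAM1") {
  map <- data.frame(genotypes$chrom, genotypes$marker_id, 0,
                    genotypes$pos)
  utils::write.table(map, map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  allele_str <- c("1 1", "1 2", "2 2")
  rows <- vapply(seq_len(nrow(pedigree)), function(i) {
    id <- pedigree$id[i]
    g <- if (id %in% names(genotypes)) genotypes[[id]] else
      rep(NA_integer_, nrow(genotypes))
    gs <- ifelse(is.na(g), "0 0", allele_str[g + 1])
    paste(c(family, id,
            if (is.na(pedigree$sire[i])) "0" else pedigree$sire[i],
            if (is.na(pedigree$dam[i])) "0" else pedigree$dam[i],
            if (is.na(pedigree$sex[i])) "0"
              else if (pedigree$sex[i] == "M") "1" else "2",
            if (is.na(pedigree$affected[i])) "0"
              else if (pedigree$affected[i]) "2" else "1",
            gs), collapse = " ")
  }, character(1))
  writeLines(rows, ped_path)
  invisible(c(ped_path, map_path))
}

#' Convert 1-based inclusive intervals to BED (0-based half-open) and back
#'
#' @param start,end 1-based inclusive interval.
#' @return Tibble with converted coordinates.
#' @export
to_bed_coords <- function(start, end) {
  tibble(bed_start = start - 1L, bed_end = end)
}

#' @rdname to_bed_coords
#' @param bed_start,bed_end 0-based half-open interval.
#' @export
from_bed_coords <- function(bed_start, bed_end) {
  tibble(start = bed_start + 1L, end = bed_end)
}

#' Write linkage regions as a BED file
#'
#' @param regions Tibble from [extract_regions()] (`chrom`, `start`, `end`,
#'   1-based inclusive).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  b <- to_bed_coords(regions$start, regions$end)
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  utils::write.table(
    data.frame(regions$chrom, fmt(b$bed_start), fmt(b$bed_end),
               if ("peak_marker" %in% names(regions)) regions$peak_marker
               else ".",
               if ("peak_lod" %in% names(regions)) regions$peak_lod else "."),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read/write per-site read counts as TSV
#'
#' Long format: `chrom`, `pos`, `individual`, `ref_count`, `alt_count`.
#'
#' @param counts Read-count tibble with matrix-columns `ref`/`alt` (as from
#'   [emulate_rad()]).
#' @param path File path.
#' @return `read_readcounts` returns the matrix-column tibble;
#'   `write_readcounts` returns `path` invisibly.
#' @export
write_readcounts <- function(counts, path) {
  inds <- colnames(counts$ref)
  long <- purrr::map_dfr(inds, function(id)
    tibble(chrom = counts$chrom, pos = counts$pos, individual = id,
           ref_count = counts$ref[, id], alt_count = counts$alt[, id]))
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_readcounts
#' @export
read_readcounts <- function(path) {
  long <- utils::read.table(path, header = TRUE, sep = "\t",
                            colClasses = c("character", "integer",
                                           "character", "integer", "integer"))
  inds <- unique(long$individual)
  sites <- unique(long[, c("chrom", "pos")])
  sites <- sites[order(sites$chrom, sites$pos), ]
  key <- paste(sites$chrom, sites$pos)
  rc <- ac <- matrix(0L, nrow(sites), length(inds),
                     dimnames = list(NULL, inds))
  row_i <- match(paste(long$chrom, long$pos), key)
  col_i <- match(long$individual, inds)
  rc[cbind(row_i, col_i)] <- long$ref_count
  ac[cbind(row_i, col_i)] <- long$alt_count
  out <- as_tibble(sites)
  out$ref <- rc
  out$alt <- ac
  out
}

#' Write a pedigree TSV
#'
#' Columns: id, sire, dam, sex, generation, affected.
#'
#' @param pedigree Pedigree tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(pedigree, path) {
  utils::write.table(pedigree, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
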