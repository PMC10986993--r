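#' Canonical variant identifiers
#'
#' A variant is identified by `chrom:pos:ref:alt` with a 1-based position.
#' Multi-allelic VCF records are represented as several biallelic variants
#' sharing `chrom:pos`. The key uniquely identifies a column of a
#' [dosage_matrix()].
#'
#' @param chrom Chromosome label (character).
#' @param pos 1-based position in base pairs.
#' @param ref,alt Reference and alternate allele strings; must differ.
#' @return `variant_key()` returns a character vector of keys;
#'   `parse_variant_key()` returns a data frame with columns
#'   `chrom`, `pos`, `ref`, `alt`, `key`.
#' @examples
#' variant_key("7", 100490, "A", "G")
#' parse_variant_key("7:100490:A:G")
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  if (any(ref == alt)) stop("ref and alt alleles must differ")
  paste(chrom, pos, ref, alt, sep = ":")
}

#' @rdname variant_key
#' @param key Character vector of `chrom:pos:ref:alt` keys.
#' @export
parse_variant_key <- function(key) {
  parts <- strsplit(key, ":", fixed = TRUE)
  bad <- lengths(parts) != 4L
  if (any(bad)) {
    stop("malformed variant key(s): ", paste(key[bad][1:min(3, sum(bad))], collapse = ", "))
  }
  m <- do.call(rbind, parts)
  data.frame(
    chrom = m[, 1L],
    pos = as.integer(m[, 2L]),
    ref = m[, 3L],
    alt = m[, 4L],
    key = key,
    stringsAsFactors = FALSE
  )
}

# Palindromic (strand-ambiguous) variants: A/T or C/G pairs.
is_palindromic <- function(ref, alt) {
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  !is.na(comp[ref]) & unname(comp[ref]) == alt
}

#' Gene regions of blood group systems
#'
#' Reads a table mapping blood group / HPA systems to the genomic regions of
#' their antigen-coding genes. Coordinates are 1-based and inclusive (VCF
#' convention); each region is extended by `flank` base pairs on both sides
#' when variants are extracted, so that regulatory variation adjacent to the
#' gene can enter the models.
#'
#' @param path Path to a tab- or comma-separated file with columns
#'   `system`, `gene`, `chrom`, `start`, `end`.
#' @param flank Flanking extension in bp applied downstream (default 2000).
#' @return A data frame of class `gene_region_table` with columns
#'   `system`, `gene`, `chrom`, `start`, `end`, `flank`.
#' @export
read_gene_regions <- function(path, flank = 2000L) {
  if (!file.exists(path)) stop("gene region table not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  gene_regions(df, flank = flank)
}

#' @rdname read_gene_regions
#' @param df Data frame with columns `system`, `gene`, `chrom`, `start`, `end`.
#' @export
gene_regions <- function(df, flank = 2000L) {
  need <- c("system", "gene", "chrom", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("gene region table lacks column(s): ", paste(miss, collapse = ", "))
  df <- df[, need]
  df$chrom <- as.character(df$chrom)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (any(df$start > df$end)) stop("gene region with start > end")
  if (flank < 0) stop("flank must be >= 0")
  df$flank <- as.integer(flank)
  class(df) <- c("gene_region_table", "data.frame")
  df
}
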