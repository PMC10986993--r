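#' Load allele dosages from an imputed VCF
#'
#' Reads a VCF (v4.2+, plain or bgzipped) and builds a [dosage_matrix()] of
#' expected alternate-allele counts. When a per-genotype dosage field (`DS`)
#' is present it takes precedence; otherwise the dosage is the alternate
#' allele count of the hard genotype call (`GT`). Records with a missing call
#' and no dosage field become missing entries. Multi-allelic records are split
#' into one biallelic variant per alternate allele, keyed `chrom:pos:ref:alt`.
#'
#' @param vcf_path Path to the VCF file.
#' @param regions Optional [gene_regions()] table; when supplied, only
#'   variants inside any region extended by its `flank` are retained, and an
#'   error is raised if a region's chromosome is absent from the VCF.
#' @return A [dosage_matrix()] restricted to the requested regions.
#' @examples
#' \dontrun{
#' regions <- read_gene_regions("blood_group_genes.tsv")
#' dm <- load_dosages("cohort.vcf.gz", regions)
#' }
#' @export
load_dosages <- function(vcf_path, regions = NULL) {
  if (!file.exists(vcf_path)) stop("VCF not readable: ", vcf_path)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (!is.matrix(fix)) {  # single-record VCFs come back as a bare vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  if (is.null(fix) || nrow(fix) == 0) stop("VCF contains no variant records: ", vcf_path)

  chroms_seen <- unique(fix[, "CHROM"])
  if (!is.null(regions)) {
    absent <- !(as.character(regions$chrom) %in% chroms_seen)
    if (any(absent)) {
      r <- regions[which(absent)[1], ]
      stop(sprintf("region chromosome '%s' (%s/%s) absent from VCF",
                   r$chrom, r$system, r$gene))
    }
  }

  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  if (anyNA(pos)) {
    bad <- which(is.na(pos))[1]
    stop(sprintf("malformed record at %s:%s (position not numeric)",
                 fix[bad, "CHROM"], fix[bad, "POS"]))
  }

  ds <- tryCatch(vcfR::extract.gt(vcf, element = "DS"),
                 error = function(e) NULL)
  gt <- tryCatch(vcfR::extract.gt(vcf, element = "GT"),
                 error = function(e) NULL)
  if (is.null(ds) && is.null(gt)) stop("VCF has neither GT nor DS genotype fields")
  samples <- colnames(if (!is.null(gt)) gt else ds)
  n_rec <- nrow(fix)

  # Expand multi-allelic records: one output variant per ALT allele.
  alt_list <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n_alt <- lengths(alt_list)
  rec_idx <- rep.int(seq_len(n_rec), n_alt)
  alt_idx <- sequence(n_alt)
  variants <- data.frame(
    chrom = fix[rec_idx, "CHROM"],
    pos = pos[rec_idx],
    ref = fix[rec_idx, "REF"],
    alt = unlist(alt_list),
    stringsAsFactors = FALSE
  )
  variants$key <- variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)

  if (!is.null(regions)) {
    keep <- rep(FALSE, nrow(variants))
    for (i in seq_len(nrow(regions))) {
      r <- regions[i, ]
      fl <- if (!is.null(r$flank)) r$flank else 2000L
      keep <- keep | (variants$chrom == as.character(r$chrom) &
                        variants$pos >= r$start - fl &
                        variants$pos <= r$end + fl)
    }
  } else {
    keep <- rep(TRUE, nrow(variants))
  }

  if (anyDuplicated(variants$key[keep])) {
    dup <- variants$key[keep][duplicated(variants$key[keep])]
    warning("duplicate variant keys in VCF; keeping first occurrence: ",
            paste(utils::head(dup, 3), collapse = ", "))
    keep[keep] <- !duplicated(variants$key[keep])
  }

  kidx <- which(keep)
  values <- matrix(NA_real_, nrow = length(samples), ncol = length(kidx),
                   dimnames = list(samples, variants$key[kidx]))

  gt_counts <- NULL
  if (!is.null(gt)) {
    # allele-index counts per record x sample, NA when any allele is missing
    gt_split <- strsplit(gt, "[/|]")
    dim(gt_split) <- dim(gt)
  }

  for (j in seq_along(kidx)) {
    v <- kidx[j]
    r <- rec_idx[v]
    k <- alt_idx[v]
    val <- rep(NA_real_, length(samples))
    if (!is.null(ds)) {
      ds_r <- ds[r, ]
      if (n_alt[r] > 1L) {
        parts <- strsplit(ds_r, ",", fixed = TRUE)
        ds_val <- suppressWarnings(as.numeric(vapply(parts, function(p) {
          if (length(p) >= k) p[k] else NA_character_
        }, character(1))))
      } else {
        ds_val <- suppressWarnings(as.numeric(ds_r))
      }
      val <- ds_val
    }
    if (!is.null(gt) && anyNA(val)) {
      need <- which(is.na(val))
      cnt <- vapply(gt_split[r, need], function(a) {
        if (length(a) == 0 || any(a == "." | is.na(a))) return(NA_real_)
        sum(a == as.character(k))
      }, numeric(1))
      val[need] <- cnt
    }
    values[, j] <- val
  }

  dosage_matrix(values, variants[kidx, , drop = FALSE])
}

#' Write a dosage matrix as a VCF
#'
#' Emits a minimal VCF v4.2 with `GT` (hard call, from the rounded dosage)
#' and `DS` (the dosage itself) per sample, suitable for round-tripping
#' through [load_dosages()]. Missing entries become `./.` with `DS` omitted
#' as `.`.
#'
#' @param dm A [dosage_matrix()].
#' @param path Output path (plain text).
#' @export
write_vcf <- function(dm, path) {
  v <- dm$variants
  d <- dm$dosages
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=rbcforest",
    paste0("##contig=<ID=", unique(v$chrom), ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=A,Type=Float,Description=\"Estimated alternate allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
            rownames(d)), collapse = "\t")
  ), con)
  gt_codes <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(v)), function(j) {
    dj <- d[, j]
    hard <- pmin(pmax(round(dj), 0), 2)
    cell <- ifelse(is.na(dj), "./.:.",
                   paste0(gt_codes[hard + 1L], ":", format_dosage(dj)))
    paste(c(v$chrom[j], v$pos[j], v$key[j], v$ref[j], v$alt[j], ".", "PASS", ".",
            "GT:DS", cell), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

# Decimal representation that round-trips dyadic-grid dosages exactly.
format_dosage <- function(x) {
  out <- vapply(x, function(z) {
    if (is.na(z)) return(".")
    s <- format(z, digits = 15, scientific = FALSE)
    s
  }, character(1))
  out
}
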