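test_that("variant keys round-trip and reject degenerate alleles", {
  k <- variant_key("7", 100490L, "A", "G")
  expect_equal(k, "7:100490:A:G")
  p <- parse_variant_key(k)
  expect_equal(p$pos, 100490L)
  expect_equal(p$alt, "G")
  expect_error(variant_key("1", 5, "A", "A"), "differ")
  expect_error(parse_variant_key("1:5:A"), "malformed")
})

test_that("load_dosages derives dosage from GT and prefers the DS field", {
  samples <- c("S1", "S2", "S3")
  path <- write_tiny_vcf(c(
    vcf_header(samples),
    "1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\t.\tC\tT\t.\tPASS\t.\tGT:DS\t1/1:1.37\t0/0:0.02\t./.:.",
    "1\t300\t.\tG\tA\t.\tPASS\t.\tGT\t./.\t0/1\t1|1"
  ))
  dm <- load_dosages(path)
  expect_equal(dim(dm), c(3L, 3L))
  # GT-only record: alternate allele counts, 0/0 -> 0
  expect_equal(unname(dm$dosages[, "1:100:A:G"]), c(0, 1, 2))
  # DS takes precedence over the hard call (1/1 but DS 1.37)
  expect_equal(unname(dm$dosages[, "1:200:C:T"]), c(1.37, 0.02, NA))
  # missing call with no dosage -> missing entry; phased separator accepted
  expect_equal(unname(dm$dosages[, "1:300:G:A"]), c(NA, 1, 2))

  # independent text-level parse of the DS record
  raw <- readLines(path)
  rec <- strsplit(grep("^1\t200", raw, value = TRUE), "\t")[[1]]
  ds_oracle <- suppressWarnings(as.numeric(vapply(
    strsplit(rec[10:12], ":"), `[`, character(1), 2)))
  expect_equal(unname(dm$dosages[, "1:200:C:T"]), ds_oracle)
})

test_that("load_dosages splits multi-allelic records into biallelic variants", {
  path <- write_tiny_vcf(c(
    vcf_header(c("S1", "S2")),
    "1\t500\t.\tA\tG,T\t.\tPASS\t.\tGT:DS\t1/2:0.9,1.1\t0/1:1.0,0.1"
  ))
  dm <- load_dosages(path)
  expect_setequal(dm$variants$key, c("1:500:A:G", "1:500:A:T"))
  expect_equal(unname(dm$dosages[, "1:500:A:G"]), c(0.9, 1.0))
  expect_equal(unname(dm$dosages[, "1:500:A:T"]), c(1.1, 0.1))

  # GT-only multi-allelic: count of each alternate allele index
  path2 <- write_tiny_vcf(c(
    vcf_header("S1"),
    "1\t600\t.\tA\tG,T\t.\tPASS\t.\tGT\t1/2"
  ))
  dm2 <- load_dosages(path2)
  expect_equal(unname(dm2$dosages[1, ]), c(1, 1))
})

test_that("region extraction keeps exactly the in-region variants", {
  # a gene whose region (with 2 kb flanks) holds 62 segregating variants,
  # flanked by out-of-region variants on both sides and another chromosome
  pos_in <- seq(100000L, by = 250L, length.out = 62L)
  lines <- c(
    vcf_header("S1", contigs = c("7", "9")),
    sprintf("7\t%d\t.\tA\tG\t.\tPASS\t.\tGT\t0/1", c(95000L, pos_in, 130000L)),
    "9\t100000\t.\tA\tG\t.\tPASS\t.\tGT\t0/1"
  )
  regions <- gene_regions(data.frame(
    system = "Cartwright", gene = "ACHE", chrom = "7",
    start = min(pos_in) + 1500L, end = max(pos_in) - 1500L))
  dm <- load_dosages(write_tiny_vcf(lines), regions)
  expect_equal(ncol(dm), 62L)

  expect_error(
    load_dosages(write_tiny_vcf(lines),
                 gene_regions(data.frame(system = "X", gene = "Y", chrom = "12",
                                         start = 1L, end = 10L))),
    "chromosome '12'")
})

test_that("slice_region honors inclusive boundaries and flanks", {
  d <- grid_dosages(5, 6)
  v <- data.frame(chrom = "1", pos = c(800L, 1000L, 1500L, 3000L, 5000L, 5200L),
                  ref = "A", alt = "G", stringsAsFactors = FALSE)
  v$key <- variant_key(v$chrom, v$pos, v$ref, v$alt)
  colnames(d) <- v$key
  dm <- dosage_matrix(d, v)

  # flank 0: positions exactly at start/end are retained (inclusive)
  r0 <- data.frame(chrom = "1", start = 1000L, end = 5000L, flank = 0L)
  expect_equal(slice_region(dm, r0)$variants$pos, c(1000L, 1500L, 3000L, 5000L))

  # a variant 1,500 bp upstream of the gene start is kept with 2 kb flanks
  r2k <- data.frame(chrom = "1", start = 2300L, end = 3100L, flank = 2000L)
  expect_true(800L %in% slice_region(dm, r2k)$variants$pos)

  # brute-force position filter oracle over random regions
  withr::with_seed(42, {
    for (i in 1:25) {
      st <- sample(500:5500, 1)
      en <- st + sample(0:2000, 1)
      fl <- sample(0:500, 1)
      got <- slice_region(dm, data.frame(chrom = "1", start = st, end = en, flank = fl))
      want <- v$key[vapply(v$pos, function(p) p >= st - fl && p <= en + fl, logical(1))]
      expect_identical(got$variants$key, want)
    }
  })

  # union over disjoint regions equals concatenation of slices
  a <- slice_region(dm, data.frame(chrom = "1", start = 700L, end = 1600L, flank = 0L))
  b <- slice_region(dm, data.frame(chrom = "1", start = 2900L, end = 5300L, flank = 0L))
  expect_identical(c(a$variants$key, b$variants$key), v$key)
})

test_that("harmonization maps exact, flipped and absent model variants", {
  d <- grid_dosages(8, 4)
  mv <- parse_variant_key(colnames(d))
  dm <- dosage_matrix(d, mv)

  # identical panel: unchanged, nothing flipped
  h <- harmonize_to_model(dm, mv)
  expect_identical(h$matrix$dosages, d)
  expect_equal(h$report$matched_flipped, 0L)

  # swapped ref/alt: dosage d -> 2 - d (0.4 -> 1.6)
  d2 <- d
  d2[, 2] <- 2 - d2[, 2]
  d2[1, 2] <- 1.6
  v2 <- mv
  v2$ref[2] <- mv$alt[2]
  v2$alt[2] <- mv$ref[2]
  v2$key <- variant_key(v2$chrom, v2$pos, v2$ref, v2$alt)
  h2 <- harmonize_to_model(dosage_matrix(d2, v2), mv)
  expect_equal(h2$report$matched_flipped, 1L)
  expect_equal(unname(h2$matrix$dosages[1, 2]), 0.4)
  expect_identical(h2$matrix$dosages[, -2], d[, -2])

  # model variant absent from the target: all-missing column, reported
  h3 <- harmonize_to_model(dosage_matrix(d[, -3], mv[-3, ]), mv)
  expect_equal(h3$report$unmatched, mv$key[3])
  expect_true(all(is.na(h3$matrix$dosages[, 3])))
  expect_equal(h3$report$matched_exact + h3$report$matched_flipped +
                 length(h3$report$unmatched), nrow(mv))

  expect_error(harmonize_to_model(dm, mv[c(1, 1, 2), ]), "duplicate")
})

test_that("swapped palindromic variants follow the ambiguity policy", {
  v <- data.frame(chrom = "1", pos = c(10L, 20L), ref = c("A", "C"),
                  alt = c("T", "G"), stringsAsFactors = FALSE)  # both palindromic
  v$key <- variant_key(v$chrom, v$pos, v$ref, v$alt)
  d <- grid_dosages(5, 2)
  colnames(d) <- variant_key(v$chrom, v$pos, v$alt, v$ref)  # stored swapped
  dm <- dosage_matrix(d, parse_variant_key(colnames(d)))

  h <- harmonize_to_model(dm, v)
  expect_equal(h$report$matched_flipped, 0L)
  expect_setequal(h$report$ambiguous, v$key)
  expect_setequal(h$report$unmatched, v$key)

  h2 <- harmonize_to_model(dm, v, flip_palindromic = TRUE)
  expect_equal(h2$report$matched_flipped, 2L)
  expect_identical(h2$matrix$dosages[, 1], 2 - d[, 1])
})

test_that("the allele-orientation flip is an involution on grid dosages", {
  d <- grid_dosages(50, 10)
  expect_identical(2 - (2 - d), d)
  # flip there and back through the harmonizer
  v <- parse_variant_key(colnames(d))
  vf <- v
  vf$ref <- v$alt
  vf$alt <- v$ref
  vf$key <- variant_key(vf$chrom, vf$pos, vf$ref, vf$alt)
  keep <- !is_palindromic(v$ref, v$alt)
  once <- harmonize_to_model(dosage_matrix(d, v), vf[keep, ])$matrix
  back <- harmonize_to_model(once, v[keep, ])$matrix
  expect_identical(back$dosages, d[, keep, drop = FALSE])
})

test_that("mean imputation fills by column means and preserves observed entries", {
  d <- grid_dosages(4, 3)
  dm <- dosage_matrix(d)
  expect_identical(mean_impute_missing(dm)$dosages, d)  # no missing: unchanged

  d2 <- d
  d2[, 1] <- c(0, 1, 2, NA)
  out <- mean_impute_missing(dosage_matrix(d2))
  expect_equal(unname(out$dosages[4, 1]), 1.0)          # mean of {0,1,2}
  expect_identical(out$dosages[1:3, ], d2[1:3, ])       # bit-identical elsewhere

  # reference mode: filled values equal the supplied means exactly
  means <- c(0.123456789, 1.5)
  names(means) <- colnames(d2)[1:2]
  d3 <- d
  d3[2, 1] <- NA
  d3[c(1, 4), 2] <- NA
  ref <- mean_impute_missing(dosage_matrix(d3), reference_means = means)
  expect_identical(unname(ref$dosages[2, 1]), means[[1]])
  expect_identical(unname(ref$dosages[c(1, 4), 2]), rep(means[[2]], 2))
  expect_error(mean_impute_missing(dosage_matrix(d3), reference_means = means[1]),
               "lacks variant")

  # all-missing column in self mode: filled with 1.0, warned
  d4 <- d
  d4[, 2] <- NA
  expect_warning(out4 <- mean_impute_missing(dosage_matrix(d4)), "entirely missing")
  expect_equal(unname(out4$dosages[, 2]), rep(1, 4))
})

test_that("dosage TSV serialization round-trips with stable column order", {
  co <- tiny_cohort()
  path <- tempfile(fileext = ".tsv")
  write_dosage_tsv(co$dosages, path)
  back <- read_dosage_tsv(path)
  expect_identical(back$dosages, co$dosages$dosages)
  expect_identical(back$variants$key, co$dosages$variants$key)
})
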