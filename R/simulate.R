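#' Synthetic blood-group cohort: gene panels and antigen models
#'
#' `sim_gene()` declares one antigen-coding gene region and the number of
#' array variants segregating in it; `antigen_sim_model()` declares the
#' genetic architecture of one antigen inside such a gene: a causal variant
#' at a given effect-allele frequency, a handful of tag SNPs in linkage
#' disequilibrium with it (haplotype copy-with-switch, switch probability
#' `1 - sqrt(r2)` so the dosage correlation hits the target `r^2`), and the
#' remaining panel variants as independent noise.
#'
#' Inheritance modes: `"dominant"` (antigen positive with >= 1 effect
#' allele), `"recessive"` (2 alleles required), and `"abo"` — a three-allele
#' locus (A/B/O) represented as two indicator variants (count of A alleles,
#' count of B alleles) yielding the classical A/B/AB/O phenotype, optionally
#' with an A1/A2 subtype split among A-phenotype samples.
#'
#' @param gene,system,chrom Gene symbol, owning blood group system,
#'   chromosome label.
#' @param start 1-based start position of the gene region.
#' @param n_variants Number of panel variants in the region.
#' @param spacing Base pairs between adjacent panel variants (default 60).
#' @return `sim_gene()` and `antigen_sim_model()` return plain lists
#'   consumed by [sim_cohort_config()].
#' @export
sim_gene <- function(gene, system, chrom, start, n_variants, spacing = 60L) {
  list(gene = gene, system = system, chrom = as.character(chrom),
       start = as.integer(start), n_variants = as.integer(n_variants),
       spacing = as.integer(spacing))
}

#' @rdname sim_gene
#' @param antigen Antigen name.
#' @param inheritance `"dominant"`, `"recessive"` or `"abo"`.
#' @param effect_allele_freq Causal allele frequency in (0, 1) (binary
#'   antigens).
#' @param abo_freqs Named numeric `c(A=, B=, O=)` summing to 1 (`"abo"`).
#' @param a1_freq Optional probability that an A allele is of the A1
#'   subtype; adds an `A1` phenotype column among A-phenotype samples.
#' @param n_tag_snps Tag SNPs per causal variant (default 3).
#' @param tag_r2 Target squared dosage correlation between tag and causal
#'   variant, in \[0, 1\] (default 0.8).
#' @param typed_fraction Fraction of samples with a typing result for this
#'   antigen (default 1).
#' @export
antigen_sim_model <- function(antigen, system, gene,
                              inheritance = c("dominant", "recessive", "abo"),
                              effect_allele_freq = NULL, abo_freqs = NULL,
                              a1_freq = NULL, n_tag_snps = 3L, tag_r2 = 0.8,
                              typed_fraction = 1) {
  inheritance <- match.arg(inheritance)
  if (tag_r2 < 0 || tag_r2 > 1) {
    stop(sprintf("target r^2 %.3f infeasible; feasible range is [0, 1]", tag_r2))
  }
  if (inheritance == "abo") {
    if (is.null(abo_freqs) || !all(c("A", "B", "O") %in% names(abo_freqs))) {
      stop("abo inheritance requires abo_freqs = c(A=, B=, O=)")
    }
    abo_freqs <- abo_freqs[c("A", "B", "O")] / sum(abo_freqs)
  } else {
    if (is.null(effect_allele_freq) || effect_allele_freq <= 0 || effect_allele_freq >= 1) {
      stop("effect_allele_freq must be in (0, 1)")
    }
  }
  if (typed_fraction <= 0 || typed_fraction > 1) stop("typed_fraction must be in (0, 1]")
  list(antigen = antigen, system = system, gene = gene,
       inheritance = inheritance, effect_allele_freq = effect_allele_freq,
       abo_freqs = abo_freqs, a1_freq = a1_freq,
       n_tag_snps = as.integer(n_tag_snps), tag_r2 = tag_r2,
       typed_fraction = typed_fraction)
}

#' Synthetic cohort configuration
#'
#' @param n_samples Cohort size (>= 8: the eligibility floor of 4 cases in
#'   each of two classes).
#' @param genes List of [sim_gene()] regions.
#' @param antigens List of [antigen_sim_model()] architectures; each must
#'   reference a declared gene.
#' @param dosage_noise_sd Truncated-Gaussian dosage noise (imputation
#'   uncertainty stand-in), default 0.05.
#' @param missing_rate Fraction of dosage entries masked missing, default 0.
#' @param seed Integer seed; identical configs and seeds reproduce cohorts
#'   bit-exactly.
#' @return A list of class `sim_cohort_config`.
#' @export
sim_cohort_config <- function(n_samples, genes, antigens,
                              dosage_noise_sd = 0.05, missing_rate = 0,
                              seed = 1L) {
  if (n_samples < 8L) stop("n_samples must be >= 8")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  if (dosage_noise_sd < 0) stop("dosage_noise_sd must be >= 0")
  gene_names <- vapply(genes, `[[`, character(1), "gene")
  if (anyDuplicated(gene_names)) stop("duplicate gene names")
  for (ag in antigens) {
    if (!ag$gene %in% gene_names) stop("antigen ", ag$antigen, " references unknown gene ", ag$gene)
  }
  structure(list(n_samples = as.integer(n_samples), genes = genes,
                 antigens = antigens, dosage_noise_sd = dosage_noise_sd,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_cohort_config")
}

#' Discovery-cohort default configuration
#'
#' A 20-antigen panel (19 binary antigens plus the 4-class ABO phenotype)
#' across 11 genes in 9 blood group systems, calibrated to the typed counts,
#' antigen positivity rates and per-system variant-panel sizes of a Finnish
#' blood-donor reference cohort of 1,192 samples. Dominant positivity `q`
#' maps to an effect-allele frequency `1 - sqrt(1 - q)`; recessive to
#' `sqrt(q)`; the ABO allele frequencies are solved from the A/B/AB/O
#' phenotype frequencies under Hardy-Weinberg.
#'
#' @param n_samples Cohort size (default 1192).
#' @param seed Integer seed.
#' @param dosage_noise_sd,missing_rate Passed to [sim_cohort_config()].
#' @return A [sim_cohort_config()].
#' @export
finnish_reference_config <- function(n_samples = 1192L, seed = 1L,
                                     dosage_noise_sd = 0.05, missing_rate = 0) {
  genes <- list(
    sim_gene("KEL",     "Kell",       "7",  10000001L, 127L),
    sim_gene("SLC14A1", "Kidd",       "18", 43000001L, 622L),
    sim_gene("ACKR1",   "Duffy",      "1",  159000001L, 57L),
    sim_gene("GYPA",    "MNS",        "4",  144000001L, 344L),
    sim_gene("GYPB",    "MNS",        "4",  144800001L, 344L),
    sim_gene("BCAM",    "Lutheran",   "19", 44800001L, 124L),
    sim_gene("RHCE",    "Rh",         "1",  25300001L, 221L),
    sim_gene("RHD",     "Rh",         "1",  25600001L, 45L),
    sim_gene("AQP1",    "Colton",     "7",  30900001L, 108L),
    sim_gene("ACHE",    "Cartwright", "7",  100800001L, 62L),
    sim_gene("ABO",     "ABO",        "9",  133200001L, 496L)
  )
  dom <- function(q) 1 - sqrt(1 - q)
  rec <- function(q) sqrt(q)
  frac <- function(n_typed) n_typed / 1192
  # ABO allele frequencies from phenotype frequencies A 40.9 / B 8.2 / O 42.9 (%)
  fO <- sqrt(0.429)
  fA <- (-2 * fO + sqrt(4 * fO^2 + 4 * 0.409)) / 2
  fB <- (-2 * fO + sqrt(4 * fO^2 + 4 * 0.082)) / 2
  abo <- c(A = fA, B = fB, O = fO) / (fA + fB + fO)
  antigens <- list(
    antigen_sim_model("K",   "Kell",   "KEL",     "dominant", dom(0.047), typed_fraction = frac(1192)),
    antigen_sim_model("Kpa", "Kell",   "KEL",     "dominant", dom(0.026), typed_fraction = frac(1177)),
    antigen_sim_model("Jka", "Kidd",   "SLC14A1", "dominant", dom(0.726), typed_fraction = frac(1177)),
    antigen_sim_model("Jkb", "Kidd",   "SLC14A1", "dominant", dom(0.685), typed_fraction = frac(1177)),
    antigen_sim_model("Fya", "Duffy",  "ACKR1",   "dominant", dom(0.670), typed_fraction = frac(1177)),
    antigen_sim_model("Fyb", "Duffy",  "ACKR1",   "dominant", dom(0.751), typed_fraction = frac(1175)),
    antigen_sim_model("M",   "MNS",    "GYPA",    "dominant", dom(0.877), typed_fraction = frac(1177)),
    antigen_sim_model("N",   "MNS",    "GYPA",    "dominant", dom(0.590), typed_fraction = frac(1177)),
    antigen_sim_model("S",   "MNS",    "GYPB",    "dominant", dom(0.542), typed_fraction = frac(1177)),
    antigen_sim_model("s",   "MNS",    "GYPB",    "recessive", rec(0.876), typed_fraction = frac(1177)),
    antigen_sim_model("Lua", "Lutheran", "BCAM",  "dominant", dom(0.036), typed_fraction = frac(1164)),
    antigen_sim_model("C",   "Rh",     "RHCE",    "dominant", dom(0.544), typed_fraction = frac(1192)),
    antigen_sim_model("c",   "Rh",     "RHCE",    "recessive", rec(0.794), typed_fraction = frac(1192)),
    antigen_sim_model("Cw",  "Rh",     "RHCE",    "dominant", dom(0.032), typed_fraction = frac(1177)),
    antigen_sim_model("E",   "Rh",     "RHCE",    "dominant", dom(0.199), typed_fraction = frac(1192)),
    antigen_sim_model("e",   "Rh",     "RHCE",    "recessive", rec(0.962), typed_fraction = frac(1192)),
    antigen_sim_model("D",   "Rh",     "RHD",     "dominant", dom(0.716), typed_fraction = frac(1192)),
    antigen_sim_model("Cob", "Colton", "AQP1",    "dominant", dom(0.073), typed_fraction = frac(1164)),
    antigen_sim_model("Ytb", "Cartwright", "ACHE", "dominant", dom(0.062), typed_fraction = frac(1160)),
    antigen_sim_model("ABO", "ABO",    "ABO",     "abo", abo_freqs = abo, typed_fraction = frac(1192))
  )
  sim_cohort_config(n_samples, genes, antigens, dosage_noise_sd, missing_rate, seed)
}

# Deterministic variant panel: positions, alleles and per-variant roles
# (causal / tag / noise). Seeded by config$seed independently of the cohort
# draws so that a replication cohort shares the same panel.
build_panel <- function(config) {
  withr::with_seed(config$seed, {
    rows <- list()
    for (g in config$genes) {
      nv <- g$n_variants
      pos <- g$start + (seq_len(nv) - 1L) * g$spacing
      ref <- sample(c("A", "C", "G", "T"), nv, replace = TRUE)
      alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L),
                    character(1))
      df <- data.frame(chrom = g$chrom, pos = pos, ref = ref, alt = alt,
                       gene = g$gene, system = g$system,
                       role = "noise", antigen = NA_character_,
                       subrole = NA_character_, causal_slot = NA_integer_,
                       tag_r2 = NA_real_, freq = stats::runif(nv, 0.01, 0.5),
                       stringsAsFactors = FALSE)
      # assign causal and tag slots for the antigens of this gene
      ags <- Filter(function(a) a$gene == g$gene, config$antigens)
      free <- seq_len(nv)
      for (a in ags) {
        subroles <- if (a$inheritance == "abo") {
          c("A", "B", if (!is.null(a$a1_freq)) "A1")
        } else a$antigen
        for (sr in subroles) {
          slots <- sort(sample(free, 1L + a$n_tag_snps))
          free <- setdiff(free, slots)
          causal <- slots[ceiling(length(slots) / 2)]
          df$role[causal] <- "causal"
          df$antigen[causal] <- a$antigen
          df$subrole[causal] <- sr
          tags <- setdiff(slots, causal)
          df$role[tags] <- "tag"
          df$antigen[tags] <- a$antigen
          df$subrole[tags] <- sr
          df$causal_slot[tags] <- causal
          df$tag_r2[tags] <- a$tag_r2
        }
      }
      rows[[length(rows) + 1L]] <- df
    }
    panel <- do.call(rbind, rows)
    panel$key <- variant_key(panel$chrom, panel$pos, panel$ref, panel$alt)
    rownames(panel) <- NULL
    panel
  })
}

#' Derive antigen phenotypes from causal genotypes
#'
#' Truth-level genotype-to-phenotype map, applied to the integral allele
#' counts *before* dosage noise. Dominant: positive iff at least one effect
#' allele; recessive: positive iff two. `"abo"` takes a matrix with columns
#' `A` and `B` (counts of A and B alleles) and applies the classical allele
#' table: A/O -> A, B/O -> B, A/B -> AB, O/O -> O.
#'
#' @param counts Integer vector of effect-allele counts (binary), or a
#'   matrix with columns `A`, `B` for `"abo"`.
#' @param inheritance `"dominant"`, `"recessive"` or `"abo"`.
#' @return Character vector of calls (`"positive"`/`"negative"`, or
#'   `A`/`B`/`AB`/`O`).
#' @export
derive_phenotypes <- function(counts, inheritance = c("dominant", "recessive", "abo")) {
  inheritance <- match.arg(inheritance)
  if (inheritance == "abo") {
    stopifnot(is.matrix(counts), all(c("A", "B") %in% colnames(counts)))
    a <- counts[, "A"]
    b <- counts[, "B"]
    stopifnot(all(a == round(a)), all(b == round(b)))
    ifelse(a > 0 & b > 0, "AB", ifelse(a > 0, "A", ifelse(b > 0, "B", "O")))
  } else {
    stopifnot(all(counts == round(counts)))
    need <- if (inheritance == "dominant") 1L else 2L
    ifelse(counts >= need, "positive", "negative")
  }
}

# Draw per-variant allele counts for one cohort given a panel. Tags copy the
# causal haplotype allele and switch to an independent draw with probability
# 1 - sqrt(r2). Returns list(counts = n x nv integer matrix, truth).
draw_genotypes <- function(panel, config, antigens) {
  n <- config$n_samples
  nv <- nrow(panel)
  counts <- matrix(0L, n, nv)
  truth <- list()
  for (a in antigens) {
    rows_a <- which(panel$antigen %in% a$antigen & panel$gene == a$gene)
    if (a$inheritance == "abo") {
      hap1 <- sample(names(a$abo_freqs), n, replace = TRUE, prob = a$abo_freqs)
      hap2 <- sample(names(a$abo_freqs), n, replace = TRUE, prob = a$abo_freqs)
      hap_ind <- list(A = cbind(hap1 == "A", hap2 == "A"),
                      B = cbind(hap1 == "B", hap2 == "B"))
      hap_freq <- c(A = unname(a$abo_freqs["A"]), B = unname(a$abo_freqs["B"]))
      if (!is.null(a$a1_freq)) {
        a1_1 <- hap_ind$A[, 1] & stats::runif(n) < a$a1_freq
        a1_2 <- hap_ind$A[, 2] & stats::runif(n) < a$a1_freq
        hap_ind$A1 <- cbind(a1_1, a1_2)
        hap_freq["A1"] <- unname(a$abo_freqs["A"]) * a$a1_freq
      }
    } else {
      h <- cbind(stats::runif(n) < a$effect_allele_freq,
                 stats::runif(n) < a$effect_allele_freq)
      hap_ind <- stats::setNames(list(h), a$antigen)
      hap_freq <- stats::setNames(a$effect_allele_freq, a$antigen)
    }
    causal_keys <- character(0)
    tag_info <- list()
    for (sr in names(hap_ind)) {
      ci <- rows_a[panel$role[rows_a] == "causal" & panel$subrole[rows_a] == sr]
      hp <- hap_ind[[sr]]
      counts[, ci] <- as.integer(hp[, 1]) + as.integer(hp[, 2])
      causal_keys <- c(causal_keys, panel$key[ci])
      tis <- rows_a[panel$role[rows_a] == "tag" & panel$subrole[rows_a] == sr]
      s <- 1 - sqrt(panel$tag_r2[tis])
      for (jj in seq_along(tis)) {
        ti <- tis[jj]
        t1 <- ifelse(stats::runif(n) < s[jj], stats::runif(n) < hap_freq[[sr]], hp[, 1])
        t2 <- ifelse(stats::runif(n) < s[jj], stats::runif(n) < hap_freq[[sr]], hp[, 2])
        counts[, ti] <- as.integer(t1) + as.integer(t2)
        tag_info[[panel$key[ti]]] <- list(
          causal = panel$key[ci],
          target_r2 = panel$tag_r2[ti],
          realized_r2 = suppressWarnings(stats::cor(counts[, ti], counts[, ci]))^2
        )
      }
    }
    truth[[a$antigen]] <- list(
      antigen = a$antigen, system = a$system, gene = a$gene,
      inheritance = a$inheritance,
      causal_keys = causal_keys,
      effect_freqs = if (a$inheritance == "abo") as.list(a$abo_freqs) else a$effect_allele_freq,
      tags = tag_info
    )
  }
  noise <- which(panel$role == "noise")
  for (j in noise) counts[, j] <- stats::rbinom(n, 2L, panel$freq[j])
  list(counts = counts, truth = truth)
}

#' Simulate a synthetic blood-group cohort
#'
#' Generates allele dosages, antigen typing calls and a ground-truth record
#' for a cohort defined by a [sim_cohort_config()]. Causal haplotype alleles
#' are drawn i.i.d. at the effect-allele frequency; tag SNPs copy the causal
#' haplotype with a switch probability hitting the target `r^2`; noise
#' variants are independent. Dosage = allele count + truncated Gaussian
#' noise, clipped to \[0, 2\] and quantized to a 1/1024 grid (the finite
#' precision of printed dosage fields; on this grid the allele-orientation
#' flip `d -> 2 - d` is exactly involutive). Entries are masked missing at
#' `missing_rate`; phenotypes come from [derive_phenotypes()] applied to the
#' pre-noise causal genotypes, masked to each antigen's `typed_fraction`.
#' Fully reproducible by seed.
#'
#' @param config A [sim_cohort_config()].
#' @param sample_prefix Prefix for generated sample identifiers.
#' @return A list of class `sim_cohort`: `dosages` (a [dosage_matrix()]),
#'   `phenotypes` (a `phenotype_table`), `truth` (per-antigen causal keys,
#'   realized tag `r^2`, generating frequencies), `regions` (a
#'   [gene_regions()] table for the simulated genes).
#' @export
simulate_cohort <- function(config, sample_prefix = "S") {
  stopifnot(inherits(config, "sim_cohort_config"))
  panel <- build_panel(config)
  out <- withr::with_seed(config$seed, {
    sim_draw(panel, config, config$antigens, sample_prefix)
  })
  out$regions <- panel_regions(config)
  out
}

sim_draw <- function(panel, config, antigens, sample_prefix,
                     drop_mask = NULL, flip_mask = NULL) {
  n <- config$n_samples
  ids <- sprintf("%s%05d", sample_prefix, seq_len(n))
  g <- draw_genotypes(panel, config, antigens)

  # phenotypes from pre-noise causal genotypes
  pheno <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  for (a in antigens) {
    ci <- which(panel$role == "causal" & panel$antigen %in% a$antigen &
                  panel$gene == a$gene)
    if (a$inheritance == "abo") {
      cm <- g$counts[, ci, drop = FALSE]
      colnames(cm) <- panel$subrole[ci]
      calls <- derive_phenotypes(cm[, c("A", "B")], "abo")
      if (!is.null(a$a1_freq)) {
        a1 <- ifelse(calls == "A",
                     ifelse(cm[, "A1"] >= 1L, "positive", "negative"),
                     NA_character_)
      }
    } else {
      calls <- derive_phenotypes(g$counts[, ci], a$inheritance)
    }
    untyped <- stats::runif(n) >= a$typed_fraction
    calls[untyped] <- NA
    pheno[[a$antigen]] <- calls
    if (a$inheritance == "abo" && !is.null(a$a1_freq)) {
      a1[untyped] <- NA
      pheno[["A1"]] <- a1
    }
  }
  class(pheno) <- c("phenotype_table", "data.frame")

  # dosages: noise, clip, quantize, mask
  d <- g$counts + stats::rnorm(length(g$counts), 0, config$dosage_noise_sd)
  d[] <- round(pmin(2, pmax(0, d)) * 1024) / 1024  # clip, then 1/1024 grid
  if (config$missing_rate > 0) {
    d[stats::runif(length(d)) < config$missing_rate] <- NA_real_
  }

  variants <- panel[, c("chrom", "pos", "ref", "alt", "key")]
  truth <- g$truth
  if (!is.null(drop_mask)) {
    truth$dropped_keys <- variants$key[drop_mask]
    d <- d[, !drop_mask, drop = FALSE]
    variants <- variants[!drop_mask, , drop = FALSE]
    flip_mask <- flip_mask[!drop_mask]
  }
  if (!is.null(flip_mask) && any(flip_mask)) {
    orig <- variants$key[flip_mask]
    tmp <- variants$ref[flip_mask]
    variants$ref[flip_mask] <- variants$alt[flip_mask]
    variants$alt[flip_mask] <- tmp
    variants$key <- variant_key(variants$chrom, variants$pos, variants$ref, variants$alt)
    d[, flip_mask] <- 2 - d[, flip_mask]
    truth$flipped_keys <- stats::setNames(variants$key[flip_mask], orig)
  }
  dimnames(d) <- list(ids, variants$key)

  structure(list(dosages = dosage_matrix(d, variants),
                 phenotypes = pheno, truth = truth),
            class = "sim_cohort")
}

panel_regions <- function(config) {
  df <- do.call(rbind, lapply(config$genes, function(g) {
    data.frame(system = g$system, gene = g$gene, chrom = g$chrom,
               start = g$start, end = g$start + (g$n_variants - 1L) * g$spacing,
               stringsAsFactors = FALSE)
  }))
  gene_regions(df)
}

#' Simulate a replication cohort
#'
#' Re-draws a cohort under the same generative law and variant panel as
#' `base`, but with the conditions of an independent validation cohort:
#' effect-allele frequencies shifted by `freq_shift`, a `1 - panel_overlap`
#' fraction of panel variants absent (possibly including causal variants —
#' the scenario in which tag SNPs and mean imputation must carry the model),
#' a `flip_fraction` of the remaining non-palindromic variants stored with
#' swapped ref/alt alleles and dosage `2 - d`, and `extra_missing`
#' additional dosage missingness. Palindromic variants are never flipped:
#' an orientation flip there is indistinguishable from a strand flip, which
#' the harmonizer's default policy refuses.
#'
#' @param base The base [sim_cohort_config()].
#' @param freq_shift Added to every effect-allele frequency (clamped to
#'   (0.001, 0.999)).
#' @param panel_overlap Fraction of panel variants present (in \[0, 1\]).
#' @param flip_fraction Fraction of eligible variants stored flipped.
#' @param extra_missing Additional missingness rate.
#' @param seed Seed for the replication draws (the panel stays that of
#'   `base$seed`).
#' @param sample_prefix Prefix for replication sample identifiers.
#' @return A `sim_cohort` list; `truth` additionally records `dropped_keys`
#'   and the original-to-stored key map `flipped_keys`.
#' @export
simulate_replication_cohort <- function(base, freq_shift = 0.02,
                                        panel_overlap = 0.9,
                                        flip_fraction = 0.3,
                                        extra_missing = 0.05,
                                        seed = base$seed + 1L,
                                        sample_prefix = "R") {
  stopifnot(inherits(base, "sim_cohort_config"))
  for (v in c(panel_overlap, flip_fraction, extra_missing)) {
    if (v < 0 || v > 1) stop("fractions must be in [0, 1]")
  }
  clamp <- function(f) pmin(0.999, pmax(0.001, f + freq_shift))
  antigens <- lapply(base$antigens, function(a) {
    if (a$inheritance == "abo") {
      fr <- a$abo_freqs
      fr["A"] <- clamp(fr["A"])
      fr["B"] <- clamp(fr["B"])
      a$abo_freqs <- fr / sum(fr)
    } else {
      a$effect_allele_freq <- clamp(a$effect_allele_freq)
    }
    a
  })
  cfg <- base
  cfg$antigens <- antigens
  cfg$missing_rate <- min(0.99, base$missing_rate + extra_missing)
  cfg$seed <- as.integer(seed)

  panel <- build_panel(base)
  out <- withr::with_seed(as.integer(seed), {
    drop_mask <- stats::runif(nrow(panel)) > panel_overlap
    eligible <- !drop_mask & !is_palindromic(panel$ref, panel$alt)
    flip_mask <- eligible & stats::runif(nrow(panel)) < flip_fraction
    sim_draw(panel, cfg, antigens, sample_prefix,
             drop_mask = drop_mask, flip_mask = flip_mask)
  })
  out$regions <- panel_regions(base)
  out
}
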