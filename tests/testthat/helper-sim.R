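# Shared fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

tiny_genes <- function() {
  list(sim_gene("KEL", "Kell", "7", 10000001L, 40L),
       sim_gene("ABO", "ABO", "9", 133200001L, 50L))
}

tiny_config <- function(n = 400L, seed = 11L, noise = 0.05, miss = 0) {
  sim_cohort_config(
    n_samples = n,
    genes = tiny_genes(),
    antigens = list(
      antigen_sim_model("K", "Kell", "KEL", "dominant", 0.3),
      antigen_sim_model("ABO", "ABO", "ABO", "abo",
                        abo_freqs = c(A = 0.26, B = 0.06, O = 0.68))
    ),
    dosage_noise_sd = noise, missing_rate = miss, seed = seed
  )
}

tiny_cohort <- function() cached("tiny_cohort", simulate_cohort(tiny_config()))

# a small trained binary model shared by engine/bundle/prediction tests
tiny_k_model <- function() {
  cached("tiny_k_model", {
    co <- tiny_cohort()
    fit_antigen_model(co$dosages$dosages, co$phenotypes$K,
                      antigen = "K", system = "Kell",
                      config = forest_config(n_trees = 300L, seed = 5L))
  })
}

# dosages on the 1/1024 grid (the simulator's emitted precision)
grid_dosages <- function(n, m, seed = 1L) {
  withr::with_seed(seed, {
    d <- matrix(round(runif(n * m, 0, 2) * 1024) / 1024, n, m)
  })
  rownames(d) <- sprintf("S%03d", seq_len(n))
  colnames(d) <- variant_key("1", seq_len(m) * 10L, "A", "G")
  d
}

random_calls <- function(n, p_pos = 0.5) {
  ifelse(runif(n) < p_pos, "positive", "negative")
}

write_tiny_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  writeLines(lines, path)
  path
}

vcf_header <- function(samples, contigs = "1") {
  c("##fileformat=VCFv4.2",
    paste0("##contig=<ID=", contigs, ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=A,Type=Float,Description=\"Dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}
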