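# Small generators used across test files. All randomness is seeded at the
# call sites via withr::local_seed / set.seed.

# Independent HWE genotype matrix at given allele frequencies.
make_G <- function(n, mafs) {
  G <- sapply(mafs, function(q) rbinom(n, 2, q))
  colnames(G) <- paste0("v", seq_along(mafs))
  G
}

# A tiny island/variant world built directly (no simulator) for region tests.
toy_islands <- function() {
  tibble::tibble(island_id = c("A", "B"), chrom = "chr1",
                 start = c(10000, 100000), end = c(12000, 103000))
}

toy_variants <- function() {
  tibble::tibble(
    variant_id = paste0("v", 1:6),
    chrom = "chr1",
    # 0-based coords 10499, 11499, 12999 (shore), 15499 (shelf), 99000-ish
    pos = c(10500, 11500, 13000, 15500, 100500, 102500),
    maf = c(0.004, 0.02, 0.03, 0.01, 0.2, 0.04),
    info_score = 0.95, hwe_p = 0.5)
}

# Fixture configs for scan-level tests; modest sizes keep the suite quick.
scan_config <- function(seed = 101, n_samples = 400, scenarios = list()) {
  sim_config(n_samples = n_samples, n_islands = 8,
             effect_scenarios = scenarios, seed = seed)
}
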