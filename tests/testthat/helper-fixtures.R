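# Shared fixture builders. Cohort planting lives in the package itself
# (plant_cohort / random_plant_specs); only thin aliases and tiny static
# genomes are defined here.

write_fixture_vcf <- function(genome, variants, path, clnsig = NULL) {
  write_deletions_vcf(genome, variants, path, clnsig = clnsig)
}

# A tiny deterministic genome with hand-placed structure used by several
# format tests.
tiny_genome <- function() {
  new_genome(c(c1 = "TTACAGCAGGTTACGTACGTAAATTTCCCGGG",
               c2 = "ACGTACGTACGTACGTACGT"))
}
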