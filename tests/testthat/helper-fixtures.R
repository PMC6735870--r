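# shared fixtures: built once per test run, in code (no stored data)

# direct two-pass Pearson sliding scan: the independent oracle for the
# FFT/prefix-sum implementation
naive_pearson_scan <- function(q, r) {
  n <- length(q)
  vapply(seq_len(length(r) - n + 1), function(s) {
    w <- r[s:(s + n - 1)]
    if (sd(w) == 0 || sd(q) == 0) return(-Inf)
    cor(q, w)
  }, numeric(1))
}

# mild ligand parameters for enumeration tests: weights of order 1 so both
# species place often and partition functions stay comfortable
mild_params <- function() {
  ligand_params(netropsin_conc = 1e-6, yoyo_conc = 1e-6,
                affinity = netropsin_affinity_table(4, at_K = 3e6,
                                                    other_K = 5e5),
                yoyo_K = 8e5)
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# small shared theory genomes (cost a few seconds, reused across files)
th_1mb <- theory_genome(random_genome(1e6, seed = 101))
th_small <- theory_genome(random_genome(1.2e5, seed = 102))
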