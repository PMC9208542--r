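# shared fixtures, built once per test run

cached <- new.env(parent = emptyenv())

# the bundled orthogroup profiles (build + calibration ~20 s, reused widely)
ref_profiles <- function() {
  if (is.null(cached$profiles)) cached$profiles <- reference_profiles(seed = 1)
  cached$profiles
}

# a small proteome generated from the default chordate history
ref_bundle <- function() {
  if (is.null(cached$bundle)) {
    cfg <- sim_config(seed = 11)
    truth <- simulate_history(cfg)
    prot <- generate_proteome(truth, ref_profiles(), cfg)
    cached$bundle <- list(cfg = cfg, truth = truth, proteome = prot$proteome,
                          membership = prot$membership)
  }
  cached$bundle
}

# consolidated calls for the bundle proteome (classification ~30 s, reused)
ref_calls <- function() {
  if (is.null(cached$calls)) {
    b <- ref_bundle()
    cached$calls <- classify_sequences(b$proteome, ref_profiles())
  }
  cached$calls
}

# one implanted member sequence per orthogroup (deterministic)
member_of <- function(label, seed = 99) {
  profs <- ref_profiles()
  imp <- dnaserep:::implant_table()
  row <- imp[imp$label == label, ]
  core <- withr::with_seed(seed, dnaserep:::implant_core(profs[[label]]))
  paste0(row$prefix, core, row$suffix)
}

# gappy toy MSA over a 4-letter reduced alphabet (non-trivial I/D structure)
toy_msa_gappy <- function() {
  aa_alignment(tibble::tibble(
    id = paste0("s", 1:4),
    aligned = c("AC-DE", "ACGDE", "AC-D-", "A-GDE")))
}

toy_msa_clean <- function(seq = "ACDE", n = 3) {
  aa_alignment(tibble::tibble(id = paste0("r", seq_len(n)),
                              aligned = rep(seq, n)))
}

all_strings <- function(alphabet, len) {
  do.call(paste0, expand.grid(rep(list(alphabet), len),
                              stringsAsFactors = FALSE))
}

random_protein <- function(len) {
  paste(sample(dnaserep:::AA20, len, replace = TRUE), collapse = "")
}
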