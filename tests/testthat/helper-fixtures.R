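# Shared fixtures. Library generation and fingerprinting dominate test
# runtime, so every test file draws from one session-level cache.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# Small synthetic world shared across module tests.
fixture_gen <- function(n_base = 40, seed = 101) {
  cached(sprintf("gen_%d_%d", n_base, seed),
         generate_library(generator_params(n_base_metabolites = n_base,
                                           rng_seed = seed)))
}

fixture_fps <- function(n_base = 40, seed = 101) {
  cached(sprintf("fps_%d_%d", n_base, seed), {
    gen <- fixture_gen(n_base, seed)
    fps <- compute_fingerprints(gen$library$smiles, fingerprint_config())
    rownames(fps) <- gen$library$record_id
    fps
  })
}

fixture_spectra <- function(n_base = 40, seed = 101) {
  cached(sprintf("sp_%d_%d", n_base, seed), {
    gen <- fixture_gen(n_base, seed)
    generate_spectra(gen$library, gen$truth)
  })
}

# Hand-written miniature library covering known chemistry: ethanol and
# ethylene glycol with 0-2 TMS groups, plus an amino acid-like record.
tiny_records <- function() {
  data.frame(
    record_id = c("eth0", "eth1", "gly0", "gly1", "gly2", "ala2"),
    base_id = c("eth", "eth", "gly", "gly", "gly", "ala"),
    name = c("ethanol", "ethanol 1TMS", "glycol", "glycol 1TMS",
             "glycol 2TMS", "alanine 2TMS"),
    smiles = c("CCO", "CCO[Si](C)(C)C", "OCCO", "OCCO[Si](C)(C)C",
               "C(CO[Si](C)(C)C)O[Si](C)(C)C",
               "CC(N[Si](C)(C)C)C(=O)O[Si](C)(C)C"),
    n_tms = c(0L, 1L, 0L, 1L, 2L, 2L),
    ri = c(450, 780, 700, 910, 1080, 1110),
    stringsAsFactors = FALSE)
}

tiny_library <- function() {
  cached("tiny", derivative_library(
    cbind(tiny_records(),
          monoisotopic_mass = monoisotopic_mass(tiny_records()$smiles)),
    provenance = "tiny fixture"))
}

# Random 0/1 fingerprint pair for property tests.
random_bits <- function(n_bits = 64, density = 0.3) {
  as.integer(runif(n_bits) < density)
}

write_tiny_csv <- function(path, records = tiny_records()) {
  utils::write.table(records, path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  path
}

# Ranked candidate sets with prescribed errors, for evaluator tests.
ranked_from_errors <- function(true_error, pim_errors) {
  set <- structure(list(mode = "ci", seed_record_id = "T",
                        pim_ids = sprintf("P%d", seq_along(pim_errors)),
                        reference_ri = 1000),
                   class = "candidate_set")
  pred <- c(T = 1000 * (1 + true_error / 100),
            setNames(1000 * (1 + pim_errors / 100),
                     sprintf("P%d", seq_along(pim_errors))))
  rank_candidates(set, pred)
}
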