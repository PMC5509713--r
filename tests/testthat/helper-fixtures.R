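## Lazily built, cached across test files within one test run.
get_fixture42 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_fixture(sim_config(seed = 42L))
    cache
  }
})

toy_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- read_energy_model(energy_model_path("toy"))
    cache
  }
})

default_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- read_energy_model(energy_model_path("default"),
                                  temperature = 25)
    }
    cache
  }
})

## evidence bundle straight from a fixture's emitted tables, exactly as
## the cli would assemble it
fixture_evidence <- function(fx, e_symbiont = 1e-3) {
  ev <- fx$evidence_tables
  widths <- setNames(Biostrings::width(fx$transcripts),
                     names(fx$transcripts))
  symb_ids <- symbiont_contaminants(ev$symbiont_hits, widths,
                                    ev$subject_lengths,
                                    e_cutoff = e_symbiont)
  build_evidence_bundle(names(fx$transcripts), symbiont_ids = symb_ids,
                        protein_hits = ev$protein_hits,
                        domain_hits = ev$domain_hits,
                        signal_calls = ev$signal_calls,
                        housekeeping_hits = ev$housekeeping_hits)
}

write_tsv_lines <- function(lines, path) {
  writeLines(lines, path)
  path
}
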