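# Builders for small in-code fixtures used across the test files.

# Clean (noiseless) percent-scale dataset from per-temperature rate
# constants, optionally several treatments/replicates.
clean_dataset <- function(k_by_temp = c(`4` = 0.1, `8` = 0.15, `16` = 0.3,
                                        `20` = 0.45),
                          treatments = "control", replicates = 1L,
                          days = 0:5) {
  rows <- list()
  for (tr in treatments) {
    for (tt in names(k_by_temp)) {
      for (r in seq_len(replicates)) {
        rows[[length(rows) + 1L]] <- data.frame(
          treatment = tr, temperature_c = as.numeric(tt), replicate = r,
          day = days, tbars = 100 * exp(k_by_temp[[tt]] * days),
          scale = "percent", stringsAsFactors = FALSE)
      }
    }
  }
  kinetic_dataset(do.call(rbind, rows))
}

# Published control-row rate constants (mean k, day^-1) keyed by printed
# kelvin, pulled from the packaged fixture so tests state them only once.
control_rates <- function() {
  pub <- published_rate_constants()
  pub[pub$extract == "control", ]
}
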