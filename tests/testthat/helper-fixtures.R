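# Shared fixtures built in code.

# A sample of size n with *exact* mean m and sample SD s (moment-matched by
# standardising an arbitrary base vector). Used to reconstruct observation
# vectors that are summary-equivalent to published mean/SD/n rows.
make_sample <- function(m, s, n) {
  z <- seq_len(n)
  m + s * (z - mean(z)) / sd(z)
}

# Zero-SD observation table: every observation equals its species-period mean.
zero_sd_obs <- function(specs) {
  do.call(rbind, lapply(seq_len(nrow(specs)), function(i) {
    tibble::tibble(species = specs$species[i], period = specs$period[i],
                   diameter = rep(specs$mean[i], specs$n[i]))
  }))
}

write_csv_lines <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

# Table of the study's per-species summary statistics (the synthetic
# generator's target parameters), handy for summary-level tests.
study_specs <- function() default_config()$specs
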