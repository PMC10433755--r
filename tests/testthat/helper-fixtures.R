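# Small shared fixtures, built in code at test time.

five_arm_table <- function(arm_length = 2e4) {
  genome_table(stats::setNames(rep(arm_length, 5),
                               c("2L", "2R", "3L", "3R", "X")))
}

# A miniature planted-signal world reused by dataset/model tests:
# 60 kb arms, `n` peaks, configurable signal geometry.
tiny_world <- function(n = 60, signal_strength = 1, offset = 0, seed = 7,
                       arm_length = 6e4, width_mean = 120, width_sd = 25) {
  arms <- stats::setNames(rep(arm_length, 5), c("2L", "2R", "3L", "3R", "X"))
  sim <- simulate_genome(arms, seed = derive_seed(seed, 1))
  spec <- assay_sim_spec("tiny", peak_count = n, width_mean = width_mean,
                         width_sd = width_sd,
                         signal_strength = signal_strength,
                         motifs_per_peak = 2, summit_offset_bp = offset,
                         seed = derive_seed(seed, 2))
  planted <- plant_peaks(sim$sequences, sim$genome, spec)
  list(sim = sim, planted = planted, spec = spec)
}

write_temp_narrowpeak <- function(lines) {
  path <- withr::local_tempfile(fileext = ".narrowPeak",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
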