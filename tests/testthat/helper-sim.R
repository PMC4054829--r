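# A scaled-down simulation configuration with the same statistical
# structure as the default (cohort sizes, detection probability, noise,
# biases, expression noise) but a smaller genome, used where a test loops
# over many seeds. Overrides in `...` win over the scaled defaults.
small_sim_config <- function(seed, ...) {
  args <- utils::modifyList(
    list(
      chrom_length = 3e5,
      n_blocks = 40L,
      noise_peaks = 15L,
      n_target_genes = 6L,
      n_group = c(I = 8L, II = 10L, IV = 10L, V = 8L),
      n_silent_both = 5L,
      n_terms = 12L,
      term_size = c(6L, 8L)
    ),
    list(...)
  )
  do.call(simulate_config, c(list(seed = seed), args))
}
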