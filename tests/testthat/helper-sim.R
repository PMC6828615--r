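# Small configurations used across tests: a 12 cm hose (10 sections per
# half) and a coarse imaging grid keep the unit suite fast.

small_cfg <- function(seed = 1, ...) {
  defaults <- list(hose_length = 12, n_taxa = 60,
                   dominant_profile = c(Cytophagaceae = 0.247,
                                        Bradyrhizobium = 0.234,
                                        TM6_Dependentiae = 0.096),
                   step_changes = list(), reads_per_section = 5000,
                   missing_section_prob = 0, seed = seed)
  override <- list(...)
  defaults[names(override)] <- override   # wholesale, no list recursion
  do.call(sim_config, defaults)
}

coarse_imaging <- function(...) {
  args <- utils::modifyList(list(axial_pixel = 4, lateral_pixel = 8,
                                 noise_sd = 0), list(...))
  do.call(imaging_config, args)
}

small_layout <- function() {
  hose_layout(n_pieces = 2)
}

# flat-field config: no trend, no small-scale noise
flat_cfg <- function(baseline = 300, seed = 1, ...) {
  sim_config(hose_length = 12,
             baseline_thickness = c(top = baseline, bottom = baseline),
             trend_slope = c(top = 0, bottom = 0),
             smallscale_cv = c(top = 0, bottom = 0),
             step_changes = list(), missing_section_prob = 0,
             n_taxa = 20, reads_per_section = 1000, seed = seed, ...)
}

random_counts <- function(n_taxa, n_sections, lambda = 20) {
  matrix(stats::rpois(n_taxa * n_sections, lambda), n_taxa, n_sections,
         dimnames = list(sprintf("t%03d", seq_len(n_taxa)),
                         sprintf("s%03d", seq_len(n_sections))))
}
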