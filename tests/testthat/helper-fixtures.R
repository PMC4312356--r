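# Shared fixtures, built once per test run and cached in an environment.
.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

noisy_control <- function(seed = 1L)
  control_preset(noise_sd_current = 2, noise_sd_fluo = 0.01, seed = seed)

noisy_hf <- function(seed = 1L)
  hf_preset(noise_sd_current = 2, noise_sd_fluo = 0.01, seed = seed)

# one clean (noiseless) control cell with all three protocol traces
clean_control_record <- function() {
  cached("clean_control_record",
         atriaflux:::simulate_cell_record(control_preset(),
                                          atriaflux:::default_protocols(),
                                          "ctrl_cell", "ctrl_animal"))
}

clean_hf_record <- function() {
  cached("clean_hf_record",
         atriaflux:::simulate_cell_record(hf_preset(),
                                          atriaflux:::default_protocols(),
                                          "hf_cell", "hf_animal"))
}

# the study-sized noisy cohort (6 + 6 animals x 4 cells) and its analysis
study_cohort <- function() {
  cached("study_cohort",
         make_cohort(noisy_control(), noisy_hf(), n_animals = 6,
                     cells_per_animal = 4, seed = 20260923L))
}

study_pipeline <- function() {
  cached("study_pipeline", run_pipeline(study_cohort()))
}

truth_table <- function(cohort) {
  do.call(rbind, lapply(cohort, function(r) {
    ts <- r$truth_summary
    data.frame(cell_id = r$cell_id, amplitude = ts$amplitude_nM,
               k_sys = ts$k_sys, k_caff = ts$k_caff, k_pmca = ts$k_pmca,
               beta = ts$beta, g_ncx = ts$g_ncx,
               peak = ts$peak_density, entry = ts$entry_umol,
               sr = ts$sr_at_caffeine_caffeine)
  }))
}

rel_bias_pct <- function(measured, truth) 100 * mean(measured / truth - 1)
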