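# Shared fixtures and independent oracles.

# small complete label set: one figure, three grid points
tiny_labels <- function(paper = "paperA", fig = "fig1") {
  record_set(data.frame(
    paper_id = paper, figure_id = fig,
    protein_name = "fus",
    protein_conc_um = c(1, 5, 10), rna_conc_um = c(0.1, 0.5, 1),
    ph = 7.4, temperature_c = 25, phase_status = c(0L, 0L, 1L),
    stringsAsFactors = FALSE), origin = "label")
}

# exhaustive-permutation minimum assignment cost (oracle for the
# Hungarian solver); feasible for min(dim) <= 7
brute_min_cost <- function(C) {
  n <- nrow(C); m <- ncol(C)
  if (n > m) return(brute_min_cost(t(C)))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  best <- Inf
  for (cols in utils::combn(m, n, simplify = FALSE)) {
    for (p in perms(cols)) {
      best <- min(best, sum(C[cbind(seq_len(n), p)]))
    }
  }
  best
}

# gestalt similarity values frozen from Python difflib SequenceMatcher
# (the reference implementation of the ratio this package computes)
DIFFLIB_RATIOS <- data.frame(
  a = c("abc", "FUS", "polyU", "fused in sarcoma", "hnRNPA1", "G3BP1",
        "TDP-43", "polyA RNA", "LAF-1", "abcdef", ""),
  b = c("abd", "FUS", "", "fus", "hnRNP A1", "PGL-3",
        "TDP43", "poly(A) RNA", "DDX4", "abcdxf", ""),
  ratio = c(0.6666666666666666, 1.0, 0.0, 0.3157894736842105,
            0.9333333333333333, 0.4, 0.9090909090909091, 0.9,
            0.0, 0.8333333333333334, 1.0),
  stringsAsFactors = FALSE)

# standard benchmark-style scenario used across tests
make_scenario <- function(seed, rate, n_figures = 3,
                          numeric_noise_sd = 0.01,
                          unit_jitter_rate = 0.1, threshold = 0.2) {
  labels <- generate_labels(generator_config(n_figures = n_figures,
                                             seed = seed))
  corrupt(labels,
          corruption_config(numeric_noise_sd = numeric_noise_sd,
                            miss_field_rate = rate,
                            drop_record_rate = rate,
                            spurious_record_rate = rate,
                            typo_rate = rate,
                            unit_jitter_rate = unit_jitter_rate,
                            seed = seed + 10000L),
          threshold = threshold)
}

# evaluator tally for one figure of a scenario
scenario_figure_tally <- function(ev, fig) {
  key <- grep(paste0("::", fig, "$"), names(ev$scopes), value = TRUE)
  ev$scopes[[key]]$tally
}
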