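test_that("label generation is deterministic and grid-structured", {
  cfg <- generator_config(n_figures = 5, seed = 7)
  a <- generate_labels(cfg)
  b <- generate_labels(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  meta <- attr(a, "figure_meta")
  expect_identical(nrow(meta), 5L)
  for (fig in unique(a$figure_id)) {
    L <- a[a$figure_id == fig, , drop = FALSE]
    expect_gte(nrow(L), 3)
    expect_lte(nrow(L), 40)
    expect_identical(length(unique(L$protein_name)), 1L)
    expect_identical(length(unique(L$ph)), 1L)
    expect_identical(length(unique(L$temperature_c)), 1L)
    # full grid: #records = #protein levels x #rna levels
    expect_identical(nrow(L),
                     length(unique(L$protein_conc_um)) *
                       length(unique(L$rna_conc_um)))
    # both phase outcomes occur and phase is monotone in the product
    expect_setequal(unique(L$phase_status), c(0L, 1L))
    cutoff <- meta$cutoff[meta$figure_id == fig]
    expect_identical(L$phase_status,
                     as.integer(L$protein_conc_um * L$rna_conc_um > cutoff))
    expect_false(anyNA(as.data.frame(L)[, unname(
      llpsie:::FIELD_VALUE_COLUMN)]))
  }
})

test_that("the default configuration matches the benchmark scale", {
  labels <- generate_labels(generator_config(seed = 123))
  expect_identical(length(unique(labels$figure_id)), 49L)
  # ~18 experiments/figure on average => ~880 records (expectation
  # bookkeeping: grid sizes 3:6 x 3:5 drawn uniformly)
  expect_gt(nrow(labels), 700)
  expect_lt(nrow(labels), 1060)
  expect_identical(length(unique(labels$paper_id)), 17L)
})

test_that("zero corruption reproduces the labels with perfect expected tallies", {
  labels <- generate_labels(generator_config(n_figures = 3, seed = 2))
  s <- corrupt(labels, corruption_config(numeric_noise_sd = 0, seed = 9))
  a <- as.data.frame(s$extracted)
  a <- a[order(a$figure_id, a$protein_conc_um, a$rna_conc_um), ]
  rownames(a) <- NULL
  attributes(a)[c("origin")] <- NULL
  b <- as.data.frame(labels)
  rownames(b) <- NULL
  attributes(b)[c("origin", "figure_meta")] <- NULL
  expect_identical(a, b)
  for (fig in names(s$expected_tallies)) {
    t <- s$expected_tallies[[fig]]
    n <- sum(labels$figure_id == fig)
    expect_true(all(t[, "tp"] == n))
    expect_true(all(t[, "fp"] == 0L))
    expect_true(all(t[, "fn"] == 0L))
  }
})

test_that("record drops become false negatives in every present field", {
  labels <- generate_labels(generator_config(n_figures = 4, seed = 13))
  s <- corrupt(labels, corruption_config(numeric_noise_sd = 0,
                                         drop_record_rate = 0.3,
                                         seed = 31))
  for (fig in names(s$expected_tallies)) {
    n <- sum(labels$figure_id == fig)
    k <- sum(s$extracted$figure_id == fig)
    t <- s$expected_tallies[[fig]]
    expect_true(all(t[, "fn"] == n - k))  # labels are complete
    expect_true(all(t[, "tp"] == k))
    expect_true(all(t[, "fp"] == 0L))
  }
})

test_that("spurious insertions become false positives in their present fields", {
  labels <- generate_labels(generator_config(n_figures = 4, seed = 14))
  s <- corrupt(labels, corruption_config(numeric_noise_sd = 0,
                                         spurious_record_rate = 0.8,
                                         seed = 32))
  total_spurious <- nrow(s$extracted) - nrow(labels)
  expect_gt(total_spurious, 0)
  for (fig in names(s$expected_tallies)) {
    n <- sum(labels$figure_id == fig)
    k <- sum(s$extracted$figure_id == fig) - n
    t <- s$expected_tallies[[fig]]
    for (f in c("protein_name", "protein_conc", "rna_conc")) {
      expect_identical(unname(t[f, "fp"]), k)
    }
    for (f in c("ph", "temperature", "phase_status")) {
      expect_identical(unname(t[f, "fp"]), 0L)
    }
    expect_true(all(t[, "fn"] == 0L))
    expect_true(all(t[, "tp"] == n))
  }
})

test_that("scenarios are a pure function of their configuration", {
  mk <- function() make_scenario(77, rate = 0.15, n_figures = 3)
  a <- mk(); b <- mk()
  expect_identical(as.data.frame(a$extracted), as.data.frame(b$extracted))
  expect_identical(a$expected_tallies, b$expected_tallies)
  expect_identical(scenario_as_mock_script(a), scenario_as_mock_script(b))
})

test_that("the evaluator reproduces by-construction tallies under mixed corruption", {
  for (seed in 1:8) {
    rate <- c(0, 0.05, 0.2, 0.3)[seed %% 4 + 1]
    s <- make_scenario(seed * 3, rate = rate, n_figures = 2,
                       unit_jitter_rate = 0.2)
    ev <- evaluate_extraction(s$extracted, s$labels,
                              threshold = s$threshold)
    for (fig in names(s$expected_tallies)) {
      expect_identical(unclass(scenario_figure_tally(ev, fig)),
                       unclass(s$expected_tallies[[fig]]),
                       info = sprintf("seed %d fig %s", seed, fig))
    }
  }
})

test_that("as corruption vanishes all per-field F1 approach 1", {
  f1_at <- function(rate) {
    s <- make_scenario(55, rate = rate, n_figures = 3)
    ev <- evaluate_extraction(s$extracted, s$labels)
    ev$aggregate$f1_mean[ev$aggregate$field == "Average"]
  }
  expect_equal(f1_at(0), 1, tolerance = 1e-9)
  expect_gt(f1_at(0.05), f1_at(0.3))
})

test_that("the mock script reproduces the extracted set through the full pipeline", {
  s <- make_scenario(91, rate = 0.2, n_figures = 3,
                     unit_jitter_rate = 0.5)
  backend <- scenario_backend(s)
  bundles <- scenario_bundles(s)
  blocks <- default_prompt_blocks()
  got <- list()
  for (p in names(bundles)) {
    got <- c(got, run_figure_by_figure(bundles[[p]], "figure", blocks,
                                       "minimal_dk_guide", backend))
  }
  df <- do.call(rbind, lapply(got, as.data.frame))
  rownames(df) <- NULL
  exp <- as.data.frame(s$extracted)
  rownames(exp) <- NULL
  expect_identical(df, exp)
  # unit-jittered raw forms appear in the script and still round-trip
  script <- scenario_as_mock_script(s)
  expect_true(any(grepl(" mM| nM", unlist(script))))
  # an empty figure yields an empty JSON array response
  labels1 <- generate_labels(generator_config(n_figures = 1, seed = 6))
  s1 <- corrupt(labels1, corruption_config(numeric_noise_sd = 0,
                                           drop_record_rate = 1,
                                           seed = 8))
  expect_identical(nrow(s1$extracted), 0L)
  expect_identical(jsonlite::fromJSON(scenario_as_mock_script(s1)[[1]]),
                   list())
})
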