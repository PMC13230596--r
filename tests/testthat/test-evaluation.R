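test_that("numeric field distance follows the normalized-range formula", {
  expect_equal(numeric_field_distance(30, 25, c(20, 40)), 0.25)
  expect_equal(numeric_field_distance(7.0, 7.5, c(6.0, 8.0)), 0.25)
  expect_equal(numeric_field_distance(5, 5, c(0, 1)), 0)
  # values beyond the label range clamp to 1
  expect_equal(numeric_field_distance(1000, 25, c(20, 40)), 1)
  # degenerate range keeps exact-match semantics
  expect_equal(numeric_field_distance(25, 25, c(25, 25)), 0)
  expect_equal(numeric_field_distance(26, 25, c(25, 25)), 1)
  # symmetry
  expect_equal(numeric_field_distance(30, 25, c(20, 40)),
               numeric_field_distance(25, 30, c(20, 40)))
})

test_that("text distance reproduces the gestalt sequence-matcher ratio", {
  for (i in seq_len(nrow(DIFFLIB_RATIOS))) {
    expect_equal(
      text_field_distance(DIFFLIB_RATIOS$a[i], DIFFLIB_RATIOS$b[i]),
      1 - DIFFLIB_RATIOS$ratio[i], tolerance = 1e-12,
      info = paste(DIFFLIB_RATIOS$a[i], "vs", DIFFLIB_RATIOS$b[i]))
  }
  # symmetry over random strings
  set.seed(11)
  for (k in 1:30) {
    a <- paste(sample(letters[1:5], sample(0:8, 1), TRUE), collapse = "")
    b <- paste(sample(letters[1:5], sample(0:8, 1), TRUE), collapse = "")
    expect_equal(text_field_distance(a, b), text_field_distance(b, a))
    expect_gte(text_field_distance(a, b), 0)
    expect_lte(text_field_distance(a, b), 1)
  }
})

test_that("phase distance is the mismatch indicator", {
  expect_equal(phase_field_distance(1, 1), 0)
  expect_equal(phase_field_distance(0, 0), 0)
  expect_equal(phase_field_distance(1, 0), 1)
  expect_equal(phase_field_distance(0, 1), 1)
})

test_that("record cost averages six fields with the missing-field convention", {
  labels <- tiny_labels()
  ranges <- field_ranges(labels)
  l <- labels[1, , drop = FALSE]
  expect_equal(record_cost(l, l, ranges), 0)
  # temperature off by half the label range: the range here is
  # degenerate (all labels 25), so build a two-point range by hand
  e <- l
  e$temperature_c <- 35
  rg <- ranges
  rg$temperature <- c(20, 40)
  expect_equal(record_cost(e, l, rg), 0.5 / 6)
  # missing vs present counts 1; both-missing counts 0
  e <- l
  e$rna_conc_um <- NA_real_
  expect_equal(record_cost(e, l, ranges), 1 / 6)
  l2 <- l
  l2$rna_conc_um <- NA_real_
  expect_equal(record_cost(e, l2, ranges), 0)
})

test_that("non-convertible units compare numerically only on an exact unit match", {
  labels <- record_set(data.frame(
    paper_id = "p", figure_id = "f", protein_name = "fus",
    protein_conc_um = c(2, 4), protein_conc_unit = "mg/ml",
    ph = 7, stringsAsFactors = FALSE), origin = "label")
  ranges <- field_ranges(labels)
  same_unit <- labels[1, , drop = FALSE]
  expect_equal(record_cost(same_unit, labels[1, , drop = FALSE], ranges), 0)
  # same value, different unit scale: maximal mismatch
  e <- labels[1, , drop = FALSE]
  e$protein_conc_unit <- NA_character_
  d <- llpsie:::record_field_distances(e, labels[1, , drop = FALSE], ranges)
  expect_equal(unname(d["protein_conc"]), 1)
})

test_that("cost matrices are rectangular with entries in [0, 1]", {
  labels <- tiny_labels()
  C <- build_cost_matrix(labels[1, , drop = FALSE], labels)
  expect_identical(dim(C), c(1L, 3L))
  expect_equal(C[1, 1], 0)
  set.seed(21)
  s <- make_scenario(31, rate = 0.2, n_figures = 1)
  E <- s$extracted; L <- s$labels
  C <- build_cost_matrix(E, L)
  expect_true(all(C >= 0 & C <= 1))
  expect_error(build_cost_matrix(E[0, ], L),
               class = "llps_validation_error")
})

test_that("assignment solves small matrices and reports unmatched sides", {
  m <- solve_assignment(matrix(c(0.1, 0.8, 0.9, 0.2), 2, 2))
  expect_identical(m$pairs$extracted, c(1L, 2L))
  expect_identical(m$pairs$label, c(1L, 2L))
  expect_equal(m$total_cost, 0.3)
  m <- solve_assignment(matrix(c(0.6, 0.2), 1, 2))
  expect_identical(m$pairs$label, 2L)
  expect_identical(m$unmatched_labels, 1L)
  expect_length(m$unmatched_extracted, 0)
  m <- solve_assignment(matrix(c(0.6, 0.2, 0.9), 3, 1))
  expect_identical(m$pairs$extracted, 2L)
  expect_identical(sort(m$unmatched_extracted), c(1L, 3L))
})

test_that("assignment equals the exhaustive-permutation minimum up to 7x7", {
  set.seed(99)
  for (k in 1:50) {
    n <- sample(1:7, 1); m <- sample(1:7, 1)
    C <- matrix(round(runif(n * m), 3), n, m)  # rounding induces ties
    res <- solve_assignment(C)
    expect_equal(res$total_cost, brute_min_cost(C), tolerance = 1e-9)
    expect_identical(nrow(res$pairs), min(n, m))
    # determinism under ties
    expect_identical(solve_assignment(C)$pairs, res$pairs)
  }
})

test_that("classification follows the threshold and unmatched rules", {
  labels <- tiny_labels()
  ranges <- field_ranges(labels)
  C <- build_cost_matrix(labels, labels, ranges)
  m <- solve_assignment(C)
  tally <- classify_and_tally(m, labels, labels, ranges, threshold = 0.2)
  expect_true(all(tally[, "tp"] == 3L))
  expect_true(all(tally[, "fp"] == 0L))
  expect_true(all(tally[, "fn"] == 0L))

  # matched pair with one field distance 0.5 at threshold 0.2:
  # that field flips to FP, the others stay TP
  e <- as.data.frame(labels)
  e$rna_conc_um[2] <- e$rna_conc_um[2] + 0.45  # 0.45/0.9 = 0.5
  e <- record_set(e, origin = "extracted")
  C <- build_cost_matrix(e, labels, ranges)
  m <- solve_assignment(C)
  tally <- classify_and_tally(m, e, labels, ranges, threshold = 0.2,
                              field_distances = attr(C, "field_distances"))
  expect_identical(unname(tally["rna_conc", ]), c(2L, 1L, 0L))
  expect_identical(unname(tally["ph", ]), c(3L, 0L, 0L))

  # 1 extracted vs 3 labels, matched perfectly: TP=1, FN=2 per field
  e1 <- labels[1, , drop = FALSE]
  C <- build_cost_matrix(e1, labels, ranges)
  m <- solve_assignment(C)
  tally <- classify_and_tally(m, e1, labels, ranges)
  expect_true(all(tally[, "tp"] == 1L))
  expect_true(all(tally[, "fn"] == 2L))
  expect_true(all(tally[, "fp"] == 0L))
})

test_that("precision/recall/F1 use the standard formulas with NA on zero denominators", {
  tally <- matrix(c(3L, 1L, 2L), nrow = 1,
                  dimnames = list("ph", c("tp", "fp", "fn")))
  prf <- compute_prf(tally)
  expect_equal(prf$precision, 0.75)
  expect_equal(prf$recall, 0.6)
  expect_equal(prf$f1, 2 * 0.75 * 0.6 / 1.35)
  prf <- compute_prf(matrix(c(0L, 0L, 0L), nrow = 1,
                            dimnames = list("ph", c("tp", "fp", "fn"))))
  expect_true(is.na(prf$precision) && is.na(prf$recall) && is.na(prf$f1))
  prf <- compute_prf(matrix(c(5L, 0L, 0L), nrow = 1,
                            dimnames = list("ph", c("tp", "fp", "fn"))))
  expect_equal(c(prf$precision, prf$recall, prf$f1), c(1, 1, 1))
})

test_that("aggregation means scopes, excludes undefined metrics, and defines Average", {
  mk <- function(scope, f1s) {
    data.frame(scope = scope, field = llpsie:::TARGET_FIELDS,
               precision = f1s, recall = f1s, f1 = f1s,
               stringsAsFactors = FALSE)
  }
  # single scope: aggregates equal the scope row, SD 0
  agg <- aggregate_metrics(mk("s1", rep(0.8, 6)))
  expect_equal(agg$f1_mean, rep(0.8, 7))
  expect_equal(agg$f1_sd, rep(0, 7))
  # two scopes, per-field F1 1.0 and 0.5
  agg <- aggregate_metrics(rbind(mk("s1", rep(1, 6)), mk("s2", rep(0.5, 6))))
  expect_equal(agg$f1_mean, rep(0.75, 7))
  expect_equal(agg$f1_sd[7], stats::sd(c(1, 0.5)))
  # three scopes with one field undefined in one scope: hand-recomputed
  m <- rbind(mk("s1", c(NA, 1, 1, 1, 1, 1)),
             mk("s2", c(0.5, 1, 1, 1, 1, 1)),
             mk("s3", c(1, 0.5, 0.5, 0.5, 0.5, 0.5)))
  agg <- aggregate_metrics(m)
  expect_equal(agg$f1_mean[1], mean(c(0.5, 1)))       # NA excluded
  expect_equal(agg$f1_mean[2], mean(c(1, 1, 0.5)))
  per_field_means <- c(0.75, rep(5 / 6, 5))
  expect_equal(agg$f1_mean[7], mean(per_field_means))
  per_scope_avgs <- c(mean(rep(1, 5)), mean(c(0.5, rep(1, 5))),
                      mean(c(1, rep(0.5, 5))))
  expect_equal(agg$f1_sd[7], stats::sd(per_scope_avgs))
})

test_that("tally conservation holds on corrupted scenarios", {
  for (seed in c(5, 17)) {
    s <- make_scenario(seed, rate = 0.2, n_figures = 2)
    ev <- evaluate_extraction(s$extracted, s$labels)
    for (key in names(ev$scopes)) {
      sc <- ev$scopes[[key]]
      fig <- sub(".*::", "", key)
      E <- s$extracted[s$extracted$figure_id == fig, , drop = FALSE]
      L <- s$labels[s$labels$figure_id == fig, , drop = FALSE]
      present_e <- colSums(llpsie:::field_presence(E))
      expect_equal(unname(sc$tally[, "tp"] + sc$tally[, "fp"]),
                   unname(present_e))
      if (!is.null(sc$match)) {
        expect_identical(nrow(sc$match$pairs) +
                           length(sc$match$unmatched_labels), nrow(L))
        expect_identical(nrow(sc$match$pairs), min(nrow(E), nrow(L)))
      }
    }
  }
})

test_that("perfect extraction is a fixed point: all metrics 1, all costs 0", {
  s <- make_scenario(23, rate = 0, numeric_noise_sd = 0, n_figures = 3)
  ev <- evaluate_extraction(s$extracted, s$labels)
  for (sc in ev$scopes) {
    expect_equal(sc$match$total_cost, 0)
    expect_true(all(sc$metrics$f1 == 1, na.rm = TRUE))
  }
  m <- ev$metrics
  expect_true(all(m$precision[!is.na(m$precision)] == 1))
  expect_true(all(m$recall[!is.na(m$recall)] == 1))
  expect_equal(ev$aggregate$f1_mean[ev$aggregate$field == "Average"], 1)
})

test_that("per-field F1 is non-decreasing in the threshold", {
  s <- make_scenario(41, rate = 0.2, n_figures = 2)
  sw <- threshold_sweep(s$extracted, s$labels,
                        thresholds = c(0, 0.05, 0.1, 0.2, 0.5, 1))
  for (f in c(llpsie:::TARGET_FIELDS, "Average")) {
    v <- sw$f1_mean[sw$field == f]
    v <- v[!is.na(v)]
    expect_true(all(diff(v) >= -1e-12), info = f)
  }
  # at threshold 1.0 every matched pair is TP in every present field
  by_t <- attr(sw, "by_threshold")
  m1 <- by_t[["1"]]
  ev1 <- evaluate_extraction(s$extracted, s$labels, threshold = 1)
  for (key in names(ev1$scopes)) {
    sc <- ev1$scopes[[key]]
    if (is.null(sc$match)) next
    pe <- llpsie:::field_presence(
      s$extracted[s$extracted$figure_id == sub(".*::", "", key), ,
                  drop = FALSE])
    matched_present <- colSums(pe[sc$match$pairs$extracted, , drop = FALSE])
    expect_equal(unname(sc$tally[, "tp"]), unname(matched_present))
  }
  expect_error(threshold_sweep(s$extracted, s$labels, c(0.5, 0.2)),
               class = "llps_validation_error")
})

test_that("wilcoxon comparison: degenerate, shifted and symmetric cases", {
  a <- seq(0.1, 1, by = 0.1)
  expect_warning(r <- compare_methods_wilcoxon(a, a), "zero")
  expect_equal(r$p_value, 1)
  expect_false(r$significant)

  # +0.1 shift over 10 scopes: exact enumeration gives 2/2^10
  r <- compare_methods_wilcoxon(a + 0.1, a)
  expect_equal(r$statistic, 55)
  expect_equal(r$p_value, 2 / 1024)
  expect_true(r$significant)
  # antisymmetric: swapping the methods gives the same p
  r2 <- compare_methods_wilcoxon(a, a + 0.1)
  expect_equal(r2$p_value, r$p_value)

  # brute-force sign-flip enumeration oracle on a small mixed case
  d <- c(0.12, -0.05, 0.3, 0.07, -0.2, 0.15, 0.02)
  rks <- rank(abs(d))
  Vobs <- sum(rks[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), length(d)))
  Vnull <- as.matrix(signs) %*% rks
  p_oracle <- min(1, 2 * min(mean(Vnull <= Vobs), mean(Vnull >= Vobs)))
  r <- compare_methods_wilcoxon(d + 1, rep(1, length(d)))
  expect_equal(r$statistic, Vobs)
  expect_equal(r$p_value, p_oracle)
})
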