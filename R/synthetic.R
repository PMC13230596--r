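# Synthetic benchmark scenarios: label sets with LLPS-like structure
# (per-figure concentration grids with a monotone phase boundary, one
# buffer pH and temperature per figure) and controllably corrupted
# "extracted" counterparts whose expected TP/FP/FN tallies are tracked
# during generation. Every downstream stage — parsing, normalization,
# matching, scoring — is thereby testable offline against exact
# expectations.
#
# The expected tallies assume the optimal assignment recovers the true
# record correspondence. The generator enforces that by construction:
# each surviving corrupted record must undercut its cost to every other
# label, and every spurious record's (constant) cost row, by a
# separation margin; figures violating the margin are redrawn and
# counted in the manifest. Spurious records carry only the three fields
# name/protein-conc/RNA-conc, with values engineered to clamp at
# distance 1 and a name far from the figure's protein, so their cost to
# every label is identical and no optimal-assignment tie can change the
# tallies.

#' Generator configuration
#'
#' Defaults describe the benchmark structure the package targets: 49
#' figures grouped three per paper, contiguous log-spaced concentration
#' sub-grids of 3-6 protein by 3-5 RNA levels (mean 18 experiments per
#' figure, ~880 in total), one buffer pH and one temperature per figure
#' (temperature may be alias-coded, e.g. `"RT"`), and phase separation
#' above the median concentration product.
#'
#' @param n_figures Number of figures.
#' @param experiments_per_figure Length-2 range of experiments per
#'   figure.
#' @param protein_pool Protein display names, cycled over figures.
#' @param conc_grid List with `protein` and `rna` concentration grids
#'   (micromolar, ascending).
#' @param ph_values Candidate buffer pH values.
#' @param temperature_values Candidate temperatures as raw strings
#'   (aliases allowed).
#' @param phase_cutoff Concentration-product cutoff for phase = 1;
#'   `NULL` (default) uses each figure's median product so both
#'   outcomes occur.
#' @param figures_per_paper Figures grouped into one paper id.
#' @param seed Mandatory integer seed.
#' @return A `generator_config` object.
#' @export
generator_config <- function(
    n_figures = 49,
    experiments_per_figure = c(3, 40),
    protein_pool = c("FUS", "G3BP1", "PGL-3", "LAF-1", "DDX4", "TDP-43",
                     "NPM1", "hnRNPA1"),
    conc_grid = list(protein = c(0.1, 0.2, 0.5, 1, 2, 5, 10, 20),
                     rna = c(0.01, 0.02, 0.05, 0.1, 0.2, 0.5, 1, 2)),
    ph_values = c(6.5, 7, 7.4, 8),
    temperature_values = c("25", "37", "RT", "4", "22"),
    phase_cutoff = NULL,
    figures_per_paper = 3,
    seed) {
  if (missing(seed)) llps_config_error("generator seed is mandatory")
  if (length(conc_grid$protein) == 0 || length(conc_grid$rna) == 0) {
    llps_config_error("concentration grids must be non-empty")
  }
  structure(list(n_figures = n_figures,
                 experiments_per_figure = experiments_per_figure,
                 protein_pool = protein_pool, conc_grid = conc_grid,
                 ph_values = ph_values,
                 temperature_values = as.character(temperature_values),
                 phase_cutoff = phase_cutoff,
                 figures_per_paper = figures_per_paper, seed = seed),
            class = "generator_config")
}

safe_sample <- function(x, n = 1) x[sample.int(length(x), n)]

#' Generate synthetic label record sets
#'
#' Each figure's records form a protein x RNA concentration grid
#' (contiguous sub-ranges of the configured grids) with deterministic
#' phase labels from the cutoff rule; all six target fields are present
#' in every label record. Figure metadata (display name, raw
#' temperature string, cutoff) is attached as attribute
#' `"figure_meta"`.
#'
#' @param cfg A [generator_config].
#' @return A label [record_set].
#' @export
generate_labels <- function(cfg) {
  with_seed(cfg$seed, {
    rows <- list()
    meta <- list()
    rules <- default_rules()
    lo <- cfg$experiments_per_figure[1]
    hi <- cfg$experiments_per_figure[2]
    combos <- expand.grid(np = 3:6, nr = 3:5)
    combos <- combos[combos$np * combos$nr >= lo &
                       combos$np * combos$nr <= hi &
                       combos$np <= length(cfg$conc_grid$protein) &
                       combos$nr <= length(cfg$conc_grid$rna), ]
    if (nrow(combos) == 0) {
      llps_config_error(
        "no feasible grid size inside experiments_per_figure bounds")
    }
    for (i in seq_len(cfg$n_figures)) {
      fig <- sprintf("fig%02d", i)
      paper <- sprintf("paper%02d", ceiling(i / cfg$figures_per_paper))
      display <- cfg$protein_pool[(i - 1) %% length(cfg$protein_pool) + 1]
      name <- canonicalize_protein_name(display, rules)
      ci <- combos[sample.int(nrow(combos), 1), ]
      gp <- cfg$conc_grid$protein
      gr <- cfg$conc_grid$rna
      sp <- sample.int(length(gp) - ci$np + 1, 1)
      sr <- sample.int(length(gr) - ci$nr + 1, 1)
      pvals <- gp[sp:(sp + ci$np - 1)]
      rvals <- gr[sr:(sr + ci$nr - 1)]
      ph <- safe_sample(cfg$ph_values)
      temp_raw <- safe_sample(cfg$temperature_values)
      temp_c <- normalize_temperature(temp_raw, rules)$value
      grid <- expand.grid(rna = rvals, protein = pvals)
      grid <- grid[order(grid$protein, grid$rna), ]
      products <- grid$protein * grid$rna
      cutoff <- cfg$phase_cutoff %||% stats::median(products)
      phase <- as.integer(products > cutoff)
      if (length(unique(phase)) < 2) {
        warning(sprintf(
          "figure %s: concentration grid does not straddle the phase cutoff",
          fig))
      }
      rows[[fig]] <- data.frame(
        paper_id = paper, figure_id = fig,
        protein_name = name,
        protein_conc_um = grid$protein, rna_conc_um = grid$rna,
        ph = ph, temperature_c = temp_c, phase_status = phase,
        stringsAsFactors = FALSE)
      meta[[fig]] <- data.frame(
        figure_id = fig, paper_id = paper, display_name = display,
        name = name, ph = ph, temp_raw = temp_raw, temp_c = temp_c,
        cutoff = cutoff, n = nrow(grid), stringsAsFactors = FALSE)
    }
    labels <- record_set(do.call(rbind, rows), origin = "label")
    attr(labels, "figure_meta") <- do.call(rbind, meta)
    rownames(attr(labels, "figure_meta")) <- NULL
    labels
  })
}

#' Corruption configuration
#'
#' @param numeric_noise_sd Gaussian noise SD on the concentration
#'   fields, as a fraction of the figure's label range (applied on the
#'   canonical micromolar scale before any unit jitter); default 0.01,
#'   emulating small coordinate-readout jitter. pH and temperature come
#'   from text in practice and are left exact.
#' @param miss_field_rate Probability each field of a surviving record
#'   is dropped.
#' @param drop_record_rate Probability a label record is omitted.
#' @param spurious_record_rate Expected spurious records per figure
#'   (Poisson).
#' @param typo_rate Probability of a single-character substitution in
#'   the protein name.
#' @param unit_jitter_rate Probability a micromolar value is
#'   re-expressed in mM/nM in the raw (pre-normalization) form.
#' @param seed Mandatory integer seed.
#' @return A `corruption_config` object.
#' @export
corruption_config <- function(numeric_noise_sd = 0.01,
                              miss_field_rate = 0, drop_record_rate = 0,
                              spurious_record_rate = 0, typo_rate = 0,
                              unit_jitter_rate = 0, seed) {
  if (missing(seed)) llps_config_error("corruption seed is mandatory")
  rates <- c(miss_field_rate, drop_record_rate, spurious_record_rate,
             typo_rate, unit_jitter_rate)
  if (any(rates < 0 | rates > 1) || numeric_noise_sd < 0) {
    llps_config_error("rates must be in [0, 1] and noise sd >= 0")
  }
  structure(list(numeric_noise_sd = numeric_noise_sd,
                 miss_field_rate = miss_field_rate,
                 drop_record_rate = drop_record_rate,
                 spurious_record_rate = spurious_record_rate,
                 typo_rate = typo_rate,
                 unit_jitter_rate = unit_jitter_rate, seed = seed),
            class = "corruption_config")
}

TYPO_ALPHABET <- c("q", "x", "z", "j")

#' Corrupt a label set into a scenario with known expected tallies
#'
#' Applies record drops, field omissions, concentration noise, name
#' typos, unit jitter and spurious insertions, replaying the evaluator's
#' distance and threshold rules on the known true correspondence to
#' compute the exact expected per-figure TP/FP/FN tallies. Extracted
#' rows are shuffled within each figure, so recovering the
#' correspondence genuinely requires the assignment step.
#'
#' @param labels A label [record_set] from [generate_labels()].
#' @param ccfg A [corruption_config].
#' @param threshold Distance threshold the tallies are stated at.
#' @param margin Separation margin enforced between the costliest
#'   survivor-to-true-label pairing and the cheapest spurious-row cost
#'   (default 0.005). Survivor-vs-label separation itself only requires
#'   strict row-minimality of the true pairing; exact ties are accepted
#'   when tie-equivalent (identical per-field distances).
#' @param max_attempts Redraws allowed per figure before giving up.
#' @return An `llps_scenario`: `labels`, `extracted`, `expected_tallies`
#'   (per-figure `field_tally` matrices), `threshold`, `manifest`.
#' @export
corrupt <- function(labels, ccfg, threshold = 0.2, margin = 0.005,
                    max_attempts = 100) {
  meta <- attr(labels, "figure_meta")
  fig_ids <- unique(labels$figure_id)
  with_seed(ccfg$seed, {
    ex_rows <- list()
    raw_rows <- list()
    tallies <- list()
    attempts_log <- integer(0)
    for (fig in fig_ids) {
      L <- labels[labels$figure_id == fig, , drop = FALSE]
      fm <- meta[meta$figure_id == fig, ]
      ranges <- field_ranges(L)
      res <- NULL
      for (attempt in seq_len(max_attempts)) {
        cand <- draw_figure_corruption(L, fm, ranges, ccfg)
        if (corruption_margin_ok(cand, L, ranges, margin)) {
          res <- cand
          attempts_log[fig] <- attempt
          break
        }
      }
      if (is.null(res)) {
        llps_error("llps_generation_error", sprintf(
          "figure %s: no margin-respecting corruption in %d attempts",
          fig, max_attempts))
      }
      tallies[[fig]] <- figure_expected_tally(res, L, ranges, threshold)
      perm <- sample.int(nrow(res$extracted))
      ex_rows[[fig]] <- res$extracted[perm, , drop = FALSE]
      raw_rows[[fig]] <- res$raw[perm]
    }
    extracted <- record_set(do.call(rbind, ex_rows), origin = "extracted")
    structure(list(
      labels = labels, extracted = extracted,
      expected_tallies = tallies, threshold = threshold,
      manifest = list(corruption = unclass(ccfg), threshold = threshold,
                      margin = margin, attempts = as.list(attempts_log),
                      n_regenerated = sum(attempts_log - 1L)),
      raw_script = raw_rows
    ), class = "llps_scenario")
  })
}

# One corruption draw for one figure. Returns extracted rows (survivors
# in label order, then spurious), their raw pre-normalization forms for
# the mock script, the survivor -> label index map, and counts.
draw_figure_corruption <- function(L, fm, ranges, ccfg) {
  n <- nrow(L)
  dropped <- stats::runif(n) < ccfg$drop_record_rate
  rows <- list(); raw <- list(); truth <- integer(0)
  for (j in seq_len(n)) {
    if (dropped[j]) next
    miss <- stats::runif(length(TARGET_FIELDS)) < ccfg$miss_field_rate
    names(miss) <- TARGET_FIELDS
    if (all(miss)) { dropped[j] <- TRUE; next }  # empty record = omission
    e <- L[j, , drop = FALSE]
    r <- list()
    # protein name: typo then (conceptually) canonicalization, which
    # folds unknown names — so the stored name is the folded typo form
    if (miss["protein_name"]) e$protein_name <- NA_character_
    else {
      nm <- e$protein_name
      if (stats::runif(1) < ccfg$typo_rate && nchar(nm) > 0) {
        pos <- sample.int(nchar(nm), 1)
        ch <- safe_sample(setdiff(TYPO_ALPHABET, substr(nm, pos, pos)))
        substr(nm, pos, pos) <- ch
      }
      e$protein_name <- nm
      r$protein_name <- if (nm == L$protein_name[j]) fm$display_name else nm
    }
    for (f in c("protein_conc", "rna_conc")) {
      col <- paste0(f, "_um")
      if (miss[f]) { e[[col]] <- NA_real_; next }
      v <- e[[col]]
      span <- ranges[[f]][["uM"]][2] - ranges[[f]][["uM"]][1]
      if (ccfg$numeric_noise_sd > 0 && span > 0) {
        v <- max(v + stats::rnorm(1, 0, ccfg$numeric_noise_sd * span), 0)
        e[[col]] <- v
      }
      r[[f]] <- conc_raw_form(v, ccfg$unit_jitter_rate)
    }
    if (miss["ph"]) e$ph <- NA_real_
    else r$ph <- paste("pH", fmt_num(e$ph))
    if (miss["temperature"]) e$temperature_c <- NA_real_
    else r$temperature <- fm$temp_raw
    if (miss["phase_status"]) e$phase_status <- NA_integer_
    else r$phase_status <- if (e$phase_status == 1) "droplets" else "soluble"
    rows[[length(rows) + 1L]] <- e
    raw[[length(raw) + 1L]] <- r
    truth <- c(truth, j)
  }
  n_spurious <- stats::rpois(1, ccfg$spurious_record_rate)
  for (k in seq_len(n_spurious)) {
    sp <- spurious_record(L, fm, ranges)
    rows[[length(rows) + 1L]] <- sp$row
    raw[[length(raw) + 1L]] <- sp$raw
  }
  extracted <- if (length(rows) > 0) do.call(rbind, rows) else
    L[integer(0), , drop = FALSE]
  list(extracted = extracted, raw = raw, truth = truth,
       n_dropped = sum(dropped), n_spurious = n_spurious,
       n_survivors = length(truth))
}

# raw pre-normalization string for a micromolar value; only jitter into
# mM/nM when the factor round-trips exactly in double arithmetic
conc_raw_form <- function(v, jitter_rate) {
  if (stats::runif(1) < jitter_rate) {
    unit <- safe_sample(c("mM", "nM"))
    if (unit == "mM" && (v / 1000) * 1000 == v) {
      return(paste(fmt_num(v / 1000), "mM"))
    }
    if (unit == "nM" && (v * 1000) * 1e-3 == v) {
      return(paste(fmt_num(v * 1000), "nM"))
    }
  }
  paste(fmt_num(v), "uM")
}

# A spurious record: name far from the figure's protein, concentrations
# beyond the label range (distance clamps to 1), ph/temperature/phase
# missing — so its cost row is constant across all labels and none of
# its fields can score a true positive.
spurious_record <- function(L, fm, ranges) {
  repeat {
    nm <- paste(safe_sample(letters, 7), collapse = "")
    if (text_field_distance(nm, fm$name) >= 0.5) break
  }
  row <- L[1, , drop = FALSE]
  row$protein_name <- nm
  for (f in c("protein_conc", "rna_conc")) {
    rg <- ranges[[f]][["uM"]]
    span <- rg[2] - rg[1]
    if (!is.finite(span) || span == 0) span <- max(rg[2], 1)
    row[[paste0(f, "_um")]] <- rg[2] + span * (1 + stats::runif(1))
  }
  row$ph <- NA_real_
  row$temperature_c <- NA_real_
  row$phase_status <- NA_integer_
  raw <- list(protein_name = nm,
              protein_conc = paste(fmt_num(row$protein_conc_um), "uM"),
              rna_conc = paste(fmt_num(row$rna_conc_um), "uM"))
  list(row = row, raw = raw)
}

# Separation conditions making the tallies invariant across all optimal
# assignments. (a) Each survivor's cost to its true label is a strict
# minimum of its row: any deviation then strictly increases the total,
# so the true correspondence is optimal; labels tying the minimum (to
# numerical precision) are allowed only when tie-EQUIVALENT — identical
# per-field distance vector, e.g. grid rows that differ only in a field
# the record lost — in which case any optimal assignment produces the
# same tallies. (b) Every survivor undercuts every spurious row's
# constant cost by `margin`, so no optimum ever swaps a survivor out
# for a spurious record.
corruption_margin_ok <- function(cand, L, ranges, margin) {
  ns <- cand$n_survivors
  if (nrow(cand$extracted) == 0 || nrow(L) == 0) return(TRUE)
  C <- build_cost_matrix(cand$extracted, L, ranges)
  fd <- attr(C, "field_distances")
  eps <- 1e-9
  if (ns > 0) {
    for (s in seq_len(ns)) {
      t <- cand$truth[s]
      c_true <- C[s, t]
      for (j in seq_len(ncol(C))) {
        if (j == t) next
        if (C[s, j] < c_true - eps) return(FALSE)
        if (C[s, j] < c_true + eps) {
          dt <- fd[s, t, ]; dj <- fd[s, j, ]
          same <- (is.na(dt) & is.na(dj)) |
            (!is.na(dt) & !is.na(dj) & abs(dt - dj) < eps)
          if (!all(same)) return(FALSE)
        }
      }
    }
    if (cand$n_spurious > 0) {
      c_true_max <- max(C[cbind(seq_len(ns), cand$truth)])
      c_spur_min <- min(C[(ns + 1):nrow(C), , drop = FALSE])
      if (c_true_max + margin > c_spur_min) return(FALSE)
    }
  }
  TRUE
}

# Exact expected tallies under the evaluator's rules, assuming the
# margin-enforced correspondence: survivors classify per field against
# their true labels; spurious fields are false positives; unmatched
# labels (drops exceeding spurious insertions) are false negatives in
# every present field.
figure_expected_tally <- function(cand, L, ranges, threshold) {
  tally <- matrix(0L, nrow = length(TARGET_FIELDS), ncol = 3,
                  dimnames = list(TARGET_FIELDS, c("tp", "fp", "fn")))
  ns <- cand$n_survivors
  for (s in seq_len(ns)) {
    e <- cand$extracted[s, , drop = FALSE]
    l <- L[cand$truth[s], , drop = FALSE]
    d <- record_field_distances(e, l, ranges)
    pres <- field_presence(e)[1, ]
    for (f in TARGET_FIELDS) {
      if (!pres[f]) next
      if (d[[f]] < threshold) tally[f, "tp"] <- tally[f, "tp"] + 1L
      else tally[f, "fp"] <- tally[f, "fp"] + 1L
    }
  }
  if (cand$n_spurious > 0) {
    for (f in c("protein_name", "protein_conc", "rna_conc")) {
      tally[f, "fp"] <- tally[f, "fp"] + cand$n_spurious
    }
  }
  n_unmatched_labels <- max(cand$n_dropped - cand$n_spurious, 0L)
  if (n_unmatched_labels > 0) {
    tally[, "fn"] <- tally[, "fn"] + n_unmatched_labels
  }
  structure(tally, class = c("field_tally", "matrix"))
}

#' Mock-backend script for a scenario
#'
#' Per-figure JSON response texts (raw, pre-normalization forms: jittered
#' units, temperature aliases, phase vocabulary, display-case names)
#' that reproduce the scenario's extracted set exactly once run through
#' [parse_model_output()] and [normalize_records()].
#'
#' @param s An `llps_scenario`.
#' @return Named list figure id -> JSON text.
#' @export
scenario_as_mock_script <- function(s) {
  out <- list()
  for (fig in names(s$raw_script)) {
    recs <- s$raw_script[[fig]]
    out[[fig]] <- as.character(jsonlite::toJSON(
      recs, auto_unbox = TRUE, pretty = TRUE))
  }
  out
}

#' Oracle-mode mock backend for a scenario
#'
#' @param s An `llps_scenario`.
#' @return A counting backend replaying the scenario's mock script.
#' @export
scenario_backend <- function(s) {
  mock_backend(scenario_as_mock_script(s))
}

#' Paper bundles for a scenario
#'
#' One [paper_bundle] per scenario paper, with a figure directive per
#' figure and synthetic placeholder image paths (the mock backends never
#' open them).
#'
#' @param s An `llps_scenario`.
#' @return Named list of [paper_bundle]s.
#' @export
scenario_bundles <- function(s) {
  meta <- attr(s$labels, "figure_meta")
  out <- list()
  for (paper in unique(meta$paper_id)) {
    fm <- meta[meta$paper_id == paper, ]
    figures <- lapply(seq_len(nrow(fm)), function(i) {
      list(directive = figure_directive(fm$figure_id[i]),
           image = sprintf("synthetic://%s.png", fm$figure_id[i]))
    })
    out[[paper]] <- paper_bundle(
      paper, figures,
      caption_method_text = sprintf(
        "Synthetic caption and methods text for %s.", paper),
      full_text = sprintf("Synthetic full text for %s.", paper),
      pdf = sprintf("synthetic://%s.pdf", paper))
  }
  out
}

#' @export
print.llps_scenario <- function(x, ...) {
  cat(sprintf(
    "<llps_scenario> %d figure(s), %d label / %d extracted record(s), threshold %s\n",
    length(x$expected_tallies), nrow(x$labels), nrow(x$extracted),
    fmt_num(x$threshold)))
  invisible(x)
}
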