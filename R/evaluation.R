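# Scoring extracted record sets against curated labels.
#
# Within each scope (figure for figure-by-figure extraction, paper for
# single-shot), extracted and label records are paired by minimum-cost
# assignment over the record-cost matrix. For each matched pair and each
# of the six target fields, the pair counts as a true positive when the
# per-field distance is below the threshold (default 0.2, chosen
# tolerant of curation noise), otherwise as a false positive. Extracted
# records left unmatched are false positives in every present field;
# unmatched labels are false negatives likewise. Precision, recall and
# F1 are computed per field and scope, then averaged across scopes, with
# the overall Average defined as the mean of the six per-field means.

#' Classify matched pairs and tally TP/FP/FN per field
#'
#' @param match A `match_result` from [solve_assignment()].
#' @param extracted,labels The scope's [record_set]s (row order as used
#'   to build the cost matrix).
#' @param ranges [field_ranges] computed from `labels`.
#' @param threshold Per-field distance cutoff in \[0, 1\]; default 0.2.
#' @param comparison `"lt"` (strict below, the default) or `"le"` for
#'   sensitivity checks.
#' @param strict_recall If `TRUE`, a matched label field that was not
#'   recovered (distance at/above threshold, or present in the label but
#'   missing from the extraction) additionally counts as a false
#'   negative. Off by default: plain matched-pair misses count only
#'   against precision.
#' @param field_distances Optional precomputed E x L x field distance
#'   array (the `"field_distances"` attribute of [build_cost_matrix()]);
#'   recomputed from the records when absent.
#' @return Integer matrix fields x (tp, fp, fn), class `field_tally`.
#' @export
classify_and_tally <- function(match, extracted, labels, ranges,
                               threshold = 0.2,
                               comparison = c("lt", "le"),
                               strict_recall = FALSE,
                               field_distances = NULL) {
  comparison <- match.arg(comparison)
  if (threshold < 0 || threshold > 1) {
    llps_validation_error("threshold must be in [0, 1]")
  }
  below <- if (comparison == "lt") function(d) d < threshold
           else function(d) d <= threshold
  tally <- matrix(0L, nrow = length(TARGET_FIELDS), ncol = 3,
                  dimnames = list(TARGET_FIELDS, c("tp", "fp", "fn")))
  pe <- if (nrow(extracted) > 0) field_presence(extracted) else NULL
  pl <- if (nrow(labels) > 0) field_presence(labels) else NULL

  if (!is.null(match) && nrow(match$pairs) > 0) {
    ii <- match$pairs$extracted; jj <- match$pairs$label
    if (is.null(field_distances)) {
      pd <- t(vapply(seq_along(ii), function(k) {
        record_field_distances(extracted[ii[k], , drop = FALSE],
                               labels[jj[k], , drop = FALSE], ranges)
      }, numeric(length(TARGET_FIELDS))))
    } else {
      pd <- sapply(seq_along(TARGET_FIELDS), function(k) {
        field_distances[cbind(ii, jj, k)]
      })
      if (length(ii) == 1L) pd <- matrix(pd, nrow = 1)
    }
    colnames(pd) <- TARGET_FIELDS
    for (f in TARGET_FIELDS) {
      e_has <- pe[ii, f]; l_has <- pl[jj, f]
      d <- pd[, f]
      hit <- e_has & below(d)
      hit[is.na(hit)] <- FALSE
      miss <- e_has & !hit
      tally[f, "tp"] <- tally[f, "tp"] + sum(hit)
      tally[f, "fp"] <- tally[f, "fp"] + sum(miss)
      if (strict_recall) {
        tally[f, "fn"] <- tally[f, "fn"] +
          sum(miss & l_has) + sum(!e_has & l_has)
      }
    }
  }
  unmatched_e <- if (is.null(match)) seq_len(nrow(extracted)) else match$unmatched_extracted
  unmatched_l <- if (is.null(match)) seq_len(nrow(labels)) else match$unmatched_labels
  if (length(unmatched_e) > 0) {
    tally[, "fp"] <- tally[, "fp"] +
      as.integer(colSums(pe[unmatched_e, , drop = FALSE]))
  }
  if (length(unmatched_l) > 0) {
    tally[, "fn"] <- tally[, "fn"] +
      as.integer(colSums(pl[unmatched_l, , drop = FALSE]))
  }
  structure(tally, class = c("field_tally", "matrix"))
}

#' Precision / recall / F1 from a field tally
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`. Zero
#' denominators leave the metric undefined (`NA`); undefined metrics are
#' excluded from aggregation rather than imputed as 0.
#'
#' @param tally A `field_tally` matrix.
#' @return data.frame: field, tp, fp, fn, precision, recall, f1.
#' @export
compute_prf <- function(tally) {
  tp <- tally[, "tp"]; fp <- tally[, "fp"]; fn <- tally[, "fn"]
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  f1 <- ifelse(!is.na(precision) & !is.na(recall) & precision + recall > 0,
               2 * precision * recall / (precision + recall), NA_real_)
  f1[!is.na(precision) & !is.na(recall) & precision + recall == 0] <- NA_real_
  data.frame(field = rownames(tally), tp = unname(tp), fp = unname(fp),
             fn = unname(fn), precision = unname(precision),
             recall = unname(recall), f1 = unname(f1),
             stringsAsFactors = FALSE)
}

#' Aggregate per-scope metrics
#'
#' Per-field mean and standard deviation of precision, recall and F1
#' across scopes (undefined values excluded), plus an `Average` row: its
#' mean is the mean of the six per-field means, its SD the standard
#' deviation across scopes of the per-scope average.
#'
#' @param metrics Long data.frame with columns scope, field, precision,
#'   recall, f1 (one row per scope x field).
#' @return data.frame: field (six fields then `"Average"`), then
#'   `<metric>_mean` / `<metric>_sd` columns and `n_scopes`.
#' @export
aggregate_metrics <- function(metrics) {
  mets <- c("precision", "recall", "f1")
  out <- data.frame(field = c(TARGET_FIELDS, "Average"),
                    stringsAsFactors = FALSE)
  scopes <- unique(metrics$scope)
  for (m in mets) {
    field_means <- sapply(TARGET_FIELDS, function(f) {
      v <- metrics[[m]][metrics$field == f]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    })
    field_sds <- sapply(TARGET_FIELDS, function(f) {
      v <- metrics[[m]][metrics$field == f]
      v <- v[!is.na(v)]
      if (length(v) < 2) 0 else stats::sd(v)
    })
    per_scope_avg <- sapply(scopes, function(s) {
      v <- metrics[[m]][metrics$scope == s]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    })
    avg_mean <- mean(field_means, na.rm = TRUE)
    psa <- per_scope_avg[!is.na(per_scope_avg)]
    avg_sd <- if (length(psa) < 2) 0 else stats::sd(psa)
    out[[paste0(m, "_mean")]] <- c(unname(field_means), avg_mean)
    out[[paste0(m, "_sd")]] <- c(unname(field_sds), avg_sd)
  }
  out$n_scopes <- length(scopes)
  out
}

# Prepare per-scope evaluation contexts: subsets, ranges and the
# (threshold-independent) assignment.
prepare_scopes <- function(extracted, labels, scope = c("figure", "paper")) {
  scope <- match.arg(scope)
  lk <- scope_key(labels, scope)
  ek <- scope_key(extracted, scope)
  keys <- unique(c(lk, ek[!ek %in% lk]))
  lapply(stats::setNames(keys, keys), function(s) {
    eL <- labels[lk == s, , drop = FALSE]
    eE <- extracted[ek == s, , drop = FALSE]
    ranges <- if (nrow(eL) > 0) field_ranges(eL) else NULL
    fd <- NULL
    match <- if (nrow(eE) > 0 && nrow(eL) > 0) {
      C <- build_cost_matrix(eE, eL, ranges)
      fd <- attr(C, "field_distances")
      solve_assignment(C)
    } else NULL
    list(key = s, extracted = eE, labels = eL, ranges = ranges,
         match = match, field_distances = fd)
  })
}

#' Evaluate extracted records against labels
#'
#' The full scoring pipeline: split by scope, match by minimum-cost
#' assignment, classify at the distance threshold, and aggregate
#' per-field precision/recall/F1 across scopes. Scopes present in the
#' labels but absent from the extraction are scored against an empty
#' extraction (all false negatives); the reverse yields all false
#' positives.
#'
#' @param extracted,labels [record_set]s.
#' @param threshold Distance threshold, default 0.2.
#' @param scope `"figure"` (default; per-figure matching as used for
#'   figure-by-figure extraction) or `"paper"` (single-shot).
#' @param strict_recall,comparison Passed to [classify_and_tally()].
#' @return An `llps_eval` object; see [print.llps_eval()].
#' @export
evaluate_extraction <- function(extracted, labels, threshold = 0.2,
                                scope = c("figure", "paper"),
                                strict_recall = FALSE,
                                comparison = c("lt", "le")) {
  scope <- match.arg(scope)
  comparison <- match.arg(comparison)
  validate_record_set(extracted)
  validate_record_set(labels)
  ctxs <- prepare_scopes(extracted, labels, scope)
  scopes <- list()
  rows <- list()
  for (s in names(ctxs)) {
    ctx <- ctxs[[s]]
    if (nrow(ctx$extracted) == 0 && nrow(ctx$labels) == 0) next
    tally <- classify_and_tally(ctx$match, ctx$extracted, ctx$labels,
                                ctx$ranges, threshold = threshold,
                                comparison = comparison,
                                strict_recall = strict_recall,
                                field_distances = ctx$field_distances)
    prf <- compute_prf(tally)
    scopes[[s]] <- list(match = ctx$match, tally = tally, metrics = prf,
                        n_extracted = nrow(ctx$extracted),
                        n_labels = nrow(ctx$labels))
    prf$scope <- s
    rows[[s]] <- prf
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  metrics <- metrics[, c("scope", setdiff(names(metrics), "scope"))]
  structure(list(
    scope = scope, threshold = threshold, comparison = comparison,
    strict_recall = strict_recall,
    scopes = scopes, metrics = metrics,
    aggregate = aggregate_metrics(metrics)
  ), class = "llps_eval")
}

#' @export
print.llps_eval <- function(x, digits = 3, ...) {
  cat(sprintf(
    "<llps_eval> %d %s scope(s), threshold %s (%s)%s\n",
    length(x$scopes), x$scope, fmt_num(x$threshold),
    if (x$comparison == "lt") "strict below" else "at or below",
    if (x$strict_recall) ", strict recall" else ""))
  agg <- x$aggregate
  show <- data.frame(
    field = agg$field,
    precision = round(agg$precision_mean, digits),
    recall = round(agg$recall_mean, digits),
    f1 = round(agg$f1_mean, digits),
    f1_sd = round(agg$f1_sd, digits))
  print.data.frame(show, row.names = FALSE)
  invisible(x)
}

#' @export
summary.llps_eval <- function(object, ...) {
  print(object)
  cat("\nPer-scope average F1:\n")
  print(round(per_scope_average(object), 3))
  invisible(object)
}

#' Per-scope average F1
#'
#' For each scope, the mean of its defined per-field F1 values — the
#' unit of the across-method significance comparison.
#'
#' @param eval An `llps_eval` object.
#' @param metric `"f1"`, `"precision"` or `"recall"`.
#' @return Named numeric vector, one entry per scope.
#' @export
per_scope_average <- function(eval, metric = "f1") {
  m <- eval$metrics
  sapply(split(m[[metric]], m$scope)[unique(m$scope)], function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
}

#' Evaluate over a ladder of thresholds
#'
#' The assignment is threshold-independent, so records are matched once
#' per scope and re-classified at each threshold.
#'
#' @param extracted,labels [record_set]s.
#' @param thresholds Ascending numeric vector of thresholds.
#' @param scope,strict_recall,comparison As in [evaluate_extraction()].
#' @return data.frame of aggregate rows per threshold (class
#'   `llps_sweep`), with the per-threshold `llps_eval`-style metrics in
#'   attribute `"by_threshold"`.
#' @export
threshold_sweep <- function(extracted, labels,
                            thresholds = c(0, 0.05, 0.1, 0.2, 0.5, 1.0),
                            scope = c("figure", "paper"),
                            strict_recall = FALSE,
                            comparison = c("lt", "le")) {
  scope <- match.arg(scope)
  comparison <- match.arg(comparison)
  if (is.unsorted(thresholds)) {
    llps_validation_error("thresholds must be sorted ascending")
  }
  ctxs <- prepare_scopes(extracted, labels, scope)
  by_threshold <- list()
  agg_rows <- list()
  for (tau in thresholds) {
    rows <- list()
    for (s in names(ctxs)) {
      ctx <- ctxs[[s]]
      if (nrow(ctx$extracted) == 0 && nrow(ctx$labels) == 0) next
      tally <- classify_and_tally(ctx$match, ctx$extracted, ctx$labels,
                                  ctx$ranges, threshold = tau,
                                  comparison = comparison,
                                  strict_recall = strict_recall,
                                  field_distances = ctx$field_distances)
      prf <- compute_prf(tally)
      prf$scope <- s
      rows[[s]] <- prf
    }
    metrics <- do.call(rbind, rows)
    rownames(metrics) <- NULL
    agg <- aggregate_metrics(metrics)
    agg$threshold <- tau
    key <- fmt_num(tau)
    by_threshold[[key]] <- metrics
    agg_rows[[key]] <- agg
  }
  out <- do.call(rbind, agg_rows)
  rownames(out) <- NULL
  out <- out[, c("threshold", setdiff(names(out), "threshold"))]
  attr(out, "by_threshold") <- by_threshold
  class(out) <- c("llps_sweep", "data.frame")
  out
}

#' Paired Wilcoxon signed-rank comparison of two methods
#'
#' Compares two methods' per-scope average scores over the same scopes.
#' Zero differences are dropped (the Wilcoxon convention); the two-sided
#' p-value comes from the exact tie-aware sign-flip distribution of the
#' signed-rank statistic (enumerated by convolution over midranks), so
#' tied differences are handled exactly.
#'
#' @param a,b Equal-length numeric vectors of per-scope scores, paired
#'   by position.
#' @param alpha Significance level for the flag (default 0.05).
#' @return List: `statistic` (V, sum of positive-difference ranks),
#'   `p_value`, `significant`, `n`, `n_nonzero`.
#' @export
compare_methods_wilcoxon <- function(a, b, alpha = 0.05) {
  if (length(a) != length(b)) {
    llps_validation_error("paired score vectors must have equal length")
  }
  d <- a - b
  d <- d[!is.na(d)]
  nz <- d[d != 0]
  if (length(nz) == 0) {
    warning("all paired differences are zero; p = 1")
    return(list(statistic = 0, p_value = 1, significant = FALSE,
                n = length(d), n_nonzero = 0L))
  }
  if (length(nz) < 5) {
    warning("fewer than 5 non-zero differences; the test has little power")
  }
  r <- rank(abs(nz))
  V <- sum(r[nz > 0])
  p <- signed_rank_exact_p(r, V)
  list(statistic = V, p_value = p, significant = p < alpha,
       n = length(d), n_nonzero = length(nz))
}

# Exact two-sided p for the signed-rank statistic by convolution over
# the (doubled, hence integer) midranks: each rank contributes 0 or r_i
# with probability 1/2 under the null.
signed_rank_exact_p <- function(r, V) {
  r2 <- as.integer(round(2 * r))
  tot <- sum(r2)
  f <- numeric(tot + 1L)   # f[v + 1] = #sign vectors with statistic v
  f[1] <- 1
  for (ri in r2) {
    shifted <- c(numeric(ri), f[seq_len(tot + 1L - ri)])
    f <- f + shifted
  }
  total <- 2^length(r)
  v2 <- as.integer(round(2 * V))
  p_le <- sum(f[seq_len(v2 + 1L)]) / total
  p_ge <- sum(f[(v2 + 1L):(tot + 1L)]) / total
  min(1, 2 * min(p_le, p_ge))
}
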