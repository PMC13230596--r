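# Per-field distances between an extracted and a label record, and the
# cost matrix built from them.
#
# Numeric conditions (protein/RNA concentration, pH, temperature) use
# |x_pred - x_true| / (x_max - x_min), with the range taken from the
# label data of the evaluated scope only, clamped to [0, 1]. A degenerate
# range (x_max == x_min) preserves exact-match semantics: 0 if equal,
# else 1. Text (protein name) uses 1 - s with s the Ratcliff-Obershelp
# gestalt similarity (2M / (|a| + |b|), M the total length of matching
# blocks found recursively around longest common substrings). Phase
# status is the 0/1 mismatch indicator. The record cost is the mean of
# the six per-field distances, with missing<->missing contributing 0 and
# missing<->present contributing 1.

#' Field ranges from label data
#'
#' Computes, per numeric field, the min/max of the label values inside
#' the evaluated scope — the denominators of the normalized numeric
#' distance. Convertible (micromolar) and non-convertible concentration
#' values get separate per-unit ranges, since cross-unit numeric
#' comparison is meaningless.
#'
#' @param labels A [record_set] restricted to one scope.
#' @return A named list of ranges, class `field_ranges`.
#' @export
field_ranges <- function(labels) {
  rng <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) c(NA_real_, NA_real_) else range(v)
  }
  out <- list(ph = rng(labels$ph), temperature = rng(labels$temperature_c))
  for (f in c("protein_conc", "rna_conc")) {
    val <- labels[[paste0(f, "_um")]]
    unit <- labels[[paste0(f, "_unit")]]
    per_unit <- list(uM = rng(val[is.na(unit)]))
    for (u in unique(unit[!is.na(unit)])) {
      per_unit[[u]] <- rng(val[!is.na(unit) & unit == u])
    }
    out[[f]] <- per_unit
  }
  structure(out, class = "field_ranges")
}

#' Normalized numeric field distance
#'
#' `|x_pred - x_true| / (x_max - x_min)` with the label-data range of the
#' evaluated scope, clamped to \[0, 1\]. Degenerate range: 0 when the
#' values agree exactly, else 1.
#'
#' @param x_pred,x_true Extracted and label values (comparable scales).
#' @param range Numeric length-2 `c(x_min, x_max)`.
#' @return Distance in \[0, 1\].
#' @export
numeric_field_distance <- function(x_pred, x_true, range) {
  span <- range[2] - range[1]
  if (is.na(span) || span == 0) {
    return(if (isTRUE(x_pred == x_true)) 0 else 1)
  }
  min(abs(x_pred - x_true) / span, 1)
}

#' Gestalt (Ratcliff-Obershelp) text distance
#'
#' `1 - s` where `s = 2M / (|a| + |b|)` and `M` is the total length of
#' matching blocks: the longest common substring, then recursion on the
#' pieces to its left and right. Ties for the longest block are broken
#' towards the earliest position in `a`, then in `b` (the convention of
#' the standard sequence-matcher implementations). `s = 1` for an exact
#' match; two empty strings are an exact match.
#'
#' @param a,b Strings.
#' @return Distance in \[0, 1\].
#' @export
text_field_distance <- function(a, b) {
  1 - gestalt_ratio(a, b)
}

gestalt_ratio <- function(a, b) {
  la <- nchar(a); lb <- nchar(b)
  if (la + lb == 0L) return(1)
  if (la == 0L || lb == 0L) return(0)
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  m <- gestalt_match_len(av, bv, 1L, la, 1L, lb)
  2 * m / (la + lb)
}

gestalt_match_len <- function(av, bv, alo, ahi, blo, bhi) {
  if (alo > ahi || blo > bhi) return(0L)
  lm <- find_longest_match(av, bv, alo, ahi, blo, bhi)
  if (lm[3] == 0L) return(0L)
  lm[3] +
    gestalt_match_len(av, bv, alo, lm[1] - 1L, blo, lm[2] - 1L) +
    gestalt_match_len(av, bv, lm[1] + lm[3], ahi, lm[2] + lm[3], bhi)
}

find_longest_match <- function(av, bv, alo, ahi, blo, bhi) {
  besti <- alo; bestj <- blo; bestsize <- 0L
  j2len <- integer(length(bv))
  for (i in alo:ahi) {
    newj2len <- integer(length(bv))
    js <- which(bv == av[i])
    js <- js[js >= blo & js <= bhi]
    for (j in js) {
      k <- if (j > blo) j2len[j - 1L] + 1L else 1L
      newj2len[j] <- k
      if (k > bestsize) {
        besti <- i - k + 1L; bestj <- j - k + 1L; bestsize <- k
      }
    }
    j2len <- newj2len
  }
  c(besti, bestj, bestsize)
}

#' Phase-status distance
#'
#' 0 for matching binary outcomes, 1 for a mismatch.
#'
#' @param a,b Binary (0/1) phase states.
#' @return 0 or 1.
#' @export
phase_field_distance <- function(a, b) {
  as.numeric(a != b)
}

# Distance vector over the six target fields for one record pair.
# NA encodes "both missing" (contributes 0 to the cost, nothing to the
# tallies); missing<->present is 1.
record_field_distances <- function(e, l, ranges) {
  d <- stats::setNames(rep(NA_real_, length(TARGET_FIELDS)), TARGET_FIELDS)

  pair <- function(ev, lv) c(!is.na(ev), !is.na(lv))

  # protein name
  p <- pair(e$protein_name, l$protein_name)
  if (xor(p[1], p[2])) d["protein_name"] <- 1
  else if (all(p)) d["protein_name"] <- text_field_distance(e$protein_name,
                                                            l$protein_name)
  # concentrations: numeric only when units agree after folding
  for (f in c("protein_conc", "rna_conc")) {
    ev <- e[[paste0(f, "_um")]]; lv <- l[[paste0(f, "_um")]]
    eu <- e[[paste0(f, "_unit")]]; lu <- l[[paste0(f, "_unit")]]
    p <- pair(ev, lv)
    if (xor(p[1], p[2])) d[f] <- 1
    else if (all(p)) {
      same_unit <- (is.na(eu) && is.na(lu)) ||
        (!is.na(eu) && !is.na(lu) && eu == lu)
      if (!same_unit) d[f] <- 1
      else {
        key <- if (is.na(lu)) "uM" else lu
        rg <- ranges[[f]][[key]] %||% c(NA_real_, NA_real_)
        d[f] <- numeric_field_distance(ev, lv, rg)
      }
    }
  }
  p <- pair(e$ph, l$ph)
  if (xor(p[1], p[2])) d["ph"] <- 1
  else if (all(p)) d["ph"] <- numeric_field_distance(e$ph, l$ph, ranges$ph)

  p <- pair(e$temperature_c, l$temperature_c)
  if (xor(p[1], p[2])) d["temperature"] <- 1
  else if (all(p)) d["temperature"] <- numeric_field_distance(
    e$temperature_c, l$temperature_c, ranges$temperature)

  p <- pair(e$phase_status, l$phase_status)
  if (xor(p[1], p[2])) d["phase_status"] <- 1
  else if (all(p)) d["phase_status"] <- phase_field_distance(e$phase_status,
                                                             l$phase_status)
  d
}

#' Record cost
#'
#' Mean of the six per-field distances between an extracted and a label
#' record; both-missing fields contribute 0, missing-vs-present
#' contributes 1, so the cost always averages exactly six unit-interval
#' terms and lies in \[0, 1\].
#'
#' @param e,l Single-row record data (extracted, label).
#' @param ranges A [field_ranges] object for the scope.
#' @return Cost in \[0, 1\].
#' @export
record_cost <- function(e, l, ranges) {
  d <- record_field_distances(e, l, ranges)
  mean(ifelse(is.na(d), 0, d))
}

#' Build the cost matrix
#'
#' Rows are extracted records, columns are label records; entry (i, j) is
#' `record_cost(extracted[i], labels[j])`. The per-field distance array
#' is attached as attribute `"field_distances"` (E x L x 6).
#'
#' @param extracted,labels [record_set]s restricted to one scope, both
#'   non-empty.
#' @param ranges Optional precomputed [field_ranges] (from `labels`).
#' @return Numeric matrix with attribute `"field_distances"`.
#' @export
build_cost_matrix <- function(extracted, labels, ranges = NULL) {
  nE <- nrow(extracted); nL <- nrow(labels)
  if (nE == 0 || nL == 0) {
    llps_validation_error(
      "cost matrix needs non-empty extracted and label sets; route empty sides to FP/FN directly")
  }
  if (is.null(ranges)) ranges <- field_ranges(labels)
  fd <- array(NA_real_, dim = c(nE, nL, length(TARGET_FIELDS)),
              dimnames = list(NULL, NULL, TARGET_FIELDS))

  fd[, , "protein_name"] <- text_distance_matrix(extracted$protein_name,
                                                 labels$protein_name)
  for (f in c("protein_conc", "rna_conc")) {
    fd[, , f] <- conc_distance_matrix(
      extracted[[paste0(f, "_um")]], labels[[paste0(f, "_um")]],
      extracted[[paste0(f, "_unit")]], labels[[paste0(f, "_unit")]],
      ranges[[f]])
  }
  fd[, , "ph"] <- numeric_distance_matrix(extracted$ph, labels$ph,
                                          ranges$ph)
  fd[, , "temperature"] <- numeric_distance_matrix(
    extracted$temperature_c, labels$temperature_c, ranges$temperature)
  fd[, , "phase_status"] <- phase_distance_matrix(extracted$phase_status,
                                                  labels$phase_status)

  total <- matrix(0, nE, nL)
  for (k in seq_along(TARGET_FIELDS)) {
    slice <- fd[, , k]
    slice[is.na(slice)] <- 0
    total <- total + slice
  }
  C <- total / length(TARGET_FIELDS)
  attr(C, "field_distances") <- fd
  C
}

# E x L distance matrices per field. NA encodes both-missing;
# missing-vs-present is 1.
missingness_mask <- function(M, pe, pl) {
  M[outer(pe, pl, function(a, b) xor(a, b))] <- 1
  M[outer(!pe, !pl, "&")] <- NA_real_
  M
}

text_distance_matrix <- function(en, ln) {
  nE <- length(en); nL <- length(ln)
  M <- matrix(NA_real_, nE, nL)
  pe <- !is.na(en); pl <- !is.na(ln)
  if (any(pe) && any(pl)) {
    ue <- unique(en[pe]); ul <- unique(ln[pl])
    cache <- outer(ue, ul,
                   Vectorize(function(a, b) text_field_distance(a, b)))
    ei <- match(en, ue); li <- match(ln, ul)
    idx <- cbind(rep(ei, times = nL), rep(li, each = nE))
    full <- matrix(cache[idx], nE, nL)
    both <- outer(pe, pl, "&")
    M[both] <- full[both]
  }
  missingness_mask(M, pe, pl)
}

numeric_distance_matrix <- function(ev, lv, rg) {
  nE <- length(ev); nL <- length(lv)
  M <- matrix(NA_real_, nE, nL)
  pe <- !is.na(ev); pl <- !is.na(lv)
  both <- outer(pe, pl, "&")
  if (any(both)) {
    span <- rg[2] - rg[1]
    diffs <- outer(ev, lv, "-")
    full <- if (!is.na(span) && span > 0) {
      pmin(abs(diffs) / span, 1)
    } else {
      ifelse(diffs == 0, 0, 1)
    }
    M[both] <- full[both]
  }
  missingness_mask(M, pe, pl)
}

conc_distance_matrix <- function(ev, lv, eu, lu, unit_ranges) {
  nE <- length(ev); nL <- length(lv)
  M <- matrix(NA_real_, nE, nL)
  pe <- !is.na(ev); pl <- !is.na(lv)
  both <- outer(pe, pl, "&")
  if (any(both)) {
    euk <- ifelse(is.na(eu), "uM", eu)
    luk <- ifelse(is.na(lu), "uM", lu)
    same_unit <- outer(euk, luk, "==")
    M[both & !same_unit] <- 1
    diffs <- outer(ev, lv, "-")
    for (u in unique(luk[pl])) {
      sel <- both & same_unit & matrix(rep(luk == u, each = nE), nE, nL)
      if (!any(sel)) next
      rg <- unit_ranges[[u]] %||% c(NA_real_, NA_real_)
      span <- rg[2] - rg[1]
      full <- if (!is.na(span) && span > 0) {
        pmin(abs(diffs) / span, 1)
      } else {
        ifelse(diffs == 0, 0, 1)
      }
      M[sel] <- full[sel]
    }
  }
  missingness_mask(M, pe, pl)
}

phase_distance_matrix <- function(ep, lp) {
  M <- matrix(NA_real_, length(ep), length(lp))
  pe <- !is.na(ep); pl <- !is.na(lp)
  both <- outer(pe, pl, "&")
  if (any(both)) {
    full <- 1 * outer(ep, lp, "!=")
    M[both] <- full[both]
  }
  missingness_mask(M, pe, pl)
}
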