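# Minimum-cost one-to-one matching between extracted and label records
# (the assignment problem), solved with the Hungarian method in its
# O(n^3) potentials / shortest-augmenting-path form. Rectangular
# matrices are solved directly: min(|E|, |L|) pairs are produced and the
# leftover side is reported unmatched. The algorithm is fully
# deterministic: rows are augmented in index order and equal-cost
# alternatives resolve to the lowest column index scanned first.

#' Solve the assignment problem on a cost matrix
#'
#' @param C Numeric cost matrix (rows: extracted, columns: labels), all
#'   entries finite. May be rectangular.
#' @return A `match_result`: `pairs` (data.frame `extracted`, `label`,
#'   `cost`, ordered by extracted index), `unmatched_extracted`,
#'   `unmatched_labels`, `total_cost`.
#' @export
solve_assignment <- function(C) {
  if (!is.matrix(C)) C <- as.matrix(C)
  if (any(!is.finite(C))) {
    llps_validation_error("cost matrix entries must be finite")
  }
  nE <- nrow(C); nL <- ncol(C)
  if (nE == 0 || nL == 0) {
    return(match_result(integer(0), integer(0), numeric(0), nE, nL))
  }
  if (nE <= nL) {
    assign_cols <- hungarian_rect(C)
    rows <- seq_len(nE); cols <- assign_cols
  } else {
    assign_cols <- hungarian_rect(t(C))
    cols <- seq_len(nL); rows <- assign_cols
    o <- order(rows)
    rows <- rows[o]; cols <- cols[o]
  }
  costs <- C[cbind(rows, cols)]
  match_result(rows, cols, costs, nE, nL)
}

match_result <- function(rows, cols, costs, nE, nL) {
  structure(list(
    pairs = data.frame(extracted = rows, label = cols, cost = costs),
    unmatched_extracted = setdiff(seq_len(nE), rows),
    unmatched_labels = setdiff(seq_len(nL), cols),
    total_cost = sum(costs)
  ), class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d pair(s), total cost %.4f\n",
              nrow(x$pairs), x$total_cost))
  if (length(x$unmatched_extracted) > 0)
    cat(" unmatched extracted:", x$unmatched_extracted, "\n")
  if (length(x$unmatched_labels) > 0)
    cat(" unmatched labels:", x$unmatched_labels, "\n")
  invisible(x)
}

# Hungarian algorithm with row/column potentials for n rows <= m columns.
# Returns, for each row, its assigned column. Classic shortest
# augmenting path formulation; a virtual column m+1 seeds each phase.
hungarian_rect <- function(C) {
  n <- nrow(C); m <- ncol(C)
  stopifnot(n <= m)
  INF <- .Machine$double.xmax / 4
  u <- numeric(n)          # row potentials
  v <- numeric(m + 1L)     # column potentials (m+1 is the virtual column)
  p <- integer(m + 1L)     # p[j]: row currently assigned to column j (0 = none)
  way <- integer(m + 1L)   # predecessor column on the alternating path

  for (i in seq_len(n)) {
    p[m + 1L] <- i
    j0 <- m + 1L
    minv <- rep(INF, m)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      free <- which(!used[seq_len(m)])
      cur <- C[i0, free] - u[i0] - v[free]
      upd <- cur < minv[free]
      if (any(upd)) {
        idx <- free[upd]
        minv[idx] <- cur[upd]
        way[idx] <- j0
      }
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      usedj <- which(used)
      for (j in usedj) {
        if (p[j] > 0L) u[p[j]] <- u[p[j]] + delta
        v[j] <- v[j] - delta
      }
      minv[!used[seq_len(m)]] <- minv[!used[seq_len(m)]] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == m + 1L) break
    }
  }
  assign_cols <- integer(n)
  for (j in seq_len(m)) if (p[j] > 0L) assign_cols[p[j]] <- j
  assign_cols
}
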