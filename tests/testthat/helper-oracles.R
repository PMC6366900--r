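# Independent brute-force oracles used to cross-check the implementation.

# All-pairs local-maxima oracle: p is a maximum iff strictly greater than
# every other pixel within Euclidean distance <= radius, and above the image
# minimum; equal-valued candidates within the radius collapse to the
# lexicographically smallest.
oracle_local_maxima <- function(image, radius) {
  h <- nrow(image); w <- ncol(image)
  out <- list()
  for (r in 1:h) for (c in 1:w) {
    v <- image[r, c]
    if (v <= min(image)) next
    ok <- TRUE
    for (r2 in max(1, r - ceiling(radius)):min(h, r + ceiling(radius))) {
      for (c2 in max(1, c - ceiling(radius)):min(w, c + ceiling(radius))) {
        if (r2 == r && c2 == c) next
        if ((r2 - r)^2 + (c2 - c)^2 > radius^2) next
        if (image[r2, c2] > v ||
            (image[r2, c2] == v && (r2 < r || (r2 == r && c2 < c)))) {
          ok <- FALSE; break
        }
      }
      if (!ok) break
    }
    if (ok) out[[length(out) + 1L]] <- c(r, c)
  }
  if (!length(out)) return(matrix(integer(0), 0, 2))
  m <- do.call(rbind, out)
  v <- image[m]
  m[order(-v, m[, 1], m[, 2]), , drop = FALSE]
}

# Naive local-maxima + greedy NMS oracle for seed finding.
oracle_find_seeds <- function(acc, min_votes, nms_radius) {
  h <- nrow(acc); w <- ncol(acc)
  cand <- list()
  for (r in 1:h) for (c in 1:w) {
    if (acc[r, c] < min_votes) next
    ok <- TRUE
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > h || c2 < 1 || c2 > w) next
      if (acc[r2, c2] > acc[r, c]) ok <- FALSE
    }
    if (ok) cand[[length(cand) + 1L]] <- c(r, c, acc[r, c])
  }
  if (!length(cand)) return(matrix(integer(0), 0, 2))
  m <- do.call(rbind, cand)
  m <- m[order(-m[, 3], m[, 1], m[, 2]), , drop = FALSE]
  kept <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(m))) {
    if (nrow(kept) == 0 ||
        all((kept[, 1] - m[i, 1])^2 + (kept[, 2] - m[i, 2])^2 > nms_radius^2))
      kept <- rbind(kept, m[i, 1:2])
  }
  unname(kept)
}

# Full-sort top-k-median oracle via order().
oracle_top_k_median <- function(x, k) {
  top <- x[order(x, decreasing = TRUE)][seq_len(k)]
  if (k %% 2 == 1) sort(top)[(k + 1) / 2]
  else mean(sort(top)[c(k / 2, k / 2 + 1)])
}

# Exhaustive optimal one-to-one matching (max cardinality, then min total
# distance) for small instances: recursion over channel-a foci.
oracle_match <- function(pa, pb, d_max) {
  na <- nrow(pa); nb <- nrow(pb)
  d <- sqrt(outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2)
  best <- list(n = -1, cost = Inf, pairs = NULL)
  rec <- function(i, used_b, pairs, cost) {
    if (i > na) {
      n <- nrow(pairs)
      if (n > best$n || (n == best$n && cost < best$cost))
        best <<- list(n = n, cost = cost, pairs = pairs)
      return(invisible())
    }
    rec(i + 1, used_b, pairs, cost)           # leave i unmatched
    for (j in seq_len(nb)) {
      if (used_b[j] || d[i, j] > d_max) next
      u <- used_b; u[j] <- TRUE
      rec(i + 1, u, rbind(pairs, c(i, j)), cost + d[i, j])
    }
  }
  rec(1, logical(nb), matrix(integer(0), 0, 2), 0)
  best
}

# Recall/precision of detected foci against planted positions.
match_truth <- function(detected, truth, tol_px = 2) {
  if (nrow(detected) == 0)
    return(list(recall = 0, precision = NA_real_))
  d <- sqrt(outer(detected$centroid_row, truth$row, "-")^2 +
              outer(detected$centroid_col, truth$col, "-")^2)
  list(recall = sum(apply(d, 2, min) <= tol_px) / nrow(truth),
       precision = sum(apply(d, 1, min) <= tol_px) / nrow(detected))
}

# Paint a sharp disc (interior/background step) for edge and voting tests.
disc_image <- function(h, w, row, col, radius, interior = 200, bg = 50) {
  img <- matrix(bg, h, w)
  for (r in 1:h) {
    cc <- which((r - row)^2 + (seq_len(w) - col)^2 < radius^2)
    img[r, cc] <- interior
  }
  img
}
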