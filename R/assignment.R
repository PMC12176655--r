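#' @name assignment
#' @title Optimal one-to-one point matching
#'
#' @description
#' The linking engine shared by frame-to-frame tracking and live-to-endpoint
#' registration. Candidate pairs are gated by a maximum distance; within the
#' gate the matching maximises the number of matched pairs and, among
#' maximum-cardinality matchings, minimises the total Euclidean displacement.
#' The solver is an exact shortest-augmenting-path (Jonker-Volgenant style)
#' assignment on a square cost matrix padded with per-point "leave unmatched"
#' slots, run independently on each connected component of the gated
#' candidate graph, so results are deterministic and order-independent.
NULL

BIG_COST <- 1e12

# exact square linear sum assignment (shortest augmenting path with
# potentials); returns, for each column, the assigned row
lsap_square <- function(cost) {
  n <- nrow(cost)
  stopifnot(n == ncol(cost))
  u <- numeric(n + 1L)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)          # p[j+1] = row assigned to column j (0 none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L                    # virtual column
    minv <- rep(Inf, n + 1L)
    used <- logical(n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free <- which(!used[-1L])         # real columns not yet in the tree
      red <- cost[i0, free] - u[i0 + 0L] - v[free + 1L]
      upd <- red < minv[free + 1L]
      if (any(upd)) {
        idx <- free[upd]
        minv[idx + 1L] <- red[upd]
        way[idx + 1L] <- j0
      }
      jrel <- which.min(minv[free + 1L])
      j1 <- free[jrel]
      delta <- minv[j1 + 1L]
      usedj <- which(used)
      rows <- p[usedj]
      u[rows[rows > 0L]] <- u[rows[rows > 0L]] + delta
      # virtual column potential bookkeeping folds into u[i] via rows==i
      v[usedj] <- v[usedj] - delta
      notused <- which(!used)
      minv[notused] <- minv[notused] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  p[-1L]
}

# union-find over the gated candidate graph
uf_components <- function(n_a, n_b, pairs) {
  parent <- seq_len(n_a + n_b)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs$i[k])
      rb <- find(n_a + pairs$j[k])
      if (ra != rb) parent[rb] <- ra
    }
  }
  vapply(seq_len(n_a + n_b), find, integer(1))
}

# maximum-cardinality, minimum-total-cost one-to-one matching on a cost
# matrix where entries > gate (or non-finite) are disallowed; solved exactly
# per connected component of the allowed-pair graph
gated_assignment <- function(d, gate) {
  n_a <- nrow(d)
  n_b <- ncol(d)
  empty <- data.frame(i = integer(), j = integer(), dist = numeric())
  if (n_a == 0L || n_b == 0L)
    return(list(matches = empty, unmatched_a = seq_len(n_a),
                unmatched_b = seq_len(n_b), total_cost = 0))
  allowed <- is.finite(d) & d <= gate
  cand <- which(allowed, arr.ind = TRUE)
  pairs <- data.frame(i = cand[, 1], j = cand[, 2])
  comp <- uf_components(n_a, n_b, pairs)
  pen <- gate + 1
  matches <- empty
  for (cc in unique(comp)) {
    ia <- which(comp[seq_len(n_a)] == cc)
    ib <- which(comp[n_a + seq_len(n_b)] == cc)
    if (!length(ia) || !length(ib)) next
    na <- length(ia)
    nb <- length(ib)
    cost <- matrix(BIG_COST, na + nb, na + nb)
    sub <- d[ia, ib, drop = FALSE]
    sub[!(is.finite(sub) & sub <= gate)] <- BIG_COST
    cost[seq_len(na), seq_len(nb)] <- sub
    cost[cbind(seq_len(na), nb + seq_len(na))] <- pen
    cost[cbind(na + seq_len(nb), seq_len(nb))] <- pen
    cost[na + seq_len(nb), nb + seq_len(na)] <- 0
    p <- lsap_square(cost)      # p[j] = row assigned to column j
    for (j in seq_len(nb)) {
      r <- p[j]
      if (r <= na && sub[r, j] <= gate)
        matches <- rbind(matches,
                         data.frame(i = ia[r], j = ib[j], dist = sub[r, j]))
    }
  }
  matches <- matches[order(matches$i), , drop = FALSE]
  rownames(matches) <- NULL
  list(matches = matches,
       unmatched_a = setdiff(seq_len(n_a), matches$i),
       unmatched_b = setdiff(seq_len(n_b), matches$j),
       total_cost = sum(matches$dist))
}

#' Optimal gated matching between two point sets
#'
#' @param a,b numeric matrices (or data frames) with columns x, y.
#' @param max_dist gate: pairs farther apart than this are never matched.
#' @returns list with `matches` (data frame `i`, `j`, `dist`, indices into
#'   `a` and `b`), `unmatched_a`, `unmatched_b`, and `total_cost` (sum of
#'   matched distances).
#' @export
match_points <- function(a, b, max_dist) {
  a <- as.matrix(a)[, 1:2, drop = FALSE]
  b <- as.matrix(b)[, 1:2, drop = FALSE]
  check_positive(max_dist, "max_dist")
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(gated_assignment(matrix(numeric(), nrow(a), nrow(b)), max_dist))
  d <- sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2)
  gated_assignment(d, max_dist)
}
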