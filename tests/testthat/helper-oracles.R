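# Independent reference implementations used as oracles.

# all permutations of 1..n as a matrix (rows = permutations)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- NULL
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  out
}

# exhaustive min-cost perfect matching on a square cost matrix
brute_min_cost <- function(cost) {
  n <- nrow(cost)
  pm <- all_perms(n)
  costs <- apply(pm, 1, function(p) sum(cost[cbind(seq_len(n), p)]))
  min(costs)
}

# exhaustive gated matching: maximise matches, then minimise total distance;
# recursion over rows of a (row i matched to an allowed free column or left
# unmatched)
brute_gated <- function(d, gate) {
  n_a <- nrow(d); n_b <- ncol(d)
  best <- list(n = -1L, cost = Inf)
  rec <- function(i, used, n, cost) {
    if (i > n_a) {
      if (n > best$n || (n == best$n && cost < best$cost))
        best <<- list(n = n, cost = cost)
      return(invisible())
    }
    for (j in seq_len(n_b)) {
      if (!used[j] && d[i, j] <= gate) {
        used[j] <- TRUE
        rec(i + 1L, used, n + 1L, cost + d[i, j])
        used[j] <- FALSE
      }
    }
    rec(i + 1L, used, n, cost)
  }
  rec(1L, logical(n_b), 0L, 0)
  best
}

# independent phase-calling reference: explicit scan over all runs
oracle_phases <- function(foci, g1_max = 4, s_min = 10, p = 2) {
  n <- length(foci)
  high <- foci >= s_min
  low <- foci <= g1_max
  run_start <- function(v) {
    vapply(seq_len(n), function(i)
      i + p - 1L <= n && all(v[i:(i + p - 1L)]), logical(1))
  }
  hs <- run_start(high)
  ls <- run_start(low)
  s_ent <- integer(0); g2_ent <- integer(0)
  pos <- 1L
  repeat {
    cand <- which(hs)[which(hs) >= pos]
    if (!length(cand)) break
    s <- cand[1]
    s_ent <- c(s_ent, s)
    cand2 <- which(ls)[which(ls) >= s + 1L]
    if (!length(cand2)) break
    g <- cand2[1]
    g2_ent <- c(g2_ent, g)
    pos <- g
  }
  lab <- character(n)
  for (i in seq_len(n)) {
    k <- sum(s_ent <= i)           # S periods entered at or before i
    m <- sum(g2_ent <= i)          # S periods exited at or before i
    if (k == 0) lab[i] <- if (low[i]) "G1" else "transition"
    else if (k > m) lab[i] <- if (high[i]) "S" else "transition"
    else {
      more_s <- length(s_ent) > k
      lab[i] <- if (low[i]) (if (more_s) "G1" else "G2") else "transition"
    }
  }
  lab
}

# OLS by normal equations
oracle_ols_residuals <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  as.numeric(y - X %*% beta)
}

# categorical heterogeneity oracle: literal threshold chains
oracle_category <- function(d, low_max, med_max) {
  if (d <= low_max) return("low")
  if (d <= med_max) return("medium")
  "high"
}
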