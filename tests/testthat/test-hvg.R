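test_that("normalization follows the closed form and its identities", {
  m <- matrix(c(1, 3, 6), nrow = 3,
              dimnames = list(paste0("g", 1:3), "c1"))
  nr <- normalize_counts(m)
  expect_equal(nr$normalized[1, 1], log(1 + 10000 * 1 / 10),
               tolerance = 1e-12)
  # zero count with pseudocount 1 maps to log(1) = 0
  m2 <- matrix(c(0, 10), nrow = 2)
  expect_equal(normalize_counts(m2)$normalized[1, 1], 0)
  # per cell, sum over genes of (e^value - 1) equals the scale factor
  set.seed(91)
  m3 <- matrix(rpois(600, 5), nrow = 30)
  nr3 <- normalize_counts(m3)
  sums <- colSums(exp(nr3$normalized) - 1)
  expect_equal(unname(sums), rep(10000, ncol(m3)), tolerance = 1e-8)
  # scaling one cell's counts by an integer k changes nothing
  m4 <- m3
  m4[, 3] <- m4[, 3] * 7L
  expect_equal(normalize_counts(m4)$normalized[, 3], nr3$normalized[, 3],
               tolerance = 1e-12)
  # zero-total cells are excluded and reported; negatives are an error
  m5 <- cbind(m3, 0)
  expect_equal(ncol(normalize_counts(m5)$normalized), ncol(m3))
  expect_length(normalize_counts(m5)$dropped_cells, 1)
  expect_error(normalize_counts(matrix(c(-1, 2), 2)), "negative")
})

test_that("two evaluable genes give an exact fit with zero residuals", {
  set.seed(92)
  m <- matrix(rpois(80, c(2, 20)), nrow = 2,
              dimnames = list(c("a", "b"), NULL))
  fit <- fit_residuals(normalize_counts(m)$normalized)
  expect_equal(fit$genes$residual, c(0, 0), tolerance = 1e-10)
  expect_equal(sum(fit$genes$hvg), 0)
})

test_that("a gene on the fitted line has residual zero", {
  # construct three genes whose (log2 mean, log2 sd) are collinear by
  # building values with prescribed means/sds
  mk_gene <- function(mu, sd, n = 400) {
    v <- scale(stats::rnorm(n))
    as.numeric(mu + sd * v)
  }
  set.seed(93)
  mat <- rbind(mk_gene(1, 0.1), mk_gene(2, 0.2), mk_gene(4, 0.4))
  rownames(mat) <- c("g1", "g2", "g3")
  fit <- fit_residuals(mat)
  expect_equal(max(abs(fit$genes$residual)), 0, tolerance = 1e-9)
})

test_that("residuals agree with the normal-equations oracle to 1e-10", {
  sim <- simulate_counts(count_sim_config(n_genes = 300, n_cells = 120,
                                          seed = 94))
  nr <- normalize_counts(sim$counts)
  fit <- fit_residuals(nr$normalized)
  ev <- fit$genes$evaluable
  ref <- oracle_ols_residuals(fit$genes$log2_mean[ev],
                              fit$genes$log2_sd[ev])
  expect_lt(max(abs(fit$genes$residual[ev] - ref)), 1e-10)
  # OLS residuals sum to ~0
  expect_lt(abs(sum(fit$genes$residual[ev])), 1e-8)
})

test_that("planted overdispersed genes are recovered at the 0.5 cutoff", {
  sim <- simulate_counts(count_sim_config(seed = 95))    # 2000 x 500, 100 planted
  nr <- normalize_counts(sim$counts)
  fit <- fit_residuals(nr$normalized)
  tt <- sim$truth
  recall <- mean(fit$genes$hvg[tt$planted_hvg])
  fpr <- mean(fit$genes$hvg[!tt$planted_hvg])
  expect_gte(recall, 0.9)
  expect_lte(fpr, 0.05)
})

test_that("HVG calls are invariant to gene order permutation", {
  sim <- simulate_counts(count_sim_config(n_genes = 200, n_cells = 100,
                                          seed = 96))
  nr <- normalize_counts(sim$counts)
  fit <- fit_residuals(nr$normalized)
  set.seed(97)
  perm <- sample(nrow(nr$normalized))
  fit2 <- fit_residuals(nr$normalized[perm, ])
  expect_equal(fit2$genes$hvg[order(perm)], fit$genes$hvg)
})

test_that("degenerate fits are rejected", {
  m <- matrix(5, 3, 10) + 0
  m[1, 1] <- 6; m[2, 1] <- 6; m[3, 1] <- 6
  # all genes identical -> zero spread in log2 mean
  expect_error(fit_residuals(matrix(rep(c(1, 2, 1, 2), 3), nrow = 3,
                                    byrow = TRUE)),
               "degenerate|evaluable")
})

test_that("enrichment test matches exhaustive enumeration and fisher.test", {
  # symmetric table: odds ratio 1, p 1
  er <- enrichment_test(rep(c(TRUE, FALSE), each = 20),
                        rep(c(TRUE, FALSE, TRUE, FALSE), each = 10))
  expect_equal(er$odds_ratio, 1)
  expect_equal(er$p_value, 1)
  # worked table [[8,2],[1,5]]: sample OR 20, p from enumeration
  flags <- c(rep(TRUE, 10), rep(FALSE, 6))
  inset <- c(rep(TRUE, 8), rep(FALSE, 2), TRUE, rep(FALSE, 5))
  er2 <- enrichment_test(flags, inset)
  expect_equal(er2$odds_ratio, 20)
  expect_equal(er2$p_value, stats::fisher.test(er2$table)$p.value,
               tolerance = 1e-12)
  # exhaustive: all 2x2 tables with total n <= 16
  for (n in 2:16) {
    for (a in 0:n) for (b in 0:(n - a)) for (cc in 0:(n - a - b)) {
      d <- n - a - b - cc
      tab <- matrix(c(a, cc, b, d), 2)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
      p_pkg <- enrichment_test(rep(c(TRUE, FALSE), c(a + b, cc + d)),
                               rep(c(TRUE, FALSE, TRUE, FALSE),
                                   c(a, b, cc, d)))$p_value
      p_ref <- stats::fisher.test(tab)$p.value
      expect_equal(p_pkg, p_ref, tolerance = 1e-9,
                   label = sprintf("table %d,%d,%d,%d", a, b, cc, d))
    }
  }
})

test_that("zero cells trigger the continuity-corrected Woolf interval", {
  er <- enrichment_test(c(rep(TRUE, 5), rep(FALSE, 10)),
                        c(rep(TRUE, 5), rep(FALSE, 10)))
  expect_true(er$continuity_corrected)
  expect_true(is.finite(er$odds_ratio))
  expect_true(all(is.finite(er$ci)))
  # empty margin: undefined odds ratio with a reason
  er2 <- enrichment_test(rep(FALSE, 10), rep(c(TRUE, FALSE), 5))
  expect_true(is.na(er2$odds_ratio))
  expect_match(er2$note, "margin")
})

test_that("null enrichment gives odds ratios centred on 1", {
  set.seed(98)
  ors <- replicate(20, {
    flags <- runif(400) < 0.2
    inset <- runif(400) < 0.25
    enrichment_test(flags, inset)$odds_ratio
  })
  expect_lt(abs(stats::median(log(ors))), 0.35)
})

test_that("without planting the caller's positive rate is near zero", {
  rates <- vapply(1:20, function(s) {
    sim <- simulate_counts(count_sim_config(n_genes = 400, n_cells = 150,
                                            n_hvg = 0, geneset_size = 0,
                                            geneset_hvg_overlap = 0,
                                            hvg_dispersion_factor = 1,
                                            seed = 700 + s))
    fit <- fit_residuals(normalize_counts(sim$counts)$normalized)
    mean(fit$genes$hvg[fit$genes$evaluable])
  }, numeric(1))
  # the strict 0.5-residual cutoff sits far in the null tail
  expect_lt(mean(rates), 0.02)
})

test_that("condition comparison recovers extra planted variability", {
  base <- count_sim_config(n_genes = 800, n_cells = 300, n_hvg = 40,
                           seed = 99)
  plus <- count_sim_config(n_genes = 800, n_cells = 300, n_hvg = 50,
                           seed = 99)
  fa <- fit_residuals(normalize_counts(simulate_counts(base)$counts)$normalized)
  fb <- fit_residuals(normalize_counts(simulate_counts(plus)$counts)$normalized)
  cmp <- compare_variability(fa, fb)
  expect_equal(cmp$n_a + length(cmp$only_b) - length(cmp$only_a), cmp$n_b)
  # identical inputs: nothing is condition-specific
  cmp0 <- compare_variability(fa, fa)
  expect_length(cmp0$only_b, 0)
  expect_equal(length(cmp0$overlap), cmp0$n_a)
  # mismatched universes are an error
  fb2 <- fb
  fb2$genes <- fb2$genes[-1, ]
  expect_error(compare_variability(fa, fb2), "universes")
})
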