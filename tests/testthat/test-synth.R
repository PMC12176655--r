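test_that("frame count follows duration and interval", {
  cfg <- sim_config(n_founders = 1, duration = 55, frame_interval = 30,
                    seed = 1)
  sim <- simulate_lineages(cfg)
  expect_equal(sim$truth$n_frames, 111L)        # floor(55*60/30)+1
  expect_equal(sort(unique(sim$obs$frame)), 0:110)
})

test_that("a single non-dividing founder yields one full-length track", {
  cfg <- sim_config(n_founders = 1, duration = 4.5, frame_interval = 30,
                    fate_probs = c(normal = 0, endoreplication = 0,
                                   rereplication = 0, arrest = 1),
                    seed = 2)
  sim <- simulate_lineages(cfg)
  expect_equal(nrow(sim$obs), 10L)              # 10 frames, one row each
  expect_equal(nrow(sim$truth$cells), 1L)
  expect_equal(nrow(sim$truth$edges), 0L)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_founders = 0), "n_founders")
  expect_error(sim_config(phase_cv = -1), "phase_cv")
  expect_error(sim_config(fate_probs = c(normal = 0.5, endoreplication = 0,
                                         rereplication = 0, arrest = 0)),
               "sum to 1")
  expect_error(sim_config(pcna_lambda = c(G1 = 1, S = 30)), "pcna_lambda")
})

test_that("inherited 53BP1 counts match the configured Poisson mean", {
  for (mean_bp1 in c(4, 0.5)) {
    cfg <- sim_config(n_founders = 60, duration = 55,
                      bp1_inherit_mean = mean_bp1, seed = round(mean_bp1 * 10))
    sim <- simulate_lineages(cfg)
    born <- sim$truth$cells[sim$truth$cells$born_by_division, ]
    expect_gt(nrow(born), 200)
    se <- sqrt(mean_bp1 / nrow(born))
    expect_lt(abs(mean(born$bp1_birth) - mean_bp1), 2 * se + 1e-9)
  }
})

test_that("daughters appear on the frame after the parent's last", {
  sim <- small_movie(seed = 3)
  cells <- sim$truth$cells
  for (k in seq_len(nrow(sim$truth$edges))) {
    p <- sim$truth$edges$parent[k]
    d <- sim$truth$edges$daughter[k]
    expect_equal(cells$birth_frame[cells$cell == d],
                 cells$end_frame[cells$cell == p] + 1L)
  }
})

test_that("population bookkeeping is conserved frame to frame", {
  sim <- small_movie(seed = 4, n_founders = 10, duration = 40)
  alive <- table(factor(sim$obs$frame, levels = 0:(sim$truth$n_frames - 1)))
  divs <- table(factor(sim$truth$divisions$frame,
                       levels = 0:(sim$truth$n_frames - 1)))
  # each division removes one parent and adds two daughters
  expect_equal(diff(as.integer(alive)),
               as.integer(divs)[-sim$truth$n_frames])
})

test_that("equal seeds give byte-identical tables", {
  cfg <- sim_config(n_founders = 4, duration = 20, seed = 7)
  expect_identical(simulate_lineages(cfg), simulate_lineages(cfg))
  ccfg <- count_sim_config(n_genes = 100, n_cells = 40, seed = 7)
  expect_identical(simulate_counts(ccfg), simulate_counts(ccfg))
})

test_that("PCNA foci rates are phase-dependent and straddle the thresholds", {
  sim <- small_movie(seed = 5, n_founders = 10, duration = 40)
  m <- merge(sim$truth$obs_map, sim$obs, by = c("frame", "label"))
  m <- merge(m, sim$truth$phases, by = c("cell", "frame"))
  expect_lt(mean(m$pcna_foci[m$phase == "G1"]), 2)
  expect_gt(mean(m$pcna_foci[m$phase == "S"]), 20)
  expect_lt(mean(m$pcna_foci[m$phase == "G2"]), 2)
})

test_that("53BP1 bodies are present in G1 and cleared at S entry", {
  sim <- small_movie(seed = 6, n_founders = 10, duration = 40,
                     bp1_inherit_mean = 3)
  m <- merge(sim$truth$obs_map, sim$obs, by = c("frame", "label"))
  m <- merge(m, sim$truth$phases, by = c("cell", "frame"))
  born <- sim$truth$cells$cell[sim$truth$cells$born_by_division]
  g1 <- m$phase == "G1" & m$cell %in% born
  expect_gt(mean(m$bp1_foci[g1]), 1)
  expect_equal(sum(m$bp1_foci[m$phase %in% c("S", "G2")]), 0)
})

test_that("DNA-content ledger: polyploid fates exceed 4N, normal never does", {
  fp <- c(normal = 0.4, endoreplication = 0.3, rereplication = 0.3,
          arrest = 0)
  cfg <- sim_config(n_founders = 30, duration = 55, fate_probs = fp,
                    field_size = c(3000, 3000), seed = 8)
  sim <- simulate_lineages(cfg)
  ph <- merge(sim$truth$phases, sim$truth$cells[, c("cell", "fate")],
              by = "cell")
  peak <- tapply(ph$dna, list(ph$cell, ph$fate), max)
  peak_fate <- tapply(ph$dna, ph$cell, max)
  fate_of <- sim$truth$cells$fate[match(names(peak_fate),
                                        sim$truth$cells$cell)]
  long_poly <- fate_of %in% c("endoreplication", "rereplication") &
    tapply(ph$frame, ph$cell, length) > 60   # lived long enough to double
  expect_true(all(peak_fate[long_poly] > 4))
  expect_true(all(peak_fate[fate_of == "normal"] <= 4 + 1e-9))
})

test_that("nuclear area grows within a cycle and halves at division", {
  sim <- small_movie(seed = 9)
  m <- merge(sim$truth$obs_map, sim$obs, by = c("frame", "label"))
  m <- m[order(m$cell, m$frame), ]
  # trend within cells: area at end > area at birth for dividing cells
  cells <- sim$truth$cells
  div_cells <- cells$cell[cells$end_type == "division"]
  for (cc in utils::head(div_cells, 10)) {
    a <- m$area[m$cell == cc]
    expect_gt(stats::cor(seq_along(a), a), 0.8)
  }
  for (k in utils::head(seq_len(nrow(sim$truth$edges)), 10)) {
    p <- sim$truth$edges$parent[k]
    d <- sim$truth$edges$daughter[k]
    ap <- m$area[m$cell == p]
    ad <- m$area[m$cell == d]
    expect_lt(ad[1] / ap[length(ap)], 0.62)
    expect_gt(ad[1] / ap[length(ap)], 0.38)
  }
})

test_that("hard-core exclusion keeps nuclei apart", {
  sim <- small_movie(seed = 10, n_founders = 12, duration = 45)
  min_d <- min(vapply(split(sim$obs, sim$obs$frame), function(d) {
    if (nrow(d) < 2) return(Inf)
    min(stats::dist(cbind(d$x, d$y)))
  }, numeric(1)))
  expect_gte(min_d, 39.5)   # relaxation converges to the 40 px target
})

test_that("endpoint panel reflects DNA content, damage and arrest", {
  cfg <- sim_config(n_founders = 20,
                    fate_probs = c(normal = 0, endoreplication = 0.5,
                                   rereplication = 0, arrest = 0.5),
                    duration = 55, seed = 12)
  sim <- simulate_lineages(cfg)
  ep0 <- simulate_endpoint_panel(sim, marker_model(noise_cv = 0))
  map <- sim$truth$obs_map[sim$truth$obs_map$frame == sim$truth$n_frames - 1, ]
  cellid <- map$cell[match(ep0$label, map$label)]
  fate <- sim$truth$cells$fate[match(cellid, sim$truth$cells$cell)]
  dna <- sim$truth$phases$dna[sim$truth$phases$frame == sim$truth$n_frames - 1]
  dna <- dna[match(cellid,
                   sim$truth$phases$cell[sim$truth$phases$frame ==
                                           sim$truth$n_frames - 1])]
  # zero-noise DAPI is exactly proportional to DNA content
  expect_equal(ep0$dapi_total, 100 * dna, tolerance = 1e-12)
  # arrested cells: higher p21, lower pRb than cycling (endoreplicating)
  expect_gt(min(ep0$p21[fate == "arrest"]), max(ep0$p21[fate != "arrest"]) - 1e-9)
  expect_lt(max(ep0$pRb[fate == "arrest"]), min(ep0$pRb[fate != "arrest"]) + 1e-9)
  # fixed seed reruns identically
  expect_identical(simulate_endpoint_panel(sim, marker_model(), seed = 5),
                   simulate_endpoint_panel(sim, marker_model(), seed = 5))
})

test_that("count simulation plants the configured gene-set overlap", {
  cfg <- count_sim_config(n_genes = 500, n_cells = 50, n_hvg = 50,
                          geneset_size = 60, geneset_hvg_overlap = 0.5,
                          seed = 13)
  sim <- simulate_counts(cfg)
  expect_equal(length(sim$gene_set), 60)
  expect_equal(sum(sim$truth$in_geneset & sim$truth$planted_hvg), 30)
  expect_equal(sum(sim$truth$planted_hvg), 50)
  expect_true(all(sim$counts >= 0))
})

test_that("degenerate equal-count limit gives zero normalized s.d.", {
  # identical cells (equal totals and per-gene counts): s.d. is exactly 0
  m <- matrix(rep(c(2L, 5L, 9L, 1L), 10), nrow = 4,
              dimnames = list(paste0("g", 1:4), paste0("c", 1:10)))
  nr <- normalize_counts(m)
  expect_equal(unname(apply(nr$normalized, 1, stats::sd)), rep(0, 4))
  # zero-dispersion (Poisson) limit: residual variability collapses
  cfg <- count_sim_config(n_genes = 60, n_cells = 200, baseline_mean = 50,
                          dispersion = 0, n_hvg = 0, hvg_dispersion_factor = 1,
                          geneset_size = 0, geneset_hvg_overlap = 0, seed = 14)
  sim <- simulate_counts(cfg)
  nr2 <- normalize_counts(sim$counts)
  fit <- fit_residuals(nr2$normalized)
  expect_equal(sum(fit$genes$hvg), 0)
})
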