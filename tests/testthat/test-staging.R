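test_that("archetype traces yield the forced phase sequences", {
  th <- staging_thresholds()
  expect_equal(call_phases(c(0, 1, 2, 15, 20, 18, 12, 3, 2, 1), th)$labels,
               c("G1", "G1", "G1", "S", "S", "S", "S", "G2", "G2", "G2"))
  expect_equal(call_phases(rep(0, 6), th)$labels, rep("G1", 6))
  # a single high frame never makes an S phase (persistence 2)
  expect_equal(call_phases(c(1, 1, 12, 1, 1), th)$labels,
               c("G1", "G1", "transition", "G1", "G1"))
  expect_error(call_phases(integer(0), th), "empty")
  expect_error(staging_thresholds(g1_max_foci = 12, s_min_foci = 10), "<")
})

test_that("phase calling matches the run-scan oracle on random series", {
  set.seed(301)
  th <- staging_thresholds()
  for (i in 1:1000) {
    n <- sample(1:50, 1)
    # mixture that visits all regimes: lows, highs, mid-range transitions
    foci <- sample(c(0:6, 8, 9, 10:35), n, replace = TRUE)
    expect_identical(call_phases(foci, th)$labels,
                     oracle_phases(foci, 4, 10, 2))
  }
})

test_that("track starting in S at movie start is staged as S", {
  th <- staging_thresholds()
  tr <- call_phases(c(25, 28, 22, 3, 2, 1), th)
  expect_equal(tr$labels[1], "S")
  expect_equal(tr$labels[4:6], rep("G2", 3))
})

test_that("raising s_min_foci never adds S segments", {
  set.seed(302)
  for (i in 1:200) {
    foci <- sample(0:35, sample(10:50, 1), replace = TRUE)
    n_seg <- vapply(c(8, 10, 14, 20), function(smin) {
      tr <- call_phases(foci, staging_thresholds(s_min_foci = smin))
      length(tr$s_entries)        # S periods entered (replication rounds)
    }, numeric(1))
    expect_true(all(diff(n_seg) <= 0))
  }
})

test_that("phase durations are recovered to about one frame", {
  sim <- simulate_lineages(sim_config(n_founders = 30, duration = 55,
                                      field_size = c(3000, 3000), seed = 33))
  fo <- tracked_forest(sim)
  traces <- stage_tracks(fo)
  # truth durations per cell from the phase table
  pts <- merge(fo$points[, c("frame", "label", "track")],
               sim$truth$obs_map, by = c("frame", "label"))
  dom <- tapply(pts$cell, pts$track, function(z)
    as.integer(names(sort(table(z), decreasing = TRUE))[1]))
  errs <- c()
  for (id in names(traces)) {
    cell <- dom[[id]]
    tp <- sim$truth$phases[sim$truth$phases$cell == cell, ]
    seg <- traces[[id]]$segments
    for (ph in c("S")) {
      true_n <- sum(tp$phase == ph)
      got_n <- sum(seg$end[seg$phase == ph] - seg$start[seg$phase == ph] + 1)
      # compare only fully observed S phases
      if (true_n > 0 && got_n > 0 &&
          tp$phase[1] != ph && tp$phase[nrow(tp)] != ph)
        errs <- c(errs, abs(true_n - got_n))
    }
  }
  expect_gt(length(errs), 30)
  expect_lte(stats::median(errs), 1)
})

test_that("alignment on S entry puts the anchor at time zero", {
  th <- staging_thresholds()
  tr1 <- call_phases(c(rep(1, 6), rep(20, 10)), th)    # S entry frame 7
  tr2 <- call_phases(c(rep(1, 14), rep(20, 4)), th)    # S entry frame 15
  tr3 <- call_phases(rep(1, 10), th)                   # never enters S
  al <- align_lineages_by_phase(list(`1` = tr1, `2` = tr2, `3` = tr3),
                                anchor = "s_entry")
  expect_equal(al$offset_frames[1:2], c(-6, -14))
  expect_false(al$aligned[3])
  expect_true(is.na(al$offset_frames[3]))
  expect_error(align_lineages_by_phase(list(`1` = tr1), anchor = "nope"),
               "anchor")
})

test_that("aligned 53BP1 signal peaks before S entry when cleared at S", {
  sim <- simulate_lineages(sim_config(n_founders = 15, duration = 55,
                                      bp1_inherit_mean = 4,
                                      field_size = c(2500, 2500), seed = 35))
  fo <- tracked_forest(sim)
  traces <- stage_tracks(fo)
  al <- align_lineages_by_phase(traces, "s_entry", fo)
  pts <- fo$points
  agg <- NULL
  for (k in which(al$aligned)) {
    id <- al$track[k]
    sel <- pts$track == id
    rel <- pts$frame[sel] - al$anchor_frame[k]
    agg <- rbind(agg, data.frame(rel = rel, bp1 = pts$bp1_foci[sel]))
  }
  pre <- mean(agg$bp1[agg$rel >= -8 & agg$rel < 0])
  post <- mean(agg$bp1[agg$rel >= 0 & agg$rel < 8])
  expect_gt(pre, post + 0.5)
})

test_that("route classification is exact on archetypes", {
  th <- staging_thresholds()
  f_endo <- trace_endo()
  expect_equal(classify_ploidy_route(call_phases(f_endo, th),
                                     foci = f_endo)$route,
               "endoreplication")
  f_rere <- trace_rere()
  expect_equal(classify_ploidy_route(call_phases(f_rere, th),
                                     foci = f_rere)$route,
               "rereplication")
  f_norm <- trace_normal()
  expect_equal(classify_ploidy_route(call_phases(f_norm, th,
                                                 division_at_end = TRUE),
                                     division_frames = length(f_norm),
                                     foci = f_norm)$route,
               "normal")
  # S -> division -> S across generations
  f_two <- c(rep(20, 8), rep(1, 6), rep(20, 8))
  expect_equal(classify_ploidy_route(call_phases(f_two, th),
                                     division_frames = 12L,
                                     foci = f_two)$route,
               "normal")
  expect_equal(classify_ploidy_route(call_phases(rep(1, 30), th),
                                     foci = rep(1, 30))$route,
               "arrested")
  # DNA gate downgrades a polyploid call lacking >4N content
  expect_equal(classify_ploidy_route(call_phases(f_endo, th), foci = f_endo,
                                     dna_class = "G2")$route,
               "ambiguous")
})

test_that("noisy simulated polyploid fates are classified at >= 90%", {
  calls <- c()
  truth <- c()
  for (fate in c("endoreplication", "rereplication")) {
    fp <- c(normal = 0, endoreplication = 0, rereplication = 0, arrest = 0)
    fp[fate] <- 1
    sim <- simulate_lineages(sim_config(n_founders = 100, duration = 55,
                                        fate_probs = fp,
                                        field_size = c(4096, 4096),
                                        seed = 40 + nchar(fate)))
    fo <- tracked_forest(sim)
    traces <- stage_tracks(fo)
    for (id in names(traces)) {
      foci <- fo$points$pcna_foci[fo$points$track == as.integer(id)]
      calls <- c(calls, classify_ploidy_route(traces[[id]],
                                              foci = foci)$route)
      truth <- c(truth, fate)
    }
  }
  expect_gte(length(calls), 200)
  expect_gte(mean(calls == truth), 0.9)
})

test_that("lineage metrics count divisions and high-53BP1 frames", {
  sim <- small_movie(seed = 37, n_founders = 4, duration = 45)
  fo <- tracked_forest(sim)
  traces <- stage_tracks(fo)
  lm_ <- lineage_metrics(fo, traces)
  expect_equal(sum(lm_$divisions), nrow(fo$divisions))
  expect_true(all(lm_$divisions >= 0))
  expect_true(all(lm_$g1_h >= 0 & lm_$s_h >= 0))
  # the 53BP1 threshold example: series (0,3,11,12,2) has 2 high frames
  fo2 <- fo
  keep <- fo2$points$track == fo2$meta$track[1]
  fo2$points <- fo2$points[keep, ][1:5, ]
  fo2$points$bp1_foci <- c(0, 3, 11, 12, 2)
  fo2$meta <- fo2$meta[1, ]
  fo2$meta$tree <- 1
  fo2$divisions <- fo2$divisions[0, ]
  tr1 <- list(call_phases(fo2$points$pcna_foci, staging_thresholds()))
  names(tr1) <- as.character(fo2$meta$track[1])
  expect_equal(lineage_metrics(fo2, tr1)$frames_high_bp1, 2)
})

test_that("erratic foci series flag perturbed replication", {
  th <- staging_thresholds()
  clean <- c(rep(1, 6), rep(25, 16), rep(1, 6))
  noisy <- c(rep(1, 6), rep(c(25, 25, 6, 25, 7, 25), 4), rep(1, 6))
  mk_forest <- function(foci) {
    pts <- data.frame(frame = seq_along(foci) - 1, label = 1L,
                      track = 1L, x = 0, y = 0, area = 300,
                      pcna_foci = foci, bp1_foci = 0)
    structure(list(points = pts,
                   meta = data.frame(track = 1L, start_frame = 0,
                                     end_frame = length(foci) - 1,
                                     tree = 1L, parent = NA, depth = 0,
                                     generation = "P"),
                   edges = data.frame(parent = integer(),
                                      daughter = integer()),
                   divisions = data.frame(parent = integer(),
                                          frame = integer()),
                   frames = seq_along(foci) - 1),
              class = "lineage_forest")
  }
  f1 <- mk_forest(clean)
  m1 <- lineage_metrics(f1, list(`1` = call_phases(clean, th)))
  f2 <- mk_forest(noisy)
  m2 <- lineage_metrics(f2, list(`1` = call_phases(noisy, th)))
  expect_false(m1$perturbed_replication)
  expect_true(m2$perturbed_replication)
})
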