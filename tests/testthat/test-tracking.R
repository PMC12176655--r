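test_that("unambiguous nearest neighbours are linked and gates respected", {
  t0 <- data.frame(label = 1:2, x = c(0, 100), y = c(0, 100))
  t1 <- data.frame(label = 1:2, x = c(2, 101), y = c(1, 99))
  lk <- link_frames(t0, t1, link_params(max_displacement = 15))
  expect_equal(lk$links$label_t, 1:2)
  expect_equal(lk$links$label_t1, 1:2)
  expect_length(lk$unmatched_t, 0)

  # one cell moves beyond the gate: both rows unmatched
  t1b <- data.frame(label = 1:2, x = c(60, 101), y = c(1, 99))
  lk2 <- link_frames(t0, t1b, link_params(max_displacement = 15))
  expect_equal(lk2$unmatched_t, 1)
  expect_equal(lk2$unmatched_t1, 1)
  expect_equal(nrow(lk2$links), 1)

  expect_error(link_frames(data.frame(label = c(1, 1), x = 1:2, y = 1:2),
                           t1),
               "duplicate")
})

test_that("linking equals the exhaustive minimum-cost oracle", {
  set.seed(101)
  for (case in 1:300) {
    n <- sample(2:7, 1)
    a <- cbind(runif(n, 0, 50), runif(n, 0, 50))
    b <- cbind(runif(n, 0, 50), runif(n, 0, 50))
    gate <- 200   # everything allowed: perfect-matching oracle applies
    m <- match_points(a, b, gate)
    d <- sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2)
    expect_equal(nrow(m$matches), n)
    expect_equal(m$total_cost, brute_min_cost(d), tolerance = 1e-9)
  }
})

test_that("gated linking equals the exhaustive partial-matching oracle", {
  set.seed(202)
  for (case in 1:120) {
    n_a <- sample(1:5, 1)
    n_b <- sample(1:5, 1)
    a <- cbind(runif(n_a, 0, 30), runif(n_a, 0, 30))
    b <- cbind(runif(n_b, 0, 30), runif(n_b, 0, 30))
    gate <- runif(1, 5, 20)
    m <- match_points(a, b, gate)
    ref <- brute_gated(sqrt(outer(a[, 1], b[, 1], "-")^2 +
                              outer(a[, 2], b[, 2], "-")^2), gate)
    expect_equal(nrow(m$matches), ref$n)
    expect_equal(m$total_cost, ref$cost, tolerance = 1e-9)
  }
})

test_that("division rule: two half-area births near a track end", {
  obs <- rbind(
    data.frame(frame = 0:10, label = 1L, x = 100, y = 100,
               area = seq(300, 400, length.out = 11)),
    data.frame(frame = 11:15, label = 1L, x = 94, y = 100, area = 190),
    data.frame(frame = 11:15, label = 2L, x = 106, y = 100, area = 210))
  tr <- track_cells(obs, link_params())
  dv <- detect_divisions(tr)
  expect_equal(nrow(dv), 1)
  expect_equal(dv$parent_end_frame, 10)
  expect_equal(dv$daughter_start_frame, 11)

  # a single similar-area birth is a loss + appearance, not a division
  obs2 <- rbind(
    data.frame(frame = 0:10, label = 1L, x = 100, y = 100, area = 400),
    data.frame(frame = 11:15, label = 1L, x = 106, y = 100, area = 405))
  tr2 <- track_cells(obs2, link_params(max_displacement = 3))
  expect_equal(nrow(detect_divisions(tr2)), 0)
})

test_that("lineage construction labels generations by division depth", {
  # single track, no divisions
  obs <- data.frame(frame = 0:5, label = 1L, x = 0, y = 0, area = 300)
  f1 <- build_lineages(track_cells(obs))
  expect_equal(nrow(f1$meta), 1)
  expect_equal(f1$meta$generation, "P")

  # P -> (F1a, F1b); F1a -> (F2a, F2b)
  sim <- small_movie(seed = 21, n_founders = 4, duration = 45)
  fo <- tracked_forest(sim)
  expect_equal(nrow(fo$edges), 2 * nrow(fo$divisions))
  expected_gen <- ifelse(fo$meta$depth == 0, "P",
                         paste0("F", fo$meta$depth))
  expect_equal(fo$meta$generation, expected_gen)
  # every track in exactly one tree
  expect_equal(sum(is.na(fo$meta$tree)), 0)
  # conservation: tracks = nodes
  expect_equal(nrow(fo$meta), nrow(fo$points[!duplicated(fo$points$track), ]))
})

test_that("synthetic default movie is recovered nearly perfectly", {
  sim <- simulate_lineages(sim_config(n_founders = 12, duration = 50,
                                      motion_sigma = 3, seed = 23))
  tr <- track_cells(sim$obs)
  dv <- suppressWarnings(detect_divisions(tr))
  acc <- tracking_accuracy(tr, dv, sim$truth)
  expect_gte(acc$link_accuracy, 0.99)
  expect_gte(acc$edge_recall, 0.95)
})

test_that("a track claimed by two division events is a structural error", {
  obs <- data.frame(frame = rep(0:4, 3), label = rep(1:3, each = 5),
                    x = rep(c(0, 50, 100), each = 5), y = 0, area = 300)
  tr <- track_cells(obs)
  bad <- data.frame(parent = c(1L, 2L), daughter1 = c(3L, 3L),
                    daughter2 = c(2L, 1L), parent_end_frame = 4L,
                    daughter_start_frame = 5L)
  expect_error(build_lineages(tr, bad), "claimed by two")
})

test_that("curation edits replay correctly and log provenance", {
  sim <- small_movie(seed = 25, n_founders = 4, duration = 45)
  fo <- tracked_forest(sim)
  # identity
  expect_identical(apply_curation(fo, NULL), fo)
  expect_identical(apply_curation(fo, data.frame()), fo)

  # split: concatenation of the two parts equals the original
  tid <- fo$meta$track[which(fo$meta$end_frame - fo$meta$start_frame > 10)[1]]
  mid <- fo$meta$start_frame[fo$meta$track == tid] + 5L
  ed <- data.frame(op = "split", track = tid, arg = mid)
  fo2 <- suppressWarnings(apply_curation(fo, ed))
  new_id <- max(fo2$meta$track)
  pts_orig <- fo$points[fo$points$track == tid, ]
  pts_join <- fo2$points[fo2$points$track %in% c(tid, new_id), ]
  expect_equal(sort(pts_join$frame), sort(pts_orig$frame))
  expect_equal(nrow(fo2$meta), nrow(fo$meta) + 1)
  expect_length(fo2$curation_log, 1)

  # merge back restores the original frame coverage
  fo3 <- suppressWarnings(apply_curation(fo2, data.frame(op = "merge",
                                                         track = tid,
                                                         arg = new_id)))
  expect_equal(sort(fo3$points$frame[fo3$points$track == tid]),
               sort(pts_orig$frame))

  # delete removes the track
  dl <- fo$meta$track[1]
  fo4 <- suppressWarnings(apply_curation(fo, data.frame(op = "delete",
                                                        track = dl,
                                                        arg = NA)))
  expect_false(dl %in% fo4$meta$track)

  # reassign a daughter to a parent that already has two is rejected
  if (nrow(fo$divisions) >= 2) {
    d_other <- fo$divisions$daughter1[2]
    p_full <- fo$divisions$parent[1]
    expect_error(
      suppressWarnings(apply_curation(fo, data.frame(op = "reassign",
                                                     track = d_other,
                                                     arg = p_full))),
      "two daughters")
  }
})

test_that("edge recovery degrades monotonically with motion noise", {
  recs <- vapply(c(1, 6, 12), function(sig) {
    sim <- simulate_lineages(sim_config(n_founders = 8, duration = 45,
                                        motion_sigma = sig, seed = 31))
    tr <- track_cells(sim$obs)
    dv <- suppressWarnings(detect_divisions(tr))
    tracking_accuracy(tr, dv, sim$truth)$link_accuracy
  }, numeric(1))
  expect_true(all(diff(recs) <= 1e-9))
})
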