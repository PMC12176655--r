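#' Simulation configuration for synthetic lineage movies
#'
#' Defines the generative model for multigenerational time-lapse movies of
#' cells carrying a PCNA-like replication marker (channel 1) and a
#' 53BP1-like damage marker (channel 2). The defaults emulate asynchronously
#' growing cultured cells imaged at 30-minute intervals: lognormal phase
#' durations, phase-dependent Poisson PCNA foci counts that straddle the
#' staging thresholds, 53BP1 nuclear bodies inherited at birth and cleared
#' at S entry, monotone nuclear growth with halving at division, and an
#' isotropic Gaussian random walk for motion.
#'
#' @param n_founders number of founder cells at frame 0.
#' @param frame_interval acquisition cadence in minutes.
#' @param duration movie length in hours; the movie has
#'   `floor(duration * 60 / frame_interval) + 1` frames.
#' @param phase_means named vector of mean phase durations in hours
#'   (G1, S, G2, M).
#' @param phase_cv coefficient of variation of the lognormal phase durations.
#' @param pcna_lambda named vector of expected PCNA foci per frame in
#'   G1, S and G2 (M uses the G2 rate).
#' @param bp1_inherit_mean expected 53BP1 bodies per daughter at birth
#'   (Poisson).
#' @param bp1_clear_at_s if TRUE, 53BP1 bodies are removed at S entry.
#' @param motion_sigma random-walk step s.d. in pixels per frame.
#' @param field_size field of view in pixels, c(width, height).
#' @param division_displacement distance in pixels between each newborn
#'   daughter and the parent's last position.
#' @param min_spacing hard-core exclusion distance in pixels: nuclei are
#'   pushed apart so that no two centroids come closer than this (nuclei
#'   cannot interpenetrate); set 0 to disable.
#' @param fate_probs per-cycle fate probabilities, named
#'   normal/endoreplication/rereplication/arrest; must sum to 1.
#' @param treatment_schedule optional list of treatment windows, each a list
#'   with `start`, `end` (hours) and `multipliers`, a named numeric vector
#'   applied to `pcna_lambda_G1/S/G2`, `bp1_inherit_mean`,
#'   `p_endoreplication`, `p_rereplication` or `p_arrest` for draws whose
#'   time falls inside the window.
#' @param detection_dropout probability that a live cell is missing from a
#'   frame's feature table (simulates segmentation dropout; default 0).
#' @param seed integer seed; equal seeds give byte-identical outputs.
#' @returns an object of class `sim_config`.
#' @export
sim_config <- function(n_founders = 20,
                       frame_interval = 30,
                       duration = 55,
                       phase_means = c(G1 = 10, S = 8, G2 = 4, M = 0.5),
                       phase_cv = 0.15,
                       pcna_lambda = c(G1 = 1, S = 30, G2 = 1),
                       bp1_inherit_mean = 2,
                       bp1_clear_at_s = TRUE,
                       motion_sigma = 3,
                       field_size = c(2048, 2048),
                       division_displacement = 25,
                       min_spacing = 40,
                       fate_probs = c(normal = 1, endoreplication = 0,
                                      rereplication = 0, arrest = 0),
                       treatment_schedule = NULL,
                       detection_dropout = 0,
                       seed = 1L) {
  check_positive(n_founders, "n_founders")
  check_positive(frame_interval, "frame_interval")
  check_positive(duration, "duration")
  if (!all(c("G1", "S", "G2", "M") %in% names(phase_means)))
    abort_config("phase_means must name G1, S, G2 and M")
  check_positive(unname(phase_means), "phase_means")
  check_nonneg(phase_cv, "phase_cv")
  if (!all(c("G1", "S", "G2") %in% names(pcna_lambda)))
    abort_config("pcna_lambda must name G1, S and G2")
  check_nonneg(unname(pcna_lambda), "pcna_lambda")
  check_nonneg(bp1_inherit_mean, "bp1_inherit_mean")
  check_nonneg(motion_sigma, "motion_sigma")
  check_positive(field_size, "field_size")
  check_positive(division_displacement, "division_displacement")
  check_nonneg(min_spacing, "min_spacing")
  if (!all(c("normal", "endoreplication", "rereplication", "arrest") %in%
           names(fate_probs)))
    abort_config("fate_probs must name normal/endoreplication/rereplication/arrest")
  check_nonneg(unname(fate_probs), "fate_probs")
  if (abs(sum(fate_probs) - 1) > 1e-8)
    abort_config("fate_probs must sum to 1")
  if (detection_dropout < 0 || detection_dropout >= 1)
    abort_config("detection_dropout must be in [0, 1)")
  structure(list(
    n_founders = as.integer(n_founders), frame_interval = frame_interval,
    duration = duration, phase_means = phase_means, phase_cv = phase_cv,
    pcna_lambda = pcna_lambda, bp1_inherit_mean = bp1_inherit_mean,
    bp1_clear_at_s = isTRUE(bp1_clear_at_s), motion_sigma = motion_sigma,
    field_size = field_size,
    division_displacement = division_displacement,
    min_spacing = min_spacing,
    fate_probs = fate_probs / sum(fate_probs),
    treatment_schedule = treatment_schedule,
    detection_dropout = detection_dropout, seed = as.integer(seed)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  n_frames <- floor(x$duration * 60 / x$frame_interval) + 1
  cat("Synthetic lineage movie configuration\n")
  cat(sprintf("  %d founders, %g h at %g-min frames (%d frames)\n",
              x$n_founders, x$duration, x$frame_interval, n_frames))
  cat(sprintf("  phase means (h): G1=%g S=%g G2=%g M=%g (CV %g)\n",
              x$phase_means["G1"], x$phase_means["S"], x$phase_means["G2"],
              x$phase_means["M"], x$phase_cv))
  cat(sprintf("  PCNA foci lambda: G1=%g S=%g G2=%g\n",
              x$pcna_lambda["G1"], x$pcna_lambda["S"], x$pcna_lambda["G2"]))
  cat(sprintf("  fates: %s\n",
              paste(names(x$fate_probs), round(x$fate_probs, 3),
                    sep = "=", collapse = " ")))
  invisible(x)
}

# multiplier applicable at time t_h for a named parameter, from the schedule
treatment_multiplier <- function(schedule, param, t_h) {
  m <- 1
  for (w in schedule %||% list()) {
    if (t_h >= w$start && t_h <= w$end && param %in% names(w$multipliers))
      m <- m * w$multipliers[[param]]
  }
  m
}

# one cell's phase/DNA segment schedule given its fate; durations in hours.
# Returns data.frame(phase, dur, dna0, dna1) covering at least horizon_h.
draw_schedule <- function(fate, cfg, horizon_h, dna_birth = 2) {
  pm <- cfg$phase_means
  cv <- cfg$phase_cv
  d <- function(ph) rlnorm_mean_cv(1, pm[[ph]], cv)
  seg <- function(phase, dur, dna0, dna1)
    data.frame(phase = phase, dur = dur, dna0 = dna0, dna1 = dna1)
  if (fate == "arrest") {
    return(seg("G1", max(horizon_h, 1) + 1, dna_birth, dna_birth))
  }
  if (fate == "normal") {
    return(rbind(seg("G1", d("G1"), dna_birth, dna_birth),
                 seg("S",  d("S"),  dna_birth, 2 * dna_birth),
                 seg("G2", d("G2"), 2 * dna_birth, 2 * dna_birth),
                 seg("M",  d("M"),  2 * dna_birth, 2 * dna_birth)))
  }
  if (fate == "endoreplication") {
    # successive endocycles (G1 -> S -> G2, no mitosis), DNA doubling each S
    segs <- NULL
    dna <- dna_birth
    total <- 0
    while (total < horizon_h + 1) {
      g1 <- d("G1"); s <- d("S"); g2 <- d("G2")
      segs <- rbind(segs,
                    seg("G1", g1, dna, dna),
                    seg("S",  s,  dna, 2 * dna),
                    seg("G2", g2, 2 * dna, 2 * dna))
      dna <- 2 * dna
      total <- total + g1 + s + g2
    }
    return(segs)
  }
  if (fate == "rereplication") {
    # one continuous, extended S: a second S duration is appended with no
    # intervening foci-low gap; DNA rises continuously past 4N
    s1 <- d("S"); s2 <- d("S")
    return(rbind(seg("G1", d("G1"), dna_birth, dna_birth),
                 seg("S", s1 + s2, dna_birth, 4 * dna_birth),
                 seg("G2", max(horizon_h, 1) + 1,
                     4 * dna_birth, 4 * dna_birth)))
  }
  abort_config("unknown fate '%s'", fate)
}

draw_fate <- function(cfg, t_h) {
  p <- cfg$fate_probs
  p["endoreplication"] <- p["endoreplication"] *
    treatment_multiplier(cfg$treatment_schedule, "p_endoreplication", t_h)
  p["rereplication"] <- p["rereplication"] *
    treatment_multiplier(cfg$treatment_schedule, "p_rereplication", t_h)
  p["arrest"] <- p["arrest"] *
    treatment_multiplier(cfg$treatment_schedule, "p_arrest", t_h)
  p <- p / sum(p)
  sample(names(p), 1, prob = p)
}

#' Simulate a multigenerational lineage movie
#'
#' Generates a per-cell per-frame feature table (the observation table any
#' segmentation front end would produce) together with the full ground
#' truth: the lineage forest, per-frame true phases and DNA content,
#' division frames, per-track fates and inherited damage counts. Daughters
#' appear on the frame after the parent's last frame; per-frame object
#' labels are randomly permuted so that identity can only be recovered by
#' tracking.
#'
#' @param config a [sim_config()].
#' @returns list with elements `obs` (data frame, one row per cell per
#'   frame) and `truth` (class `lineage_truth`: `cells`, `edges`,
#'   `divisions`, `phases`, `obs_map`, `n_frames`, `frame_interval`).
#' @export
simulate_lineages <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  dt_h <- cfg$frame_interval / 60
  n_frames <- floor(cfg$duration * 60 / cfg$frame_interval) + 1L
  frame_time <- function(f) f * dt_h          # frames are 0-based
  last_frame <- n_frames - 1L

  # founder placement: jittered grid guaranteeing generous spacing
  k <- ceiling(sqrt(cfg$n_founders))
  gx <- cfg$field_size[1] / k
  gy <- cfg$field_size[2] / ceiling(cfg$n_founders / k)
  idx <- seq_len(cfg$n_founders) - 1L
  fx <- (idx %% k + 0.5) * gx + stats::runif(cfg$n_founders, -0.05, 0.05) * gx
  fy <- (idx %/% k + 0.5) * gy + stats::runif(cfg$n_founders, -0.05, 0.05) * gy

  cells <- list(); phases <- list(); rows <- list()
  edges <- data.frame(parent = integer(), daughter = integer())
  divisions <- data.frame(parent = integer(), frame = integer())
  next_id <- 1L

  # queue of cells to simulate; founders start mid-cycle (asynchronous)
  founder_areas <- stats::rnorm(cfg$n_founders, 250, 15)
  queue <- lapply(seq_len(cfg$n_founders), function(i) {
    list(parent = NA_integer_, birth_frame = 0L, generation = 0L,
         founder = i, birth_area = founder_areas[i], dna = 2)
  })

  while (length(queue)) {
    cell <- queue[[1]]; queue <- queue[-1]
    id <- next_id; next_id <- next_id + 1L
    t_birth <- frame_time(cell$birth_frame)
    fate <- draw_fate(cfg, t_birth)
    sched <- draw_schedule(fate, cfg, cfg$duration + 1, cell$dna)
    # founders join mid-cycle: advance the cycle clock by a uniform offset
    offset <- 0
    if (is.na(cell$parent) && fate == "normal")
      offset <- stats::runif(1, 0, sum(sched$dur))
    bounds <- cumsum(sched$dur)
    total <- bounds[length(bounds)]
    t_ref <- if (fate == "normal") total else sum(cfg$phase_means)

    # division occurs when the cycle clock passes the schedule end (normal)
    div_frame <- NA_integer_
    if (fate == "normal") {
      t_div <- t_birth + total - offset
      f_div <- floor(t_div / dt_h)
      if (f_div <= last_frame && f_div >= cell$birth_frame)
        div_frame <- as.integer(f_div)
    }
    end_frame <- if (!is.na(div_frame)) div_frame else last_frame

    fr <- cell$birth_frame:end_frame
    nf <- length(fr)
    tau <- frame_time(fr) - t_birth + offset
    seg_idx <- pmin(findInterval(tau, c(0, bounds), rightmost.closed = TRUE),
                    nrow(sched))
    seg_idx[seg_idx < 1L] <- 1L
    ph <- sched$phase[seg_idx]
    ph[ph == "M"] <- "G2"                    # M is carried by the division
    if (!is.na(div_frame)) ph[nf] <- "M"     # frame only
    # DNA content: linear within each segment
    seg_start <- c(0, bounds)[seg_idx]
    frac <- pmin(pmax((tau - seg_start) / sched$dur[seg_idx], 0), 1)
    dna <- sched$dna0[seg_idx] + frac * (sched$dna1[seg_idx] - sched$dna0[seg_idx])

    # 53BP1 bodies: inherited at birth, cleared at S entry
    bp1_birth <- stats::rpois(1, cfg$bp1_inherit_mean *
      treatment_multiplier(cfg$treatment_schedule, "bp1_inherit_mean", t_birth))
    entered_s <- cumsum(ph == "S") > 0
    bp1 <- rep(bp1_birth, nf)
    if (cfg$bp1_clear_at_s) bp1[entered_s] <- 0L
    if (is.na(cell$parent) && any(ph[1] %in% c("S", "G2", "M")))
      bp1[] <- 0L                             # founders past G1 carry none

    # PCNA foci: Poisson with phase- and treatment-dependent rate
    lam_name <- ifelse(ph == "M", "G2", ph)
    lam <- unname(cfg$pcna_lambda[lam_name])
    tmul <- vapply(frame_time(fr), function(t)
      treatment_multiplier(cfg$treatment_schedule,
                           paste0("pcna_lambda_", "S"), t), numeric(1))
    lam[lam_name == "S"] <- lam[lam_name == "S"] * tmul[lam_name == "S"]
    foci <- stats::rpois(nf, lam)

    # nuclear area: monotone growth, doubling over one reference cycle
    area_true <- cell$birth_area * (1 + tau / t_ref)
    area_obs <- area_true + stats::rnorm(nf, 0, 4)

    ch1_mean <- 400 + 15 * foci + stats::rnorm(nf, 0, 10)
    ch2_mean <- 250 + 60 * bp1 + stats::rnorm(nf, 0, 10)

    rows[[id]] <- data.frame(
      frame = fr, cell = id, x = NA_real_, y = NA_real_,
      area = area_obs, area_um2 = area_obs * 0.1056,
      ch1_mean = ch1_mean, ch1_total = ch1_mean * area_obs,
      ch2_mean = ch2_mean, ch2_total = ch2_mean * area_obs,
      pcna_foci = foci, bp1_foci = bp1,
      pcna_foci_int = pmax(0, foci * 1200 + stats::rnorm(nf, 0, 20)),
      bp1_foci_int = pmax(0, bp1 * 900 + stats::rnorm(nf, 0, 20)))
    phases[[id]] <- data.frame(cell = id, frame = fr, phase = ph, dna = dna)
    cells[[id]] <- data.frame(
      cell = id, parent = cell$parent, birth_frame = cell$birth_frame,
      end_frame = end_frame, generation = cell$generation, fate = fate,
      born_by_division = !is.na(cell$parent), bp1_birth = bp1_birth,
      end_type = if (!is.na(div_frame) && div_frame < last_frame)
        "division" else "movie_end")

    if (!is.na(div_frame) && div_frame < last_frame) {
      divisions <- rbind(divisions, data.frame(parent = id, frame = div_frame))
      split <- stats::runif(1, 0.45, 0.55)
      a_end <- area_true[nf]
      for (s in 1:2) {
        frac_a <- if (s == 1) split else 1 - split
        daughter <- list(parent = id, birth_frame = div_frame + 1L,
                         generation = cell$generation + 1L, founder = NA,
                         birth_area = a_end * frac_a, dna = 2)
        queue <- c(queue, list(daughter))
      }
    }
  }

  cells_df <- do.call(rbind, cells)
  rownames(cells_df) <- NULL
  edges <- cells_df[!is.na(cells_df$parent), c("parent", "cell")]
  names(edges) <- c("parent", "daughter")
  rownames(edges) <- NULL

  # ---- joint motion pass: Gaussian random walk with hard-core exclusion --
  # Positions are simulated frame by frame over all live cells at once so
  # that nuclei keep at least min_spacing between centroids; daughters are
  # placed symmetrically about the parent's last position.
  n_cells <- nrow(cells_df)
  pos <- matrix(NA_real_, n_cells, 2)
  founder_of <- rep(NA_integer_, n_cells)
  founder_of[is.na(cells_df$parent)] <- seq_len(sum(is.na(cells_df$parent)))
  xcoord <- lapply(rows, function(r) rep(NA_real_, nrow(r)))
  ycoord <- xcoord
  div_angle <- list()
  margin <- 10
  for (f in 0:last_frame) {
    alive <- which(cells_df$birth_frame <= f & cells_df$end_frame >= f)
    move <- alive[cells_df$birth_frame[alive] < f]
    born <- alive[cells_df$birth_frame[alive] == f]
    if (length(move))
      pos[move, ] <- pos[move, ] +
        matrix(stats::rnorm(2 * length(move), 0, cfg$motion_sigma), ncol = 2)
    for (id in born) {
      p <- cells_df$parent[id]
      if (is.na(p)) {
        i <- founder_of[id]
        pos[id, ] <- c(fx[i], fy[i])
      } else {
        key <- as.character(p)
        if (is.null(div_angle[[key]])) {
          div_angle[[key]] <- stats::runif(1, 0, 2 * pi)
          sgn <- 1
        } else sgn <- -1
        a <- div_angle[[key]]
        pos[id, ] <- pos[p, ] +
          sgn * cfg$division_displacement * c(cos(a), sin(a))
      }
    }
    # hard-core relaxation: push overlapping nuclei apart
    if (cfg$min_spacing > 0 && length(alive) > 1) {
      for (it in 1:12) {
        P <- pos[alive, , drop = FALSE]
        D <- as.matrix(stats::dist(P))
        D[upper.tri(D, diag = TRUE)] <- Inf
        bad <- which(D < cfg$min_spacing, arr.ind = TRUE)
        if (!nrow(bad)) break
        for (k in seq_len(nrow(bad))) {
          i <- alive[bad[k, 2]]; j <- alive[bad[k, 1]]
          v <- pos[j, ] - pos[i, ]
          dd <- sqrt(sum(v^2))
          if (dd < 1e-9) { v <- c(1, 0); dd <- 1 }
          push <- 0.52 * (cfg$min_spacing - dd) * v / dd
          pos[i, ] <- pos[i, ] - push
          pos[j, ] <- pos[j, ] + push
        }
      }
    }
    pos[alive, 1] <- pmin(pmax(pos[alive, 1], margin), cfg$field_size[1] - margin)
    pos[alive, 2] <- pmin(pmax(pos[alive, 2], margin), cfg$field_size[2] - margin)
    for (id in alive) {
      k <- f - cells_df$birth_frame[id] + 1L
      xcoord[[id]][k] <- pos[id, 1]
      ycoord[[id]][k] <- pos[id, 2]
    }
  }
  for (id in seq_len(n_cells)) {
    rows[[id]]$x <- xcoord[[id]]
    rows[[id]]$y <- ycoord[[id]]
  }

  obs <- do.call(rbind, rows)
  phases_df <- do.call(rbind, phases)
  rownames(obs) <- rownames(phases_df) <- NULL

  # simulated detection dropout (never the first or last frame of a cell)
  if (cfg$detection_dropout > 0) {
    drop <- stats::runif(nrow(obs)) < cfg$detection_dropout
    first_last <- obs$frame == ave(obs$frame, obs$cell, FUN = min) |
      obs$frame == ave(obs$frame, obs$cell, FUN = max)
    obs <- obs[!(drop & !first_last), , drop = FALSE]
  }

  # per-frame random label permutation: identity is only in the truth map
  obs <- obs[order(obs$frame, obs$cell), , drop = FALSE]
  obs$label <- NA_integer_
  for (f in unique(obs$frame)) {
    sel <- which(obs$frame == f)
    obs$label[sel] <- sample(length(sel))
  }
  obs_map <- data.frame(frame = obs$frame, label = obs$label, cell = obs$cell)
  obs <- data.frame(frame = obs$frame,
                    time_h = obs$frame * dt_h,
                    well = "A1", position = 1L, label = obs$label,
                    obs[, c("x", "y", "area", "area_um2", "ch1_mean",
                            "ch1_total", "ch2_mean", "ch2_total",
                            "pcna_foci", "bp1_foci", "pcna_foci_int",
                            "bp1_foci_int")])
  obs <- obs[order(obs$frame, obs$label), , drop = FALSE]
  obs_map <- obs_map[order(obs_map$frame, obs_map$label), , drop = FALSE]
  rownames(obs) <- rownames(obs_map) <- NULL

  truth <- structure(list(cells = cells_df, edges = edges,
                          divisions = divisions, phases = phases_df,
                          obs_map = obs_map, n_frames = n_frames,
                          frame_interval = cfg$frame_interval,
                          config = cfg),
                     class = "lineage_truth")
  list(obs = obs, truth = truth)
}

#' @export
print.lineage_truth <- function(x, ...) {
  cat(sprintf("Ground truth: %d cells, %d division events, %d frames\n",
              nrow(x$cells), nrow(x$divisions), x$n_frames))
  cat(sprintf("  fates: %s\n",
              paste(names(table(x$cells$fate)), table(x$cells$fate),
                    sep = "=", collapse = " ")))
  invisible(x)
}
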