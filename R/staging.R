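#' Cell-cycle staging thresholds for PCNA foci series
#'
#' G1 is called at 0-4 PCNA foci; S entry at the first run of at least
#' `persistence` consecutive frames with >= `s_min_foci` foci; G2 entry at
#' the first subsequent run of at least `persistence` frames with
#' <= `g1_max_foci` foci. Frames matching neither rule are labelled
#' "transition".
#'
#' @param g1_max_foci maximum foci count for G1/G2 (default 4).
#' @param s_min_foci minimum foci count for S (default 10).
#' @param persistence frames a run must persist to switch phase (default 2).
#' @param frame_interval minutes per frame, used for durations in hours.
#' @returns object of class `staging_thresholds`.
#' @export
staging_thresholds <- function(g1_max_foci = 4, s_min_foci = 10,
                               persistence = 2, frame_interval = 30) {
  check_nonneg(g1_max_foci, "g1_max_foci")
  check_positive(s_min_foci, "s_min_foci")
  if (g1_max_foci >= s_min_foci)
    abort_config("g1_max_foci must be < s_min_foci")
  if (persistence < 1) abort_config("persistence must be >= 1")
  check_positive(frame_interval, "frame_interval")
  structure(list(g1_max_foci = g1_max_foci, s_min_foci = s_min_foci,
                 persistence = as.integer(persistence),
                 frame_interval = frame_interval),
            class = "staging_thresholds")
}

# first index >= from at which a run of len frames all satisfying cond starts
first_run <- function(cond, len, from = 1L) {
  n <- length(cond)
  if (from > n - len + 1L) return(NA_integer_)
  for (i in from:(n - len + 1L)) {
    if (all(cond[i:(i + len - 1L)])) return(i)
  }
  NA_integer_
}

#' Call cell-cycle phases from a PCNA foci time series
#'
#' Scans the series for S entries (first persistent high-foci run) and G2
#' entries (first persistent low-foci run after an S entry), possibly over
#' several replication rounds in one track. Frames before the first S entry
#' are G1 when low and "transition" otherwise; frames inside an S period
#' are S when high and "transition" otherwise; frames after a G2 entry are
#' G2 when low (relabelled G1 when a further S entry follows, an endocycle
#' gap) and "transition" otherwise. Sub-persistence excursions stay
#' "transition" rather than being absorbed. The mitotic frame is assigned
#' by the caller via `division_at_end` since mitosis is not staged from
#' PCNA.
#'
#' @param foci non-negative integer vector, one count per frame.
#' @param th a [staging_thresholds()].
#' @param division_at_end if TRUE the final frame is labelled "M".
#' @returns object of class `phase_trace`: `labels` (per frame), `segments`
#'   (phase, start/end frame indices 1-based, duration_h), `s_entries`,
#'   `g2_entries`.
#' @export
call_phases <- function(foci, th = staging_thresholds(),
                        division_at_end = FALSE) {
  if (length(foci) == 0) stop("empty foci series", call. = FALSE)
  if (any(!is.finite(foci)) || any(foci < 0))
    stop("foci series must be non-negative and finite", call. = FALSE)
  n <- length(foci)
  high <- foci >= th$s_min_foci
  low <- foci <= th$g1_max_foci
  p <- th$persistence

  s_entries <- integer(0)
  g2_entries <- integer(0)
  pos <- 1L
  repeat {
    s <- first_run(high, p, pos)
    if (is.na(s)) break
    s_entries <- c(s_entries, s)
    g2 <- first_run(low, p, s + 1L)
    if (is.na(g2)) break
    g2_entries <- c(g2_entries, g2)
    pos <- g2
  }

  labels <- character(n)
  bnd_s <- c(s_entries, n + 1L)
  first_s <- bnd_s[1]
  # before the first S entry
  if (first_s > 1L) {
    idx <- 1:(first_s - 1L)
    labels[idx] <- ifelse(low[idx], "G1", "transition")
  }
  for (k in seq_along(s_entries)) {
    s0 <- s_entries[k]
    s1 <- if (k <= length(g2_entries)) g2_entries[k] - 1L else n
    idx <- s0:s1
    labels[idx] <- ifelse(high[idx], "S", "transition")
    if (k <= length(g2_entries)) {
      g0 <- g2_entries[k]
      g1end <- if (k < length(s_entries)) s_entries[k + 1L] - 1L else n
      idx <- g0:g1end
      # a later S entry marks this low period as an endocycle gap (G1)
      post <- if (k < length(s_entries)) "G1" else "G2"
      labels[idx] <- ifelse(low[idx], post, "transition")
    }
  }
  if (division_at_end) labels[n] <- "M"

  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segments <- data.frame(phase = r$values, start = starts, end = ends,
                         duration_h = r$lengths * th$frame_interval / 60)
  structure(list(labels = labels, segments = segments,
                 s_entries = s_entries, g2_entries = g2_entries,
                 thresholds = th),
            class = "phase_trace")
}

#' @export
print.phase_trace <- function(x, ...) {
  cat(sprintf("Phase trace over %d frames: %s\n", length(x$labels),
              paste(sprintf("%s(%g h)", x$segments$phase,
                            round(x$segments$duration_h, 2)),
                    collapse = " -> ")))
  invisible(x)
}

#' Stage every track of a lineage forest
#'
#' Runs [call_phases()] on each track's PCNA foci series; tracks ending in
#' a division get their final frame labelled "M".
#'
#' @param forest a `lineage_forest` whose points carry `pcna_foci`.
#' @param th a [staging_thresholds()].
#' @returns named list of `phase_trace`, one per track id.
#' @export
stage_tracks <- function(forest, th = staging_thresholds()) {
  pts <- forest$points
  div_parents <- forest$divisions$parent
  out <- list()
  for (tr in forest$meta$track) {
    foci <- pts$pcna_foci[pts$track == tr]
    out[[as.character(tr)]] <-
      call_phases(foci, th, division_at_end = tr %in% div_parents)
  }
  out
}

#' Align tracks in silico by cell-cycle position
#'
#' Gives each track a time offset such that the chosen anchor event (S
#' entry or division, i.e. the first frame of a division-born track) maps
#' to time zero, so traces can be averaged in cell-cycle-aligned time.
#' Tracks lacking the anchor are flagged unaligned.
#'
#' @param traces named list of `phase_trace` from [stage_tracks()].
#' @param anchor "s_entry" or "division".
#' @param forest the `lineage_forest` (required for the division anchor and
#'   for converting track-local frame indices to movie frames).
#' @returns data frame: `track`, `anchor_frame` (movie frame), `offset_frames`,
#'   `offset_h`, `aligned`.
#' @export
align_lineages_by_phase <- function(traces, anchor = c("s_entry", "division"),
                                    forest = NULL) {
  if (!is.character(anchor) || !anchor[1] %in% c("s_entry", "division"))
    abort_config("unknown alignment anchor '%s'", as.character(anchor[1]))
  anchor <- anchor[1]
  ids <- as.integer(names(traces))
  start_frames <- if (!is.null(forest))
    forest$meta$start_frame[match(ids, forest$meta$track)] else rep(0L, length(ids))
  born_div <- if (!is.null(forest))
    ids %in% c(forest$divisions$daughter1, forest$divisions$daughter2)
  else rep(FALSE, length(ids))
  anchor_frame <- rep(NA_integer_, length(ids))
  for (k in seq_along(ids)) {
    tr <- traces[[k]]
    if (anchor == "s_entry") {
      if (length(tr$s_entries))
        anchor_frame[k] <- start_frames[k] + tr$s_entries[1] - 1L
    } else {
      if (born_div[k]) anchor_frame[k] <- start_frames[k]
    }
  }
  fi <- traces[[1]]$thresholds$frame_interval
  data.frame(track = ids, anchor_frame = anchor_frame,
             offset_frames = -anchor_frame,
             offset_h = -anchor_frame * fi / 60,
             aligned = !is.na(anchor_frame))
}

#' Parameters for polyploidization-route classification
#'
#' @param max_normal_s_duration longest S phase (hours) compatible with a
#'   normal replication round; a longer uninterrupted S suggests
#'   rereplication. The default (12 h) sits more than three standard
#'   deviations above a typical 8 h S phase, and a dividing cell is called
#'   "normal" regardless of S duration, so normal cycles cannot trip this
#'   rule.
#' @param min_gap minimum number of low-foci frames between two S segments
#'   for them to count as separate replication rounds (endocycle); a
#'   shorter gap reads as S resuming, i.e. rereplication.
#' @returns object of class `route_params`.
#' @export
route_params <- function(max_normal_s_duration = 12, min_gap = 4) {
  check_positive(max_normal_s_duration, "max_normal_s_duration")
  check_positive(min_gap, "min_gap")
  structure(list(max_normal_s_duration = max_normal_s_duration,
                 min_gap = as.integer(min_gap)),
            class = "route_params")
}

#' Classify the polyploidization route of a staged trace
#'
#' Operational rules: two S segments separated by at least `min_gap`
#' low-foci frames with no intervening division is endoreplication; a
#' single S segment longer than `max_normal_s_duration`, or S resuming
#' after fewer than `min_gap` low frames, with no division, is
#' rereplication; S segments separated by a division are a normal cycle;
#' no S and no division with low foci throughout is arrest; anything else
#' is ambiguous. When an end-point DNA class is supplied and is not
#' hyperploid (>4N), endoreplication/rereplication calls are downgraded to
#' ambiguous.
#'
#' @param trace a `phase_trace` (may span a multi-generation path).
#' @param division_frames 1-based frame indices (within the trace) at which
#'   divisions occur; an empty vector means no division.
#' @param params a [route_params()].
#' @param foci the foci series the trace was called from (needed to count
#'   low-foci gap frames); defaults to reconstructing lows from labels.
#' @param dna_class optional end-point DNA content class (see
#'   [gate_dna_content()]); one of "subG1", "G1", "S", "G2", "hyperploid".
#' @returns object of class `ploidy_route`: `route` and `evidence`.
#' @export
classify_ploidy_route <- function(trace, division_frames = integer(0),
                                  params = route_params(), foci = NULL,
                                  dna_class = NULL) {
  th <- trace$thresholds
  labels <- trace$labels
  low <- if (!is.null(foci)) foci <= th$g1_max_foci
  else labels %in% c("G1", "G2")
  seg <- trace$segments
  s_seg <- seg[seg$phase == "S", , drop = FALSE]
  n_div <- length(division_frames)

  evidence <- list(n_s_segments = nrow(s_seg),
                   s_durations_h = s_seg$duration_h,
                   n_divisions = n_div, gap_low_frames = integer(0),
                   dna_class = dna_class %||% NA_character_)
  route <- "ambiguous"
  if (nrow(s_seg) == 0) {
    route <- if (n_div == 0 && all(labels %in% c("G1", "transition")) &&
                 mean(labels == "G1") > 0.5) "arrested" else "ambiguous"
  } else if (nrow(s_seg) == 1) {
    if (n_div >= 1) route <- "normal"
    else if (s_seg$duration_h[1] > params$max_normal_s_duration)
      route <- "rereplication"
    else route <- "ambiguous"
  } else {
    gaps <- integer(nrow(s_seg) - 1)
    split_by_division <- logical(length(gaps))
    for (k in seq_along(gaps)) {
      span <- (s_seg$end[k] + 1L):(s_seg$start[k + 1L] - 1L)
      gaps[k] <- sum(low[span])
      split_by_division[k] <- any(division_frames > s_seg$end[k] &
                                    division_frames <= s_seg$start[k + 1L])
    }
    evidence$gap_low_frames <- gaps
    if (all(split_by_division)) route <- "normal"
    else if (any(!split_by_division & gaps >= params$min_gap))
      route <- "endoreplication"
    else route <- "rereplication"
  }
  if (route %in% c("endoreplication", "rereplication") &&
      !is.null(dna_class) && dna_class != "hyperploid")
    route <- "ambiguous"
  structure(list(route = route, evidence = evidence), class = "ploidy_route")
}

#' @export
print.ploidy_route <- function(x, ...) {
  cat(sprintf("Ploidy route: %s (%d S segment(s), %d division(s))\n",
              x$route, x$evidence$n_s_segments, x$evidence$n_divisions))
  invisible(x)
}

#' Lineage-level stress metrics
#'
#' Per lineage tree: the number of divisions, the number of frames with
#' more than `bp1_threshold` 53BP1 foci, whether replication looks
#' perturbed (some track spends more than `perturbed_fraction` of its S
#' period, S entry to S exit, in "transition" frames), and summed phase
#' durations.
#'
#' @param forest a `lineage_forest` whose points carry `bp1_foci`.
#' @param traces named list of `phase_trace` from [stage_tracks()].
#' @param bp1_threshold foci count above which a frame counts as
#'   high-53BP1 (default 10).
#' @param perturbed_fraction transition fraction within S that flags
#'   perturbed replication (default 0.2).
#' @returns data frame with one row per tree.
#' @export
lineage_metrics <- function(forest, traces, bp1_threshold = 10,
                            perturbed_fraction = 0.2) {
  meta <- forest$meta
  pts <- forest$points
  out <- NULL
  for (tree in sort(unique(meta$tree))) {
    ids <- meta$track[meta$tree == tree]
    n_div <- sum(forest$divisions$parent %in% ids)
    bp1 <- pts$bp1_foci[pts$track %in% ids]
    high <- sum(bp1 > bp1_threshold, na.rm = TRUE)
    perturbed <- FALSE
    dur <- c(G1 = 0, S = 0, G2 = 0, M = 0, transition = 0)
    for (id in ids) {
      tr <- traces[[as.character(id)]]
      if (is.null(tr)) next
      seg <- tr$segments
      for (ph in names(dur))
        dur[ph] <- dur[ph] + sum(seg$duration_h[seg$phase == ph])
      if (length(tr$s_entries) && length(tr$g2_entries)) {
        span <- tr$s_entries[1]:(tr$g2_entries[1] - 1L)
        if (mean(tr$labels[span] == "transition") > perturbed_fraction)
          perturbed <- TRUE
      }
    }
    out <- rbind(out, data.frame(
      tree = tree, divisions = n_div, frames_high_bp1 = high,
      perturbed_replication = perturbed,
      g1_h = unname(dur["G1"]), s_h = unname(dur["S"]),
      g2_h = unname(dur["G2"]), transition_h = unname(dur["transition"])))
  }
  out
}
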