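#' Linking parameters for frame-to-frame tracking
#'
#' @param max_displacement maximum centroid displacement (pixels) allowed
#'   for a frame-to-frame link.
#' @param max_gap number of consecutive frames a cell may be missing and
#'   still rejoin its track (the gate widens proportionally to the gap).
#' @param division_window number of frames after a track end within which
#'   daughter tracks may be born.
#' @param division_radius maximum distance (pixels) between a parent's last
#'   position and a daughter's first position.
#' @param area_ratio_bounds allowed range for daughter/parent nuclear area
#'   at division (the nucleus roughly halves).
#' @returns an object of class `link_params`.
#' @export
link_params <- function(max_displacement = 20, max_gap = 1,
                        division_window = 2, division_radius = 40,
                        area_ratio_bounds = c(0.35, 0.70)) {
  check_positive(max_displacement, "max_displacement")
  check_nonneg(max_gap, "max_gap")
  check_positive(division_window, "division_window")
  check_positive(division_radius, "division_radius")
  check_positive(area_ratio_bounds, "area_ratio_bounds")
  if (area_ratio_bounds[1] >= area_ratio_bounds[2])
    abort_config("area_ratio_bounds must be increasing")
  structure(list(max_displacement = max_displacement,
                 max_gap = as.integer(max_gap),
                 division_window = as.integer(division_window),
                 division_radius = division_radius,
                 area_ratio_bounds = area_ratio_bounds),
            class = "link_params")
}

#' Link the observations of two consecutive frames
#'
#' Computes the optimal one-to-one matching (minimum total displacement
#' among maximum-cardinality matchings) between the object centroids of two
#' frames, gated by `max_displacement`. Unmatched objects on either side
#' are reported.
#'
#' @param obs_t,obs_t1 data frames with at least `label`, `x`, `y`.
#' @param params a [link_params()].
#' @returns list with `links` (data frame `label_t`, `label_t1`, `dist`),
#'   `unmatched_t`, `unmatched_t1` (label vectors).
#' @export
link_frames <- function(obs_t, obs_t1, params = link_params()) {
  for (o in list(obs_t, obs_t1))
    if (anyDuplicated(o$label))
      stop("duplicate object labels within a frame", call. = FALSE)
  m <- match_points(cbind(obs_t$x, obs_t$y), cbind(obs_t1$x, obs_t1$y),
                    params$max_displacement)
  list(links = data.frame(label_t = obs_t$label[m$matches$i],
                          label_t1 = obs_t1$label[m$matches$j],
                          dist = m$matches$dist),
       unmatched_t = obs_t$label[m$unmatched_a],
       unmatched_t1 = obs_t1$label[m$unmatched_b])
}

#' Build tracks from a per-frame observation table
#'
#' Links observations frame by frame with the optimal gated matching,
#' carrying unmatched tracks over gaps of up to `max_gap` frames (with a
#' proportionally widened gate). Tracks record their birth type (movie
#' start or appearance) and end type (movie end or loss); division edges
#' are added separately by [detect_divisions()].
#'
#' @param obs observation table (one row per object per frame, with
#'   `frame`, `label`, `x`, `y`, `area` and any feature columns).
#' @param params a [link_params()].
#' @param break_on_division if TRUE (default) a frame-to-frame link whose
#'   nuclear area drops into `area_ratio_bounds` of the previous frame
#'   while a new object appears within `division_radius` is treated as a
#'   mitosis: the old track ends and a fresh daughter track starts, so that
#'   [detect_divisions()] can pair the two newborn sisters.
#' @returns object of class `cell_tracks`: list with `points` (observation
#'   rows plus a `track` column), `meta` (one row per track) and `params`.
#' @export
track_cells <- function(obs, params = link_params(),
                        break_on_division = TRUE) {
  stopifnot(all(c("frame", "label", "x", "y") %in% names(obs)))
  has_area <- "area" %in% names(obs)
  obs <- obs[order(obs$frame, obs$label), , drop = FALSE]
  frames <- sort(unique(obs$frame))
  by_frame <- split(obs, obs$frame)

  obs$track <- NA_integer_
  next_track <- 1L
  active <- data.frame(track = integer(), last_frame = integer(),
                       x = numeric(), y = numeric(), area = numeric())
  row_index <- split(seq_len(nrow(obs)), obs$frame)

  for (fi in seq_along(frames)) {
    f <- frames[fi]
    cur <- by_frame[[as.character(f)]]
    rows <- row_index[[as.character(f)]]
    assigned <- rep(NA_integer_, nrow(cur))
    cur_area <- if (has_area) cur$area else rep(NA_real_, nrow(cur))

    # drop tracks that have been missing too long
    if (nrow(active))
      active <- active[f - active$last_frame <= params$max_gap + 1L, ,
                       drop = FALSE]

    remaining <- seq_len(nrow(cur))
    # direct links (no gap), with division breaking
    cand <- which(active$last_frame == f - 1L)
    if (length(cand) && length(remaining)) {
      m <- match_points(cbind(active$x[cand], active$y[cand]),
                        cbind(cur$x[remaining], cur$y[remaining]),
                        params$max_displacement)
      if (nrow(m$matches)) {
        ai <- cand[m$matches$i]
        oi <- remaining[m$matches$j]
        keep <- rep(TRUE, length(ai))
        if (break_on_division && has_area) {
          unmatched_now <- setdiff(remaining, oi)
          for (k in seq_along(ai)) {
            ratio <- cur_area[oi[k]] / active$area[ai[k]]
            if (!is.na(ratio) &&
                ratio >= params$area_ratio_bounds[1] &&
                ratio <= params$area_ratio_bounds[2]) {
              near_birth <- length(unmatched_now) &&
                any(sqrt((cur$x[unmatched_now] - active$x[ai[k]])^2 +
                           (cur$y[unmatched_now] - active$y[ai[k]])^2) <=
                      params$division_radius)
              if (near_birth) keep[k] <- FALSE
            }
          }
        }
        ai <- ai[keep]; oi <- oi[keep]
        if (length(ai)) {
          assigned[oi] <- active$track[ai]
          active$last_frame[ai] <- f
          active$x[ai] <- cur$x[oi]
          active$y[ai] <- cur$y[oi]
          active$area[ai] <- cur_area[oi]
          remaining <- setdiff(remaining, oi)
        }
        # parents broken at division are closed (stay at last_frame f-1 and
        # are excluded from gap rescue so daughters are not re-absorbed)
        broken <- cand[m$matches$i][!keep]
        if (length(broken))
          active <- active[!(seq_len(nrow(active)) %in% broken), , drop = FALSE]
      }
    }
    # gap rescue for tracks missing >= 1 frame: widened distance gate, plus
    # an area-continuity gate so a lost track cannot swallow a newborn
    # daughter (whose nucleus is about half the size)
    for (gap in seq_len(params$max_gap)) {
      if (!length(remaining) || !nrow(active)) break
      cand <- which(active$last_frame == f - 1L - gap)
      if (!length(cand)) next
      gate <- params$max_displacement * (gap + 1L)
      dmat <- sqrt(outer(active$x[cand], cur$x[remaining], "-")^2 +
                     outer(active$y[cand], cur$y[remaining], "-")^2)
      if (has_area) {
        rmat <- outer(1 / active$area[cand], cur_area[remaining])
        dmat[!is.na(rmat) & (rmat < 0.7 | rmat > 1.4)] <- Inf
      }
      m <- gated_assignment(dmat, gate)
      if (nrow(m$matches)) {
        ai <- cand[m$matches$i]
        oi <- remaining[m$matches$j]
        assigned[oi] <- active$track[ai]
        active$last_frame[ai] <- f
        active$x[ai] <- cur$x[oi]
        active$y[ai] <- cur$y[oi]
        active$area[ai] <- cur_area[oi]
        remaining <- setdiff(remaining, oi)
      }
    }
    # new tracks for still-unmatched observations
    if (length(remaining)) {
      ids <- next_track + seq_along(remaining) - 1L
      next_track <- next_track + length(remaining)
      assigned[remaining] <- ids
      active <- rbind(active,
                      data.frame(track = ids, last_frame = f,
                                 x = cur$x[remaining], y = cur$y[remaining],
                                 area = cur_area[remaining]))
    }
    obs$track[rows] <- assigned
  }

  pts <- obs[order(obs$track, obs$frame), , drop = FALSE]
  rownames(pts) <- NULL
  first <- !duplicated(pts$track)
  last <- !duplicated(pts$track, fromLast = TRUE)
  meta <- data.frame(
    track = pts$track[first],
    start_frame = pts$frame[first], end_frame = pts$frame[last],
    start_x = pts$x[first], start_y = pts$y[first],
    end_x = pts$x[last], end_y = pts$y[last],
    start_area = if ("area" %in% names(pts)) pts$area[first] else NA_real_,
    end_area = if ("area" %in% names(pts)) pts$area[last] else NA_real_)
  f0 <- min(frames); f1 <- max(frames)
  meta$birth_type <- ifelse(meta$start_frame == f0, "movie_start", "appearance")
  meta$end_type <- ifelse(meta$end_frame == f1, "movie_end", "loss")
  structure(list(points = pts, meta = meta, params = params,
                 frames = frames),
            class = "cell_tracks")
}

#' @export
print.cell_tracks <- function(x, ...) {
  cat(sprintf("%d tracks over %d frames (%d observations)\n",
              nrow(x$meta), length(x$frames), nrow(x$points)))
  invisible(x)
}

#' Detect cell divisions among assembled tracks
#'
#' A track end followed, within `division_window` frames and
#' `division_radius` pixels, by track births whose first areas fall within
#' `area_ratio_bounds` of the parent's last area is a division candidate.
#' Births are assigned to parents globally: each ending track offers two
#' daughter slots at its last position and the optimal gated matching
#' (maximum pairs, then minimum total distance — the same engine as the
#' frame linker) resolves competing parents and supernumerary candidates
#' deterministically. Parents with both slots filled yield one
#' DivisionEvent; a parent with more than two plausible candidates emits a
#' curation warning.
#'
#' @param tracks a `cell_tracks` object.
#' @param params a [link_params()].
#' @returns data frame with one row per division: `parent`, `daughter1`,
#'   `daughter2`, `parent_end_frame`, `daughter_start_frame`.
#' @export
detect_divisions <- function(tracks, params = tracks$params) {
  meta <- tracks$meta
  enders <- meta[meta$end_frame < max(tracks$frames), , drop = FALSE]
  births <- meta[meta$birth_type == "appearance", , drop = FALSE]
  if (!nrow(enders) || !nrow(births)) return(empty_divisions())
  np <- nrow(enders)
  nb <- nrow(births)
  d <- sqrt(outer(enders$end_x, births$start_x, "-")^2 +
              outer(enders$end_y, births$start_y, "-")^2)
  in_window <- outer(enders$end_frame, births$start_frame,
                     function(e, s) s > e & s <= e + params$division_window)
  ratio <- outer(1 / enders$end_area, births$start_area)
  ok <- in_window & d <= params$division_radius &
    (is.na(ratio) | (ratio >= params$area_ratio_bounds[1] &
                       ratio <= params$area_ratio_bounds[2]))
  many <- rowSums(ok) > 2
  for (k in which(many))
    warning(sprintf("track %d: %d division candidates; keeping best two (curation advised)",
                    enders$track[k], sum(ok[k, ])), call. = FALSE)
  # candidate sister pairs per parent: both births pass the gates and were
  # born on the same frame; cost favours pairs whose midpoint sits on the
  # parent's last position (daughters separate symmetrically at mitosis)
  cand <- NULL
  for (k in seq_len(np)) {
    js <- which(ok[k, ])
    if (length(js) < 2) next
    for (u in seq_along(js)[-length(js)]) for (v in (u + 1):length(js)) {
      j1 <- js[u]; j2 <- js[v]
      if (births$start_frame[j1] != births$start_frame[j2]) next
      mx <- (births$start_x[j1] + births$start_x[j2]) / 2
      my <- (births$start_y[j1] + births$start_y[j2]) / 2
      cost <- sqrt((mx - enders$end_x[k])^2 + (my - enders$end_y[k])^2)
      if (cost <= params$division_radius)
        cand <- rbind(cand, data.frame(p = k, j1 = j1, j2 = j2, cost = cost))
    }
  }
  if (is.null(cand)) return(empty_divisions())
  # exact set-packing per connected component: maximise the number of
  # division events, then minimise the total midpoint cost
  comp_id <- uf_components(np, nb, data.frame(i = c(cand$p, cand$p),
                                              j = c(cand$j1, cand$j2)))
  out <- NULL
  for (cc in unique(comp_id[cand$p])) {
    rows <- which(comp_id[cand$p] == cc)
    parents <- unique(cand$p[rows])
    best <- NULL; best_n <- -1L; best_cost <- Inf
    search <- function(pi, used_births, chosen, total) {
      if (pi > length(parents)) {
        n <- length(chosen)
        if (n > best_n || (n == best_n && total < best_cost)) {
          best <<- chosen; best_n <<- n; best_cost <<- total
        }
        return(invisible())
      }
      opts <- rows[cand$p[rows] == parents[pi]]
      opts <- opts[order(cand$cost[opts])]
      if (length(opts) > 4L) opts <- opts[1:4]   # bound the search
      for (o in opts) {
        if (cand$j1[o] %in% used_births || cand$j2[o] %in% used_births) next
        search(pi + 1L, c(used_births, cand$j1[o], cand$j2[o]),
               c(chosen, o), total + cand$cost[o])
      }
      search(pi + 1L, used_births, chosen, total)   # skip this parent
    }
    search(1L, integer(0), integer(0), 0)
    for (o in best) {
      k <- cand$p[o]
      dts <- sort(births$track[c(cand$j1[o], cand$j2[o])])
      out <- rbind(out, data.frame(
        parent = enders$track[k], daughter1 = dts[1], daughter2 = dts[2],
        parent_end_frame = enders$end_frame[k],
        daughter_start_frame = min(births$start_frame[c(cand$j1[o], cand$j2[o])])))
    }
  }
  if (is.null(out)) return(empty_divisions())
  out <- out[order(out$parent), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_divisions <- function() {
  data.frame(parent = integer(), daughter1 = integer(), daughter2 = integer(),
             parent_end_frame = integer(), daughter_start_frame = integer())
}

#' Assemble lineage trees from tracks and division events
#'
#' Builds the forest of binary lineage trees: every track belongs to
#' exactly one tree, edges join parents to daughters, and generation labels
#' (P, F1, F2, ...) record the division depth from the root.
#'
#' @param tracks a `cell_tracks` object.
#' @param divisions a division table from [detect_divisions()].
#' @returns object of class `lineage_forest`: `points`, `meta` (with
#'   `parent`, `tree`, `depth`, `generation`), `edges`, `divisions`.
#' @export
build_lineages <- function(tracks, divisions = empty_divisions()) {
  meta <- tracks$meta
  parent <- rep(NA_integer_, nrow(meta))
  names(parent) <- meta$track
  claimed <- c(divisions$daughter1, divisions$daughter2)
  claimed <- claimed[!is.na(claimed)]
  if (anyDuplicated(claimed)) {
    bad <- claimed[duplicated(claimed)][1]
    ev <- which(divisions$daughter1 == bad | divisions$daughter2 == bad)
    stop(sprintf("track %d claimed by two division events (rows %s)",
                 bad, paste(ev, collapse = ", ")), call. = FALSE)
  }
  for (k in seq_len(nrow(divisions))) {
    parent[as.character(divisions$daughter1[k])] <- divisions$parent[k]
    if (!is.na(divisions$daughter2[k]))
      parent[as.character(divisions$daughter2[k])] <- divisions$parent[k]
  }
  depth <- rep(NA_integer_, nrow(meta))
  names(depth) <- meta$track
  root_of <- function(tr) {
    path <- integer(0)
    while (!is.na(parent[as.character(tr)])) {
      path <- c(path, tr)
      tr <- parent[as.character(tr)]
      if (tr %in% path) stop("cycle in lineage edges", call. = FALSE)
    }
    tr
  }
  tree <- vapply(meta$track, root_of, numeric(1))
  for (tr in meta$track) {
    d <- 0L; cur <- tr
    while (!is.na(parent[as.character(cur)])) {
      d <- d + 1L
      cur <- parent[as.character(cur)]
    }
    depth[as.character(tr)] <- d
  }
  meta$parent <- unname(parent)
  meta$tree <- as.integer(tree)
  meta$depth <- unname(depth)
  meta$generation <- ifelse(meta$depth == 0L, "P", paste0("F", meta$depth))
  edges <- data.frame(parent = c(divisions$parent, divisions$parent),
                      daughter = c(divisions$daughter1, divisions$daughter2))
  edges <- edges[!is.na(edges$daughter), , drop = FALSE]
  edges <- edges[order(edges$parent, edges$daughter), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(points = tracks$points, meta = meta, edges = edges,
                 divisions = divisions, frames = tracks$frames,
                 curation_log = list()),
            class = "lineage_forest")
}

#' @export
print.lineage_forest <- function(x, ...) {
  cat(sprintf("Lineage forest: %d trees, %d tracks, %d division events\n",
              length(unique(x$meta$tree)), nrow(x$meta), nrow(x$divisions)))
  cat("  generations:", paste(names(table(x$meta$generation)),
                              table(x$meta$generation),
                              sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Replay manual curation edits on a lineage forest
#'
#' Applies an ordered list of curation records. Supported operations:
#' `reassign` (move a daughter to a new parent), `delete` (remove a track
#' and detach its daughters), `split` (cut a track at a frame into two),
#' and `merge` (concatenate a track with a later one). Edits violating the
#' binary-branching invariant are rejected with a reason; the applied edit
#' list is stored in `curation_log` for provenance.
#'
#' @param forest a `lineage_forest`.
#' @param edits data frame with columns `op`, `track`, `arg` (new parent
#'   for reassign, frame for split, other track for merge, ignored for
#'   delete).
#' @returns the edited `lineage_forest`.
#' @export
apply_curation <- function(forest, edits) {
  if (is.null(edits) || nrow(edits) == 0) return(forest)
  meta <- forest$meta
  div <- forest$divisions
  pts <- forest$points
  for (k in seq_len(nrow(edits))) {
    e <- edits[k, ]
    if (!e$track %in% meta$track && e$op != "noop")
      stop(sprintf("edit %d: unknown track %s", k, e$track), call. = FALSE)
    if (e$op == "reassign") {
      newp <- as.integer(e$arg)
      if (!newp %in% meta$track)
        stop(sprintf("edit %d: unknown parent %s", k, e$arg), call. = FALSE)
      # detach from the current event; the orphaned sister becomes a
      # singleton event awaiting consolidation
      hit <- which(div$daughter1 == e$track | div$daughter2 == e$track)
      for (h in sort(hit, decreasing = TRUE)) {
        other <- setdiff(c(div$daughter1[h], div$daughter2[h]), e$track)
        other <- other[!is.na(other)]
        p_old <- div$parent[h]
        pef <- div$parent_end_frame[h]
        div <- div[-h, , drop = FALSE]
        if (length(other))
          div <- rbind(div, data.frame(parent = p_old, daughter1 = other,
                                       daughter2 = NA_integer_,
                                       parent_end_frame = pef,
                                       daughter_start_frame =
                                         meta$start_frame[match(other, meta$track)]))
      }
      n_existing <- sum(c(div$daughter1[div$parent == newp],
                          div$daughter2[div$parent == newp]) %in% meta$track,
                        na.rm = TRUE)
      if (n_existing >= 2)
        stop(sprintf("edit %d rejected: parent %d already has two daughters",
                     k, newp), call. = FALSE)
      pm <- meta[match(newp, meta$track), ]
      dm <- meta[match(e$track, meta$track), ]
      div <- rbind(div, data.frame(parent = newp, daughter1 = e$track,
                                   daughter2 = NA_integer_,
                                   parent_end_frame = pm$end_frame,
                                   daughter_start_frame = dm$start_frame))
      # pair up singleton events for the same parent
      div <- consolidate_events(div)
    } else if (e$op == "delete") {
      meta <- meta[meta$track != e$track, , drop = FALSE]
      pts <- pts[pts$track != e$track, , drop = FALSE]
      div <- div[div$parent != e$track, , drop = FALSE]
      hit <- which(div$daughter1 == e$track | div$daughter2 == e$track)
      if (length(hit)) div <- div[-hit, , drop = FALSE]
    } else if (e$op == "split") {
      f <- as.integer(e$arg)
      sel <- pts$track == e$track
      if (!any(pts$frame[sel] >= f) || !any(pts$frame[sel] < f))
        stop(sprintf("edit %d: split frame %d outside track %d", k, f,
                     e$track), call. = FALSE)
      new_id <- max(meta$track) + 1L
      pts$track[sel & pts$frame >= f] <- new_id
      m <- meta[match(e$track, meta$track), ]
      tail_last <- m$end_frame
      meta$end_frame[match(e$track, meta$track)] <- max(pts$frame[pts$track == e$track])
      meta <- rbind(meta, within(m, {
        track <- new_id; start_frame <- f; end_frame <- tail_last
        birth_type <- "appearance"; parent <- NA_integer_
      })[names(meta)])
      meta$end_type[match(e$track, meta$track)] <- "loss"
      # division events pointing at the old track end move to the tail
      div$parent[div$parent == e$track] <- new_id
    } else if (e$op == "merge") {
      other <- as.integer(e$arg)
      if (!other %in% meta$track)
        stop(sprintf("edit %d: unknown track %s", k, e$arg), call. = FALSE)
      a <- meta[match(e$track, meta$track), ]
      b <- meta[match(other, meta$track), ]
      if (b$start_frame <= a$end_frame)
        stop(sprintf("edit %d rejected: tracks %d and %d overlap in time",
                     k, e$track, other), call. = FALSE)
      pts$track[pts$track == other] <- e$track
      meta$end_frame[match(e$track, meta$track)] <- b$end_frame
      meta$end_type[match(e$track, meta$track)] <- b$end_type
      meta <- meta[meta$track != other, , drop = FALSE]
      div$parent[div$parent == other] <- e$track
      hit <- which(div$daughter1 == other | div$daughter2 == other)
      if (length(hit)) div <- div[-hit, , drop = FALSE]
    } else {
      stop(sprintf("edit %d: unknown op '%s'", k, e$op), call. = FALSE)
    }
  }
  if (any(is.na(div$daughter2)))
    warning("curation left unpaired daughters; their division events have a single edge",
            call. = FALSE)
  div <- div[!is.na(div$daughter1), , drop = FALSE]
  tracks2 <- structure(list(points = pts,
                            meta = meta[setdiff(names(meta),
                                                c("parent", "tree", "depth",
                                                  "generation"))],
                            params = NULL, frames = forest$frames),
                       class = "cell_tracks")
  out <- build_lineages(tracks2, div)
  out$curation_log <- c(forest$curation_log, list(edits))
  out
}

# pair singleton (one-daughter) events of the same parent into one event
consolidate_events <- function(div) {
  singles <- which(is.na(div$daughter2))
  for (p in unique(div$parent[singles])) {
    mine <- which(div$parent == p & is.na(div$daughter2))
    if (length(mine) >= 2) {
      d <- sort(c(div$daughter1[mine[1]], div$daughter1[mine[2]]))
      div$daughter1[mine[1]] <- d[1]
      div$daughter2[mine[1]] <- d[2]
      div <- div[-mine[2], , drop = FALSE]
    }
  }
  div
}

#' Compare recovered tracks and divisions to the simulation ground truth
#'
#' @param tracks a `cell_tracks` object built from a synthetic movie.
#' @param divisions recovered division table.
#' @param truth the `lineage_truth` from [simulate_lineages()].
#' @returns list with `link_accuracy` (fraction of true frame-to-frame
#'   links reproduced), `edge_recall` (fraction of true parent-daughter
#'   edges recovered), `false_divisions` (events with no true counterpart).
#' @export
tracking_accuracy <- function(tracks, divisions, truth) {
  pts <- merge(tracks$points[, c("frame", "label", "track")],
               truth$obs_map, by = c("frame", "label"))
  pts <- pts[order(pts$track, pts$frame), , drop = FALSE]
  # recovered links: consecutive rows of one track on consecutive frames
  same_track <- diff(pts$track) == 0
  link_ok <- pts$cell[-1] == pts$cell[-nrow(pts)]
  # true links: consecutive presence of the same cell
  tp <- truth$obs_map[order(truth$obs_map$cell, truth$obs_map$frame), ]
  true_links <- sum(diff(tp$cell) == 0)
  got_links <- sum(same_track & link_ok)
  # track -> dominant true cell
  dom <- tapply(pts$cell, pts$track, function(z)
    as.integer(names(sort(table(z), decreasing = TRUE))[1]))
  true_edges <- truth$edges
  hit <- 0L
  for (k in seq_len(nrow(divisions))) {
    p <- dom[as.character(divisions$parent[k])]
    d1 <- dom[as.character(divisions$daughter1[k])]
    d2 <- dom[as.character(divisions$daughter2[k])]
    ok1 <- any(true_edges$parent == p & true_edges$daughter == d1)
    ok2 <- any(true_edges$parent == p & true_edges$daughter == d2)
    hit <- hit + ok1 + ok2
  }
  list(link_accuracy = got_links / true_links,
       edge_recall = if (nrow(true_edges)) hit / nrow(true_edges) else NA_real_,
       false_divisions = 2 * nrow(divisions) - hit,
       n_true_links = true_links, n_true_edges = nrow(true_edges))
}
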