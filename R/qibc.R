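#' Register an end-point staining round to the live-cell field
#'
#' Estimates a pure-translation shift between the final live frame and an
#' end-point acquisition of the same field of view, as the coordinate-wise
#' median displacement over mutual nearest neighbours, then recomputes an
#' optimal one-to-one matching after the shift. Cells lost during staining
#' washes are reported unmatched.
#'
#' @param live data frame of the final live frame: `label`, `x`, `y`.
#' @param endpoint data frame of one staining round: `label`, `x`, `y`.
#' @param tolerance maximum residual distance (pixels) for a match.
#' @returns object of class `round_registration`: `translation` (dx, dy),
#'   `matches` (live_label, endpoint_label, dist), `unmatched_live`,
#'   `unmatched_endpoint`, `failed`, `tolerance`.
#' @export
register_rounds <- function(live, endpoint, tolerance = 15) {
  check_positive(tolerance, "tolerance")
  fail <- function() structure(list(translation = c(dx = NA_real_, dy = NA_real_),
                                    matches = data.frame(live_label = integer(),
                                                         endpoint_label = integer(),
                                                         dist = numeric()),
                                    unmatched_live = live$label,
                                    unmatched_endpoint = endpoint$label,
                                    failed = TRUE, tolerance = tolerance),
                               class = "round_registration")
  if (nrow(live) == 0 || nrow(endpoint) == 0) return(fail())
  d <- sqrt(outer(live$x, endpoint$x, "-")^2 + outer(live$y, endpoint$y, "-")^2)
  nn_le <- apply(d, 1, which.min)
  nn_el <- apply(d, 2, which.min)
  mutual <- which(nn_el[nn_le] == seq_len(nrow(live)))
  if (length(mutual) < 3) return(fail())
  dx <- stats::median(endpoint$x[nn_le[mutual]] - live$x[mutual])
  dy <- stats::median(endpoint$y[nn_le[mutual]] - live$y[mutual])
  m <- match_points(cbind(live$x + dx, live$y + dy),
                    cbind(endpoint$x, endpoint$y), tolerance)
  structure(list(translation = c(dx = dx, dy = dy),
                 matches = data.frame(
                   live_label = live$label[m$matches$i],
                   endpoint_label = endpoint$label[m$matches$j],
                   dist = m$matches$dist),
                 unmatched_live = live$label[m$unmatched_a],
                 unmatched_endpoint = endpoint$label[m$unmatched_b],
                 failed = FALSE, tolerance = tolerance),
            class = "round_registration")
}

#' @export
print.round_registration <- function(x, ...) {
  if (x$failed) cat("Round registration FAILED (< 3 mutual pairs)\n")
  else cat(sprintf("Round registration: shift (%.2f, %.2f) px, %d matched, %d/%d unmatched (live/endpoint)\n",
                   x$translation[1], x$translation[2], nrow(x$matches),
                   length(x$unmatched_live), length(x$unmatched_endpoint)))
  invisible(x)
}

#' Verify fluorescence elution between staining rounds
#'
#' Computes, per matched cell, the residual signal fraction
#' (post - background) / (pre - background). The round passes when the
#' median residual fraction over evaluable cells is at most
#' `max_residual_fraction`. Cells with pre-elution signal at background
#' level are excluded from the median and counted separately; cells whose
#' residual exceeds the bound are flagged as non-eluting outliers.
#'
#' @param pre,post numeric vectors of matched per-cell intensities before
#'   and after elution.
#' @param max_residual_fraction QC bound on the median residual (default 0.1).
#' @param background constant background level subtracted from both.
#' @returns list: `pass`, `median_residual`, `residuals`, `n_excluded`,
#'   `outliers` (indices), `max_residual_fraction`.
#' @export
verify_elution <- function(pre, post, max_residual_fraction = 0.1,
                           background = 0) {
  if (length(pre) != length(post))
    stop("pre and post must be matched vectors of equal length", call. = FALSE)
  check_nonneg(max_residual_fraction, "max_residual_fraction")
  p0 <- pre - background
  p1 <- post - background
  eval_ok <- p0 > max(1e-9, 1e-6 * stats::median(abs(p0)))
  res <- rep(NA_real_, length(pre))
  res[eval_ok] <- p1[eval_ok] / p0[eval_ok]
  med <- stats::median(res[eval_ok])
  list(pass = is.finite(med) && med <= max_residual_fraction,
       median_residual = med, residuals = res,
       n_excluded = sum(!eval_ok),
       outliers = which(eval_ok & res > max_residual_fraction),
       max_residual_fraction = max_residual_fraction)
}

#' DNA-content gate factors
#'
#' Class boundaries as multiples of the G1 (2N) peak of the DAPI-total
#' distribution: subG1 below `lower`, G1 in [lower, s), S in [s, g2),
#' G2 in [g2, hyper), hyperploid (>4N) at or above `hyper`.
#'
#' @param lower,s,g2,hyper boundary factors (defaults 0.75, 1.25, 1.75, 2.5).
#' @returns object of class `gate_params`.
#' @export
gate_params <- function(lower = 0.75, s = 1.25, g2 = 1.75, hyper = 2.5) {
  v <- c(lower, s, g2, hyper)
  check_positive(v, "gate factors")
  if (any(diff(v) <= 0)) abort_config("gate factors must be increasing")
  structure(list(lower = lower, s = s, g2 = g2, hyper = hyper),
            class = "gate_params")
}

#' Gate DNA content from DAPI totals
#'
#' Locates the G1 (2N) peak as the dominant mode of the DAPI-total
#' distribution and assigns each cell a ploidy class from the gate
#' factors. When a second mode of comparable height exists below the
#' dominant one, the lower mode is taken as 2N with a warning (the G2 peak
#' of a cycling population can rival the G1 peak).
#'
#' @param dapi_totals numeric vector of per-cell integrated DAPI.
#' @param params a [gate_params()].
#' @returns list: `class` (factor with levels subG1, G1, S, G2,
#'   hyperploid), `peak` (estimated 2N position), `ambiguous` (logical).
#' @export
gate_dna_content <- function(dapi_totals, params = gate_params()) {
  x <- dapi_totals[is.finite(dapi_totals)]
  if (length(x) < 2) stop("need at least 2 cells to gate", call. = FALSE)
  if (length(x) < 50)
    warning("fewer than 50 cells; G1 peak estimate may be unstable",
            call. = FALSE)
  ambiguous <- FALSE
  x <- x[x > 0]                 # DNA stain totals are strictly positive
  if (length(x) < 2 || stats::sd(x) < 1e-12 * max(abs(x))) {
    peak <- x[1]
  } else {
    # mode-finding on the log scale: DNA content classes sit at multiples
    # of the 2N peak, i.e. equidistant in log, so a single bandwidth
    # resolves 2N/4N/8N alike
    den <- stats::density(log(x))
    yy <- den$y
    is_mode <- which(diff(sign(diff(yy))) == -2) + 1L
    if (!length(is_mode)) is_mode <- which.max(yy)
    mx <- exp(den$x[is_mode])
    my <- yy[is_mode]
    # G1 is the lowest substantial mode: polyploid or G2-heavy populations
    # can out-peak it without moving the 2N position
    substantial <- my >= 0.25 * max(my)
    peak <- min(mx[substantial])
    if (sum(my >= 0.6 * max(my)) > 1 || peak < mx[which.max(my)] - 1e-12) {
      ambiguous <- TRUE
      warning("multiple comparable DAPI modes; taking the lowest substantial mode as 2N",
              call. = FALSE)
    }
  }
  br <- c(-Inf, params$lower, params$s, params$g2, params$hyper, Inf) *
    c(1, peak, peak, peak, peak, 1)
  cls <- cut(dapi_totals, breaks = br, right = FALSE,
             labels = c("subG1", "G1", "S", "G2", "hyperploid"))
  list(class = cls, peak = peak, ambiguous = ambiguous)
}

#' Annotate lineage leaves with end-point multiplex measurements
#'
#' Attaches to every leaf track alive at the final frame its matched
#' end-point marker vector and DNA-content class, plus a
#' reference-population summary (median and quartiles per marker over all
#' matched cells). Leaves without an end-point match are annotated
#' lost-at-fixation. Annotating twice replaces the annotation (idempotent).
#'
#' @param forest a `lineage_forest`.
#' @param registration a `round_registration` between the final live frame
#'   and the end-point table.
#' @param endpoint end-point table: `label`, `x`, `y`, `dapi_total` and
#'   marker columns (e.g. pRb, gH2AX, p21, p53).
#' @param gate a [gate_params()].
#' @returns the forest with `$endpoints` (one row per final-frame leaf) and
#'   `$endpoint_summary` added.
#' @export
annotate_lineage_endpoints <- function(forest, registration, endpoint,
                                       gate = gate_params()) {
  if (registration$failed)
    stop("registration failed; cannot annotate", call. = FALSE)
  last_frame <- max(forest$frames)
  leaves <- forest$meta$track[forest$meta$end_frame == last_frame]
  pts <- forest$points
  marker_cols <- setdiff(names(endpoint), c("round", "label", "x", "y"))
  gating <- gate_dna_content(endpoint$dapi_total, gate)
  rows <- NULL
  for (tr in leaves) {
    lab <- pts$label[pts$track == tr & pts$frame == last_frame]
    hit <- registration$matches$endpoint_label[
      registration$matches$live_label == lab]
    if (length(hit) == 1) {
      e <- endpoint[endpoint$label == hit, , drop = FALSE]
      row <- data.frame(track = tr, endpoint_label = hit,
                        lost_at_fixation = FALSE,
                        dna_class = as.character(
                          gating$class[match(hit, endpoint$label)]))
      row <- cbind(row, e[, marker_cols, drop = FALSE])
    } else {
      row <- data.frame(track = tr, endpoint_label = NA_integer_,
                        lost_at_fixation = TRUE, dna_class = NA_character_)
      row[marker_cols] <- NA_real_
    }
    rows <- rbind(rows, row)
  }
  rownames(rows) <- NULL
  matched <- endpoint[endpoint$label %in% registration$matches$endpoint_label, ]
  summ <- do.call(rbind, lapply(marker_cols, function(mc) {
    q <- stats::quantile(matched[[mc]], c(0.25, 0.5, 0.75), na.rm = TRUE)
    data.frame(marker = mc, q1 = q[1], median = q[2], q3 = q[3])
  }))
  rownames(summ) <- NULL
  forest$endpoints <- rows
  forest$endpoint_summary <- summ
  forest$dna_peak <- gating$peak
  forest
}
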