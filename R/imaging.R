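#' Rendering configuration for synthetic two-channel frames
#'
#' Cells are drawn in the PCNA-like channel as smooth super-Gaussian
#' nuclear blobs (radius from the row's nuclear area) carrying the row's
#' PCNA foci count as Gaussian punctae; 53BP1-like punctae go to channel 2.
#'
#' @param width,height frame size in pixels.
#' @param nucleus_amplitude peak nuclear intensity above background (a.u.).
#' @param foci_amplitude peak punctum intensity above the nucleus (a.u.).
#' @param foci_sigma punctum Gaussian sigma in pixels.
#' @param foci_margin punctae are placed within `foci_margin` times the
#'   nuclear radius of the centre.
#' @param foci_min_sep minimum distance between punctae of one nucleus.
#' @param background constant background level (a.u.).
#' @param noise_sd Gaussian read-noise sigma (a.u.); 0 for noiseless.
#' @param overlap_tolerance fraction of summed radii below which two
#'   nuclei are flagged as overlapping in the metadata.
#' @param seed integer seed for punctum placement and noise.
#' @returns object of class `render_config`.
#' @export
render_config <- function(width = 512, height = 512,
                          nucleus_amplitude = 400, foci_amplitude = 1000,
                          foci_sigma = 1.2, foci_margin = 0.6,
                          foci_min_sep = 4, background = 100, noise_sd = 20,
                          overlap_tolerance = 1, seed = 1L) {
  check_positive(c(width, height), "frame size")
  check_positive(nucleus_amplitude, "nucleus_amplitude")
  check_positive(foci_amplitude, "foci_amplitude")
  check_positive(foci_sigma, "foci_sigma")
  check_positive(foci_margin, "foci_margin")
  check_positive(foci_min_sep, "foci_min_sep")
  check_nonneg(background, "background")
  check_nonneg(noise_sd, "noise_sd")
  structure(list(width = as.integer(width), height = as.integer(height),
                 nucleus_amplitude = nucleus_amplitude,
                 foci_amplitude = foci_amplitude, foci_sigma = foci_sigma,
                 foci_margin = foci_margin, foci_min_sep = foci_min_sep,
                 background = background, noise_sd = noise_sd,
                 overlap_tolerance = overlap_tolerance,
                 seed = as.integer(seed)),
            class = "render_config")
}

# add a radially symmetric profile f(r) centred at (cx, cy) (0-based) to img
add_blob <- function(img, cx, cy, radius, fun) {
  h <- nrow(img); w <- ncol(img)
  x0 <- max(1L, floor(cx + 1 - radius)); x1 <- min(w, ceiling(cx + 1 + radius))
  y0 <- max(1L, floor(cy + 1 - radius)); y1 <- min(h, ceiling(cy + 1 + radius))
  if (x0 > x1 || y0 > y1) return(img)
  xs <- x0:x1; ys <- y0:y1
  r <- sqrt(outer((ys - 1 - cy)^2, (xs - 1 - cx)^2, "+"))
  img[ys, xs] <- img[ys, xs] + fun(r)
  img
}

#' Render an observation table into a two-channel image stack
#'
#' @param obs observation table rows (`frame`, `x`, `y`, `area`,
#'   `pcna_foci`, `bp1_foci`); centroids must lie inside the frame.
#' @param render a [render_config()].
#' @returns object of class `image_stack`: list `frames` (per time point a
#'   list with matrices `pcna` and `bp1`, rows = y, columns = x, 0-based
#'   coordinates), `frame_ids`, `render`, `overlap_warnings`.
#' @export
render_frames <- function(obs, render = render_config()) {
  set.seed(render$seed)
  frame_ids <- sort(unique(obs$frame))
  if (nrow(obs)) {
    if (any(obs$x < 0 | obs$x >= render$width |
              obs$y < 0 | obs$y >= render$height))
      stop("centroids outside the rendered field", call. = FALSE)
  }
  overlap <- NULL
  out <- list()
  for (f in if (length(frame_ids)) frame_ids else integer(0)) {
    rows <- obs[obs$frame == f, , drop = FALSE]
    ch1 <- matrix(render$background, render$height, render$width)
    ch2 <- matrix(render$background, render$height, render$width)
    radii <- sqrt(rows$area / pi)
    if (nrow(rows) > 1) {
      d <- as.matrix(stats::dist(cbind(rows$x, rows$y)))
      lim <- outer(radii, radii, "+") * render$overlap_tolerance
      bad <- which(d < lim & upper.tri(d), arr.ind = TRUE)
      if (nrow(bad))
        overlap <- rbind(overlap, data.frame(frame = f, a = bad[, 1],
                                             b = bad[, 2]))
    }
    for (k in seq_len(nrow(rows))) {
      r0 <- radii[k]
      amp <- render$nucleus_amplitude
      ch1 <- add_blob(ch1, rows$x[k], rows$y[k], 2.2 * r0,
                      function(r) amp * exp(-(r / r0)^4))
      place <- function(n_foci) {
        pts <- matrix(numeric(0), 0, 2)
        tries <- 0
        while (nrow(pts) < n_foci && tries < 400) {
          tries <- tries + 1
          ang <- stats::runif(1, 0, 2 * pi)
          rad <- r0 * render$foci_margin * sqrt(stats::runif(1))
          p <- c(rows$x[k] + rad * cos(ang), rows$y[k] + rad * sin(ang))
          if (!nrow(pts) ||
              min(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2)) >=
                render$foci_min_sep)
            pts <- rbind(pts, p)
        }
        pts
      }
      fs <- render$foci_sigma
      fa <- render$foci_amplitude
      if (!is.null(rows$pcna_foci) && rows$pcna_foci[k] > 0) {
        pts <- place(rows$pcna_foci[k])
        for (j in seq_len(nrow(pts)))
          ch1 <- add_blob(ch1, pts[j, 1], pts[j, 2], 5 * fs,
                          function(r) fa * exp(-r^2 / (2 * fs^2)))
      }
      if (!is.null(rows$bp1_foci) && rows$bp1_foci[k] > 0) {
        pts <- place(rows$bp1_foci[k])
        for (j in seq_len(nrow(pts)))
          ch2 <- add_blob(ch2, pts[j, 1], pts[j, 2], 5 * fs,
                          function(r) fa * exp(-r^2 / (2 * fs^2)))
      }
    }
    if (render$noise_sd > 0) {
      ch1 <- ch1 + matrix(stats::rnorm(length(ch1), 0, render$noise_sd),
                          nrow(ch1))
      ch2 <- ch2 + matrix(stats::rnorm(length(ch2), 0, render$noise_sd),
                          nrow(ch2))
    }
    out[[as.character(f)]] <- list(pcna = ch1, bp1 = ch2)
  }
  structure(list(frames = out, frame_ids = frame_ids, render = render,
                 overlap_warnings = overlap),
            class = "image_stack")
}

#' Segmentation parameters
#'
#' @param smoothing_sigma Gaussian sigma (pixels) for the smoothed
#'   segmentation mask of the PCNA channel.
#' @param threshold_method "otsu" or "fixed".
#' @param fixed_threshold absolute threshold when `threshold_method` is
#'   "fixed".
#' @param min_area,max_area object size filter in pixels; objects above
#'   `max_area` (e.g. touching nuclei) are excluded and flagged.
#' @param pixel_area_um2 physical pixel area; 1 pixel is about 0.1056 um^2
#'   on the reference instrument.
#' @returns object of class `segmentation_params`.
#' @export
segmentation_params <- function(smoothing_sigma = 3,
                                threshold_method = c("otsu", "fixed"),
                                fixed_threshold = NULL,
                                min_area = 100, max_area = 5000,
                                pixel_area_um2 = 0.1056) {
  threshold_method <- match.arg(threshold_method)
  check_nonneg(smoothing_sigma, "smoothing_sigma")
  check_positive(min_area, "min_area")
  check_positive(max_area, "max_area")
  if (min_area >= max_area) abort_config("min_area must be < max_area")
  check_positive(pixel_area_um2, "pixel_area_um2")
  if (threshold_method == "fixed" && is.null(fixed_threshold))
    abort_config("fixed_threshold required for threshold_method 'fixed'")
  structure(list(smoothing_sigma = smoothing_sigma,
                 threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 min_area = min_area, max_area = max_area,
                 pixel_area_um2 = pixel_area_um2),
            class = "segmentation_params")
}

#' Segment nuclei on a smoothed PCNA-channel frame
#'
#' Thresholds the Gaussian-smoothed frame (Otsu by default), labels
#' connected components, size-filters them, and measures features on the
#' original non-smoothed signal within each mask: intensity-weighted
#' centroid, area (pixels and um^2), perimeter, circularity
#' (4 pi area / perimeter^2), elongation (major/minor axis of the
#' second-moment ellipse) and per-channel mean/total intensities.
#'
#' @param frame 2-D numeric matrix (rows = y, columns = x), the PCNA
#'   channel.
#' @param params a [segmentation_params()].
#' @param channels optional named list of additional aligned channels for
#'   intensity measurement (e.g. `list(bp1 = <matrix>)`).
#' @returns list: `mask` (integer label matrix), `features` (one row per
#'   kept object: label, x, y, area, area_um2, perimeter, circularity,
#'   elongation, <ch>_mean, <ch>_total), `excluded_labels` (size filter).
#' @export
segment_nuclei <- function(frame, params = segmentation_params(),
                           channels = NULL) {
  if (!is.matrix(frame) || any(!is.finite(frame)))
    stop("frame must be a finite 2-D matrix", call. = FALSE)
  empty <- function(mask) {
    feats <- data.frame(label = integer(), x = numeric(), y = numeric(),
                        area = numeric(), area_um2 = numeric(),
                        perimeter = numeric(), circularity = numeric(),
                        elongation = numeric(),
                        pcna_mean = numeric(), pcna_total = numeric())
    list(mask = mask, features = feats, excluded_labels = integer())
  }
  rng <- range(frame)
  if (diff(rng) == 0) return(empty(matrix(0L, nrow(frame), ncol(frame))))
  sm <- EBImage::gblur(frame, sigma = max(params$smoothing_sigma, 0.01))
  thr <- if (params$threshold_method == "otsu") {
    sm01 <- (sm - min(sm)) / (max(sm) - min(sm))
    min(sm) + EBImage::otsu(EBImage::Image(sm01), range = c(0, 1)) *
      (max(sm) - min(sm))
  } else params$fixed_threshold
  mask <- EBImage::bwlabel(sm > thr)
  mask <- EBImage::imageData(mask)
  if (max(mask) == 0) return(empty(mask))
  sizes <- tabulate(mask[mask > 0])
  keep <- which(sizes >= params$min_area & sizes <= params$max_area)
  excluded <- which(sizes > params$max_area)
  if (!length(keep)) {
    e <- empty(matrix(0L, nrow(frame), ncol(frame)))
    e$excluded_labels <- excluded
    return(e)
  }
  # relabel 1..n in raster order of first occurrence, drop filtered objects
  remap <- integer(max(mask))
  remap[keep] <- seq_along(keep)
  mask2 <- matrix(0L, nrow(mask), ncol(mask))
  nz <- mask > 0
  mask2[nz] <- remap[mask[nz]]
  feats <- NULL
  chans <- c(list(pcna = frame), channels)
  for (lb in seq_along(keep)) {
    sel <- mask2 == lb
    idx <- which(sel, arr.ind = TRUE)
    wts <- frame[sel]
    wts <- wts - min(wts) * 0                     # intensities are a.u. >= 0
    tot_w <- sum(wts)
    cx <- if (tot_w > 0) sum((idx[, 2] - 1) * wts) / tot_w else
      mean(idx[, 2] - 1)
    cy <- if (tot_w > 0) sum((idx[, 1] - 1) * wts) / tot_w else
      mean(idx[, 1] - 1)
    area <- nrow(idx)
    per <- perimeter_length(sel)
    circ <- min(4 * pi * area / per^2, 1)
    elo <- elongation_ratio(idx)
    row <- data.frame(label = lb, x = cx, y = cy, area = area,
                      area_um2 = area * params$pixel_area_um2,
                      perimeter = per, circularity = circ, elongation = elo)
    for (cn in names(chans)) {
      v <- chans[[cn]][sel]
      row[[paste0(cn, "_mean")]] <- mean(v)
      row[[paste0(cn, "_total")]] <- sum(v)
    }
    feats <- rbind(feats, row)
  }
  rownames(feats) <- NULL
  list(mask = mask2, features = feats, excluded_labels = excluded)
}

# perimeter as boundary pixel count (pixels with a 4-neighbour outside),
# which tracks 2*pi*r closely for convex blobs
perimeter_length <- function(sel) {
  up <- rbind(FALSE, sel[-nrow(sel), , drop = FALSE])
  dn <- rbind(sel[-1, , drop = FALSE], FALSE)
  lf <- cbind(FALSE, sel[, -ncol(sel), drop = FALSE])
  rt <- cbind(sel[, -1, drop = FALSE], FALSE)
  sum(sel & !(up & dn & lf & rt))
}

# major/minor axis ratio from second moments of the pixel coordinates
elongation_ratio <- function(idx) {
  if (nrow(idx) < 2) return(1)
  cc <- scale(idx, scale = FALSE)
  cv <- crossprod(cc) / nrow(cc) + diag(1 / 12, 2)  # pixel footprint
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  sqrt(max(ev) / max(min(ev), 1e-12))
}

#' Focus-detection parameters
#'
#' @param background_radius top-hat structuring-element radius (pixels);
#'   signal smoother than this scale is treated as background.
#' @param min_prominence minimum background-subtracted peak height (a.u.),
#'   measured on the matched-filtered image.
#' @param min_separation minimum distance between detected punctae.
#' @param smooth_sigma matched-filter Gaussian sigma applied before peak
#'   detection (suppresses single-pixel noise maxima); 0 disables.
#' @returns object of class `foci_params`.
#' @export
foci_params <- function(background_radius = 5, min_prominence = 100,
                        min_separation = 4, smooth_sigma = 1) {
  check_positive(background_radius, "background_radius")
  check_positive(min_prominence, "min_prominence")
  check_positive(min_separation, "min_separation")
  check_nonneg(smooth_sigma, "smooth_sigma")
  structure(list(background_radius = as.integer(background_radius),
                 min_prominence = min_prominence,
                 min_separation = min_separation,
                 smooth_sigma = smooth_sigma),
            class = "foci_params")
}

#' Detect foci within segmented nuclei
#'
#' White top-hat background subtraction followed by local-maximum
#' detection with prominence and separation gates, restricted to each
#' labelled nucleus. The integrated intensity per cell is the sum of
#' background-subtracted signal over the detected punctae footprints.
#'
#' @param frame 2-D numeric matrix (one channel).
#' @param mask integer label matrix from [segment_nuclei()].
#' @param params a [foci_params()].
#' @returns data frame: `label`, `foci`, `integrated_intensity`.
#' @export
detect_foci <- function(frame, mask, params = foci_params()) {
  stopifnot(all(dim(frame) == dim(mask)))
  labs <- sort(unique(mask[mask > 0]))
  if (!length(labs))
    return(data.frame(label = integer(), foci = integer(),
                      integrated_intensity = numeric()))
  rng <- diff(range(frame))
  if (rng == 0) {
    return(data.frame(label = labs, foci = 0L, integrated_intensity = 0))
  }
  sc <- max(abs(frame))
  fr <- if (params$smooth_sigma > 0)
    EBImage::gblur(frame, sigma = params$smooth_sigma) else frame
  kern <- EBImage::makeBrush(2L * params$background_radius + 1L, "disc")
  th <- EBImage::imageData(EBImage::whiteTopHat(EBImage::Image(fr / sc),
                                                kern)) * sc
  sep <- 2L * ceiling(params$min_separation / 2) + 1L
  mx <- EBImage::imageData(EBImage::dilate(EBImage::Image(th / sc),
                                           EBImage::makeBrush(sep, "disc"))) * sc
  peaks <- which(th >= mx - 1e-9 * sc & th >= params$min_prominence &
                   mask > 0, arr.ind = TRUE)
  # deduplicate plateau peaks closer than min_separation
  if (nrow(peaks) > 1) {
    ord <- order(-th[peaks], peaks[, 1], peaks[, 2])
    peaks <- peaks[ord, , drop = FALSE]
    keep <- rep(TRUE, nrow(peaks))
    for (i in seq_len(nrow(peaks) - 1)) {
      if (!keep[i]) next
      later <- (i + 1):nrow(peaks)
      dd <- sqrt((peaks[later, 1] - peaks[i, 1])^2 +
                   (peaks[later, 2] - peaks[i, 2])^2)
      keep[later[dd < params$min_separation]] <- FALSE
    }
    peaks <- peaks[keep, , drop = FALSE]
  }
  win <- ceiling(params$min_separation / 2)
  out <- data.frame(label = labs, foci = 0L, integrated_intensity = 0)
  for (k in seq_len(nrow(peaks))) {
    lb <- mask[peaks[k, 1], peaks[k, 2]]
    row <- match(lb, out$label)
    out$foci[row] <- out$foci[row] + 1L
    ys <- max(1, peaks[k, 1] - win):min(nrow(th), peaks[k, 1] + win)
    xs <- max(1, peaks[k, 2] - win):min(ncol(th), peaks[k, 2] + win)
    out$integrated_intensity[row] <- out$integrated_intensity[row] +
      sum(th[ys, xs])
  }
  out
}
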