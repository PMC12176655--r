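#' Marker response model for the synthetic end-point panel
#'
#' Defines how end-point staining intensities respond to a cell's true
#' state: integrated DAPI is proportional to true DNA content; gH2AX, p53
#' and p21 increase monotonically with the inherited damage load (53BP1
#' bodies at birth) and with arrest; pRb decreases with both. All signals
#' get multiplicative lognormal noise of the given CV.
#'
#' @param dapi_per_n DAPI a.u. per N of DNA content (default 100).
#' @param noise_cv multiplicative noise CV applied to every signal
#'   (default 0.05; 0 gives a deterministic panel).
#' @param damage_slopes named increments per 53BP1 body at birth for
#'   gH2AX, p53, p21 and (negative) pRb.
#' @param arrest_effects named additive effects applied to arrested cells.
#' @param baselines named baseline intensities.
#' @param offset optional field shift (dx, dy) applied to end-point
#'   centroids, emulating stage repositioning between live imaging and
#'   fixation.
#' @returns object of class `marker_model`.
#' @export
marker_model <- function(dapi_per_n = 100, noise_cv = 0.05,
                         baselines = c(pRb = 1200, gH2AX = 100, p21 = 100,
                                       p53 = 80),
                         damage_slopes = c(pRb = -60, gH2AX = 60, p21 = 40,
                                           p53 = 35),
                         arrest_effects = c(pRb = -800, gH2AX = 50,
                                            p21 = 600, p53 = 150),
                         offset = c(0, 0)) {
  check_positive(dapi_per_n, "dapi_per_n")
  check_nonneg(noise_cv, "noise_cv")
  structure(list(dapi_per_n = dapi_per_n, noise_cv = noise_cv,
                 baselines = baselines, damage_slopes = damage_slopes,
                 arrest_effects = arrest_effects, offset = offset),
            class = "marker_model")
}

#' Simulate an end-point multiplex staining panel
#'
#' Produces one staining-round table for the cells alive at the final
#' frame of a simulated movie: integrated DAPI proportional to true DNA
#' content, and pRb/gH2AX/p21/p53 responding monotonically to the cell's
#' damage and arrest state under the marker model. Centroids are the final
#' live positions plus the model's offset.
#'
#' @param sim result of [simulate_lineages()].
#' @param model a [marker_model()].
#' @param seed integer seed (defaults to the movie seed + 1).
#' @returns data frame: `round`, `label`, `x`, `y`, `dapi_total`, `pRb`,
#'   `gH2AX`, `p21`, `p53`; `label` matches the final live frame labels
#'   before the offset is applied.
#' @export
simulate_endpoint_panel <- function(sim, model = marker_model(),
                                    seed = NULL) {
  truth <- sim$truth
  set.seed(seed %||% (truth$config$seed + 1L))
  last_frame <- truth$n_frames - 1L
  fin <- sim$obs[sim$obs$frame == last_frame, , drop = FALSE]
  if (!nrow(fin)) stop("truth does not cover the final frame", call. = FALSE)
  map <- truth$obs_map[truth$obs_map$frame == last_frame, , drop = FALSE]
  cellid <- map$cell[match(fin$label, map$label)]
  dna <- truth$phases$dna[truth$phases$frame == last_frame][
    match(cellid, truth$phases$cell[truth$phases$frame == last_frame])]
  cinfo <- truth$cells[match(cellid, truth$cells$cell), ]
  damage <- cinfo$bp1_birth
  arrested <- cinfo$fate == "arrest"

  noise <- function(n) {
    if (model$noise_cv == 0) rep(1, n)
    else rlnorm_mean_cv(n, 1, model$noise_cv)
  }
  n <- nrow(fin)
  mk <- function(name) {
    v <- model$baselines[[name]] + model$damage_slopes[[name]] * damage +
      ifelse(arrested, model$arrest_effects[[name]], 0)
    pmax(v, 10) * noise(n)
  }
  data.frame(round = 1L, label = fin$label,
             x = fin$x + model$offset[1], y = fin$y + model$offset[2],
             dapi_total = model$dapi_per_n * dna * noise(n),
             pRb = mk("pRb"), gH2AX = mk("gH2AX"),
             p21 = mk("p21"), p53 = mk("p53"))
}
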