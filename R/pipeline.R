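#' Default run configuration
#'
#' A nested list with one block per pipeline stage, suitable for
#' [run_pipeline()] and for YAML round-tripping. Every block maps onto a
#' parameter constructor: `sim` to [sim_config()], `link` to
#' [link_params()], `staging` to [staging_thresholds()], `route` to
#' [route_params()], `gate` to [gate_params()], `hetero$scheme` to
#' [hetero_thresholds()], `counts` to [count_sim_config()],
#' `normalization` to [normalization_params()].
#'
#' @param seed global seed.
#' @returns nested configuration list.
#' @export
default_run_config <- function(seed = 1L) {
  list(seed = as.integer(seed),
       sim = list(n_founders = 20, duration = 55, frame_interval = 30,
                  motion_sigma = 3),
       link = list(),
       staging = list(),
       route = list(),
       gate = list(),
       hetero = list(scheme = "replication_stress", bp1_summary = "max"),
       counts = list(),
       normalization = list())
}

#' Run the integrated analysis pipeline on synthetic data
#'
#' Executes simulate -> track -> stage -> end-point annotation -> sister
#' heterogeneity on one configuration, writing every artifact (CSV/JSON/
#' Newick) plus a provenance record to `outdir`. All randomness derives
#' from `config$seed`, so a rerun with the same configuration is
#' byte-identical.
#'
#' @param config nested list as from [default_run_config()].
#' @param outdir output directory (created if needed).
#' @returns invisibly, a list with the in-memory stage results and
#'   `artifacts` (named file paths).
#' @export
run_pipeline <- function(config = default_run_config(), outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(outdir, f)
  artifacts <- c()
  seed <- config$seed %||% 1L

  # simulate
  cfg <- do.call(sim_config, c(config$sim %||% list(), list(seed = seed)))
  sim <- simulate_lineages(cfg)
  write_observation_table(sim$obs, pth("observations.csv"))
  artifacts["observations"] <- pth("observations.csv")

  # track
  lp <- do.call(link_params, config$link %||% list())
  tracks <- track_cells(sim$obs, lp)
  divisions <- detect_divisions(tracks, lp)
  forest <- build_lineages(tracks, divisions)

  # stage
  th <- do.call(staging_thresholds,
                c(config$staging %||% list(),
                  list(frame_interval = cfg$frame_interval)))
  traces <- stage_tracks(forest, th)
  rp <- do.call(route_params, config$route %||% list())
  seg_rows <- NULL
  route_rows <- NULL
  for (id in names(traces)) {
    tr <- traces[[id]]
    seg <- tr$segments
    seg_rows <- rbind(seg_rows,
                      data.frame(track = as.integer(id), phase = seg$phase,
                                 start = seg$start, end = seg$end,
                                 duration_h = seg$duration_h))
    foci <- forest$points$pcna_foci[forest$points$track == as.integer(id)]
    div_at <- if (as.integer(id) %in% forest$divisions$parent)
      length(tr$labels) else integer(0)
    rc <- classify_ploidy_route(tr, division_frames = div_at, params = rp,
                                foci = foci)
    route_rows <- rbind(route_rows,
                        data.frame(track = as.integer(id), route = rc$route,
                                   n_s_segments = rc$evidence$n_s_segments,
                                   n_divisions = rc$evidence$n_divisions))
  }
  utils::write.csv(seg_rows, pth("phase_segments.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(route_rows, pth("ploidy_routes.csv"), row.names = FALSE,
                   quote = FALSE)
  artifacts["phase_segments"] <- pth("phase_segments.csv")
  artifacts["ploidy_routes"] <- pth("ploidy_routes.csv")

  # qibc: end-point panel, registration, annotation
  ep <- simulate_endpoint_panel(sim)
  write_endpoint_table(ep, pth("endpoint.csv"))
  artifacts["endpoint"] <- pth("endpoint.csv")
  last_frame <- max(forest$frames)
  live <- sim$obs[sim$obs$frame == last_frame, c("label", "x", "y")]
  reg <- register_rounds(live, ep)
  gp <- do.call(gate_params, config$gate %||% list())
  forest <- annotate_lineage_endpoints(forest, reg, ep, gp)
  qc <- list(registration = list(failed = reg$failed,
                                 translation = unname(reg$translation),
                                 n_matched = nrow(reg$matches),
                                 n_unmatched_live = length(reg$unmatched_live),
                                 n_unmatched_endpoint =
                                   length(reg$unmatched_endpoint)))
  jsonlite::write_json(qc, pth("qc.json"), auto_unbox = TRUE, digits = NA)
  artifacts["qc"] <- pth("qc.json")
  write_lineage_json(forest, pth("lineage.json"))
  writeLines(forest_to_newick(forest, cfg$frame_interval),
             pth("lineage.nwk"))
  artifacts["lineage"] <- pth("lineage.json")
  artifacts["newick"] <- pth("lineage.nwk")

  # sister heterogeneity (live 53BP1 marker)
  hcfg <- config$hetero %||% list(scheme = "replication_stress")
  hth <- hetero_thresholds(hcfg$scheme)
  sp <- score_sister_pairs(forest, "bp1", hth,
                           bp1_summary = hcfg$bp1_summary %||% "max")
  utils::write.csv(sp$records, pth("sister_pairs.csv"), row.names = FALSE,
                   quote = FALSE)
  artifacts["sister_pairs"] <- pth("sister_pairs.csv")

  # provenance
  write_run_config(config, pth("config.yaml"))
  ver <- tryCatch(as.character(utils::packageVersion("liveqibc")),
                  error = function(e) "dev")
  prov <- list(package = "liveqibc",
               version = ver,
               seed = seed,
               config_md5 = unname(tools::md5sum(pth("config.yaml"))),
               artifacts = as.list(stats::setNames(basename(artifacts),
                                                   names(artifacts))))
  jsonlite::write_json(prov, pth("provenance.json"), auto_unbox = TRUE)
  artifacts["config"] <- pth("config.yaml")
  artifacts["provenance"] <- pth("provenance.json")

  invisible(list(sim = sim, tracks = tracks, divisions = divisions,
                 forest = forest, traces = traces, routes = route_rows,
                 registration = reg, sister_pairs = sp,
                 artifacts = artifacts))
}
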