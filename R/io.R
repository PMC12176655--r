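#' @name formats
#' @title File formats
#'
#' @description
#' Fixed interchange formats: observation and end-point tables as
#' comma-separated UTF-8 CSV with a mandatory header, "." decimal, times
#' in minutes-derived hours, coordinates in pixels, frames 0-based (time
#' of frame f is f * frame_interval); lineage forests as JSON and as
#' annotated Newick (node labels carry track ids); count matrices as
#' MatrixMarket MTX plus gene/cell lists or as dense CSV; gene sets as
#' one-symbol-per-line text; configurations as YAML.
NULL

OBS_COLUMNS <- c("frame", "time_h", "well", "position", "label", "x", "y",
                 "area", "area_um2", "ch1_mean", "ch1_total", "ch2_mean",
                 "ch2_total", "pcna_foci", "bp1_foci", "pcna_foci_int",
                 "bp1_foci_int")
OBS_NUMERIC <- setdiff(OBS_COLUMNS, "well")

ENDPOINT_COLUMNS <- c("round", "label", "x", "y", "dapi_total")

check_schema <- function(df, required, numeric_cols, path) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  for (cc in intersect(numeric_cols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !is.na(df[[cc]]) & df[[cc]] != "NA")
    if (length(bad))
      stop(sprintf("%s: line %d, field '%s': not numeric (%s)", path,
                   bad[1] + 1L, cc, df[[cc]][bad[1]]), call. = FALSE)
    df[[cc]] <- v
  }
  df
}

#' Write / read an observation table
#'
#' @param obs observation table data frame.
#' @param path CSV file path.
#' @returns `read_observation_table` returns the validated data frame.
#' @export
write_observation_table <- function(obs, path) {
  stopifnot(all(OBS_COLUMNS %in% names(obs)))
  utils::write.csv(obs[, OBS_COLUMNS], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_observation_table
#' @export
read_observation_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  df <- check_schema(df, OBS_COLUMNS, OBS_NUMERIC, path)
  for (cc in c("frame", "position", "label", "pcna_foci", "bp1_foci"))
    df[[cc]] <- as.integer(df[[cc]])
  df
}

#' Write / read an end-point staining table
#'
#' @param endpoint end-point table (round, label, x, y, dapi_total plus
#'   marker columns).
#' @param path CSV file path.
#' @returns `read_endpoint_table` returns the validated data frame.
#' @export
write_endpoint_table <- function(endpoint, path) {
  stopifnot(all(ENDPOINT_COLUMNS %in% names(endpoint)))
  utils::write.csv(endpoint, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_endpoint_table
#' @export
read_endpoint_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  df <- check_schema(df, ENDPOINT_COLUMNS,
                     setdiff(names(df), character(0)), path)
  df$round <- as.integer(df$round)
  df$label <- as.integer(df$label)
  df
}

#' Write / read a lineage forest as JSON
#'
#' The JSON document carries the track metadata, division events, edges,
#' per-observation points and curation log; reading restores a
#' `lineage_forest`.
#'
#' @param forest a `lineage_forest`.
#' @param path JSON file path.
#' @returns `read_lineage_json` returns the restored `lineage_forest`.
#' @export
write_lineage_json <- function(forest, path) {
  doc <- list(schema = "liveqibc-lineage-v1",
              frames = forest$frames,
              meta = forest$meta,
              edges = forest$edges,
              divisions = forest$divisions,
              points = forest$points,
              endpoints = forest$endpoints,
              endpoint_summary = forest$endpoint_summary)
  jsonlite::write_json(doc, path, dataframe = "columns", digits = NA,
                       na = "null", auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_lineage_json
#' @export
read_lineage_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, "liveqibc-lineage-v1"))
    stop(sprintf("%s: not a liveqibc lineage document", path), call. = FALSE)
  as_df <- function(x) if (is.null(x) || !length(x)) NULL else
    as.data.frame(x, stringsAsFactors = FALSE)
  structure(list(points = as_df(doc$points), meta = as_df(doc$meta),
                 edges = as_df(doc$edges) %||%
                   data.frame(parent = integer(), daughter = integer()),
                 divisions = as_df(doc$divisions) %||% empty_divisions(),
                 frames = doc$frames,
                 endpoints = as_df(doc$endpoints),
                 endpoint_summary = as_df(doc$endpoint_summary),
                 curation_log = list()),
            class = "lineage_forest")
}

#' Export a lineage forest as annotated Newick strings
#'
#' One Newick string per tree; node labels are `t<track id>` and branch
#' lengths are track durations in hours.
#'
#' @param forest a `lineage_forest`.
#' @param frame_interval minutes per frame for branch lengths.
#' @returns character vector of Newick strings (named by root track).
#' @export
forest_to_newick <- function(forest, frame_interval = 30) {
  meta <- forest$meta
  div <- forest$divisions
  len <- (meta$end_frame - meta$start_frame + 1) * frame_interval / 60
  names(len) <- meta$track
  kids <- function(tr) {
    k <- div[div$parent == tr, c("daughter1", "daughter2")]
    if (!nrow(k)) integer(0) else
      sort(stats::na.omit(c(k$daughter1[1], k$daughter2[1])))
  }
  nwk <- function(tr) {
    ch <- kids(tr)
    lab <- sprintf("t%d:%g", tr, len[as.character(tr)])
    if (!length(ch)) lab
    else sprintf("(%s)%s", paste(vapply(ch, nwk, character(1)),
                                 collapse = ","), lab)
  }
  roots <- meta$track[is.na(meta$parent)]
  out <- vapply(roots, function(r) paste0(nwk(r), ";"), character(1))
  names(out) <- paste0("t", roots)
  out
}

#' Parse annotated Newick strings back to a lineage edge table
#'
#' @param newick character vector of Newick strings from
#'   [forest_to_newick()].
#' @returns data frame `parent`, `daughter` (track ids).
#' @export
newick_to_edges <- function(newick) {
  out <- NULL
  for (s in newick) {
    tr <- ape::read.tree(text = s)
    ids <- function(lbl) as.integer(sub("^t", "", lbl))
    labs <- c(ids(tr$tip.label),
              if (!is.null(tr$node.label)) ids(tr$node.label) else integer(0))
    if (!is.null(tr$edge)) {
      e <- tr$edge
      out <- rbind(out, data.frame(parent = labs[e[, 1]],
                                   daughter = labs[e[, 2]]))
    }
  }
  if (is.null(out)) data.frame(parent = integer(), daughter = integer())
  else out[order(out$parent, out$daughter), , drop = FALSE]
}

#' Write / read a count matrix as MatrixMarket MTX plus gene/cell lists
#'
#' @param counts genes x cells matrix.
#' @param prefix path prefix; writes `<prefix>.mtx`, `<prefix>.genes.tsv`,
#'   `<prefix>.cells.tsv`.
#' @returns `read_counts_mtx` returns the dense integer matrix with
#'   dimnames.
#' @export
write_counts_mtx <- function(counts, prefix) {
  m <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(m, paste0(prefix, ".mtx"))
  writeLines(rownames(counts) %||% as.character(seq_len(nrow(counts))),
             paste0(prefix, ".genes.tsv"))
  writeLines(colnames(counts) %||% as.character(seq_len(ncol(counts))),
             paste0(prefix, ".cells.tsv"))
  invisible(prefix)
}

#' @rdname write_counts_mtx
#' @export
read_counts_mtx <- function(prefix) {
  m <- as.matrix(Matrix::readMM(paste0(prefix, ".mtx")))
  storage.mode(m) <- "integer"
  dimnames(m) <- list(readLines(paste0(prefix, ".genes.tsv")),
                      readLines(paste0(prefix, ".cells.tsv")))
  m
}

#' Write / read a dense count matrix as CSV
#'
#' @param counts genes x cells matrix.
#' @param path CSV path (genes in rows, first column = gene name).
#' @returns `read_counts_csv` returns the matrix.
#' @export
write_counts_csv <- function(counts, path) {
  utils::write.csv(as.data.frame(counts), path, row.names = TRUE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_counts_csv
#' @export
read_counts_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}

#' Write / read a gene set as one-symbol-per-line text
#'
#' @param genes character vector.
#' @param path text file path.
#' @returns `read_gene_set` returns the character vector.
#' @export
write_gene_set <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

#' @rdname write_gene_set
#' @export
read_gene_set <- function(path) readLines(path)

#' Write / read a run configuration as YAML
#'
#' @param config nested list of parameter blocks (see [run_pipeline()]).
#' @param path YAML path.
#' @returns `read_run_config` returns the list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) yaml::read_yaml(path)

#' Write / read a two-channel image stack as multi-page TIFF
#'
#' One file per channel (`<prefix>_pcna.tif`, `<prefix>_bp1.tif`), 32-bit
#' float pages in frame order; intensities are divided by `scale` on write
#' and restored on read. Requires the suggested `tiff` package.
#'
#' @param stack an `image_stack` from [render_frames()].
#' @param prefix output path prefix.
#' @param scale intensity scale mapping a.u. to [0, 1] in the file.
#' @returns `read_image_stack` returns a list of per-frame two-channel
#'   lists.
#' @export
write_image_stack <- function(stack, prefix, scale = 65535) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF export", call. = FALSE)
  for (ch in c("pcna", "bp1")) {
    pages <- lapply(stack$frames, function(fr) fr[[ch]] / scale)
    tiff::writeTIFF(pages, sprintf("%s_%s.tif", prefix, ch),
                    bits.per.sample = 32L)
  }
  invisible(prefix)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(prefix, scale = 65535) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF import", call. = FALSE)
  chans <- lapply(c(pcna = "pcna", bp1 = "bp1"), function(ch) {
    pgs <- tiff::readTIFF(sprintf("%s_%s.tif", prefix, ch), all = TRUE)
    lapply(pgs, function(p) p * scale)
  })
  lapply(seq_along(chans$pcna), function(i)
    list(pcna = chans$pcna[[i]], bp1 = chans$bp1[[i]]))
}
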