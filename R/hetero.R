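#' Categorical thresholds for sister-cell heterogeneity
#'
#' Two published threshold schemes ship as named presets; because the
#' cutoffs are experiment-dependent, the scheme must always be chosen
#' explicitly. Each marker has a pair (low_max, med_max): an absolute
#' sister difference d is "low" when d <= low_max, "medium" when
#' low_max < d <= med_max, and "high" when d > med_max (interval bounds
#' are closed on the lower category).
#'
#' Preset `"replication_stress"` (APH/ATRi-type experiments):
#' 53BP1 foci (1, 4); gH2AX (100, 200); p53 (50, 100); p21 (100, 500) a.u.
#' Preset `"irradiation"` (IR-in-G1-type experiments):
#' 53BP1 foci (1, 4); gH2AX (50, 100); p53 (200, 500); pRb (500, 1000) a.u.
#'
#' @param scheme "replication_stress", "irradiation", or "custom".
#' @param custom for scheme "custom": named list of c(low_max, med_max)
#'   per marker.
#' @returns object of class `hetero_thresholds`.
#' @export
hetero_thresholds <- function(scheme = c("replication_stress", "irradiation",
                                         "custom"),
                              custom = NULL) {
  if (missing(scheme))
    abort_config("a heterogeneity threshold scheme must be chosen explicitly")
  scheme <- match.arg(scheme)
  th <- switch(scheme,
    replication_stress = list(bp1 = c(1, 4), gH2AX = c(100, 200),
                              p53 = c(50, 100), p21 = c(100, 500)),
    irradiation = list(bp1 = c(1, 4), gH2AX = c(50, 100),
                       p53 = c(200, 500), pRb = c(500, 1000)),
    custom = custom)
  if (is.null(th) || !length(th))
    abort_config("scheme 'custom' requires a named 'custom' threshold list")
  for (m in names(th)) {
    v <- th[[m]]
    if (length(v) != 2 || any(v < 0) || v[1] >= v[2])
      abort_config("marker '%s': thresholds must be c(low_max, med_max) with low_max < med_max", m)
  }
  structure(list(scheme = scheme, markers = th), class = "hetero_thresholds")
}

#' Enumerate sister-cell pairs from a lineage forest
#'
#' One pair per division event, tagged with the daughters' generation.
#'
#' @param forest a `lineage_forest`.
#' @returns data frame: `pair`, `tree`, `parent`, `sister_a`, `sister_b`,
#'   `generation` (of the daughters).
#' @export
pair_sisters <- function(forest) {
  div <- forest$divisions
  if (!nrow(div))
    return(data.frame(pair = integer(), tree = integer(), parent = integer(),
                      sister_a = integer(), sister_b = integer(),
                      generation = character()))
  meta <- forest$meta
  data.frame(pair = seq_len(nrow(div)),
             tree = meta$tree[match(div$parent, meta$track)],
             parent = div$parent,
             sister_a = div$daughter1, sister_b = div$daughter2,
             generation = meta$generation[match(div$daughter1, meta$track)])
}

#' Score one sister pair's heterogeneity for a marker
#'
#' @param value_a,value_b the two sisters' marker values (foci counts or
#'   intensities on the marker's scale).
#' @param marker marker name present in the active threshold scheme.
#' @param th a [hetero_thresholds()].
#' @returns list: `marker`, `value_a`, `value_b`, `difference`, `category`
#'   ("low", "medium" or "high").
#' @export
score_pair <- function(value_a, value_b, marker, th) {
  stopifnot(inherits(th, "hetero_thresholds"))
  if (!marker %in% names(th$markers))
    abort_config("marker '%s' not in scheme '%s'", marker, th$scheme)
  b <- th$markers[[marker]]
  d <- abs(value_a - value_b)
  category <- ifelse(d <= b[1], "low", ifelse(d <= b[2], "medium", "high"))
  list(marker = marker, value_a = value_a, value_b = value_b,
       difference = d, category = category)
}

#' Score all sister pairs of a forest for one marker
#'
#' For the 53BP1 foci marker the per-daughter summary of the live trace is
#' differenced (maximum by default); for end-point markers the annotated
#' end-point values are used. Pairs with a sister missing the value are
#' excluded and counted.
#'
#' @param forest an annotated `lineage_forest` (see
#'   [annotate_lineage_endpoints()]) or any forest for the live bp1 marker.
#' @param marker one of the scheme's markers; `"bp1"` uses live imaging
#'   `bp1_foci`, others use `forest$endpoints`.
#' @param th a [hetero_thresholds()].
#' @param bp1_summary how to summarise a daughter's live 53BP1 trace:
#'   "max" (default), "mean" or "birth".
#' @param generation optionally restrict pairs to one generation label
#'   (e.g. "F1").
#' @returns list: `records` (one row per scored pair), `n_excluded`.
#' @export
score_sister_pairs <- function(forest, marker, th, bp1_summary = "max",
                               generation = NULL) {
  pairs <- pair_sisters(forest)
  if (!is.null(generation))
    pairs <- pairs[pairs$generation %in% generation, , drop = FALSE]
  value_of <- function(tr) {
    if (marker == "bp1") {
      v <- forest$points$bp1_foci[forest$points$track == tr]
      if (!length(v)) return(NA_real_)
      switch(bp1_summary, max = max(v), mean = mean(v), birth = v[1],
             abort_config("unknown bp1_summary '%s'", bp1_summary))
    } else {
      ep <- forest$endpoints
      if (is.null(ep)) abort_config("forest has no endpoint annotation")
      v <- ep[[marker]][match(tr, ep$track)]
      if (length(v) != 1) NA_real_ else v
    }
  }
  rec <- NULL
  n_excluded <- 0L
  for (k in seq_len(nrow(pairs))) {
    va <- value_of(pairs$sister_a[k])
    vb <- value_of(pairs$sister_b[k])
    if (is.na(va) || is.na(vb)) {
      n_excluded <- n_excluded + 1L
      next
    }
    s <- score_pair(va, vb, marker, th)
    rec <- rbind(rec, data.frame(pair = pairs$pair[k], tree = pairs$tree[k],
                                 generation = pairs$generation[k],
                                 marker = marker, value_a = va, value_b = vb,
                                 difference = s$difference,
                                 category = s$category))
  }
  if (is.null(rec))
    rec <- data.frame(pair = integer(), tree = integer(),
                      generation = character(), marker = character(),
                      value_a = numeric(), value_b = numeric(),
                      difference = numeric(), category = character())
  list(records = rec, n_excluded = n_excluded)
}

#' Compare heterogeneity category distributions across conditions
#'
#' Builds the categories-by-conditions contingency table and tests
#' homogeneity with Pearson's chi-square; when any expected count is zero
#' the test switches to Fisher's exact test with a warning. A 2x2 collapse
#' (low vs medium+high) with Fisher's exact test is also reported when
#' exactly two conditions are given.
#'
#' @param ... named character vectors (or factors) of per-pair categories,
#'   one argument per condition; or a single named list of such vectors.
#' @returns list: `table`, `chisq` (htest), `fisher_2x2` (htest or NULL),
#'   `method`.
#' @export
compare_conditions <- function(...) {
  args <- list(...)
  if (length(args) == 1 && is.list(args[[1]]) && !is.data.frame(args[[1]]))
    args <- args[[1]]
  if (length(args) < 2)
    abort_config("need at least two conditions")
  lv <- c("low", "medium", "high")
  tab <- vapply(args, function(v) table(factor(v, levels = lv)),
                numeric(length(lv)))
  dimnames(tab) <- list(category = lv, condition = names(args))
  keep <- rowSums(tab) > 0
  tt <- tab[keep, , drop = FALSE]
  method <- "chisq"
  exp_counts <- outer(rowSums(tt), colSums(tt)) / sum(tt)
  if (any(exp_counts == 0)) {
    warning("zero expected counts; using Fisher's exact test", call. = FALSE)
    test <- stats::fisher.test(tt)
    method <- "fisher"
  } else {
    test <- suppressWarnings(stats::chisq.test(tt, correct = FALSE))
  }
  fisher22 <- NULL
  if (ncol(tab) == 2) {
    coll <- rbind(low = tab["low", ],
                  not_low = colSums(tab[c("medium", "high"), , drop = FALSE]))
    if (all(rowSums(coll) > 0))
      fisher22 <- stats::fisher.test(coll)
  }
  list(table = tab, test = test, method = method, fisher_2x2 = fisher22)
}
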