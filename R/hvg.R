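#' Normalization parameters for UMI counts
#'
#' Log-normalization in the standard single-cell convention: each count is
#' divided by its cell's total, multiplied by a scale factor, incremented
#' by a pseudocount and natural-log transformed.
#'
#' @param scale_factor counts scale (default 10,000).
#' @param pseudocount added before the log (default 1).
#' @returns object of class `normalization_params`.
#' @export
normalization_params <- function(scale_factor = 10000, pseudocount = 1) {
  check_positive(scale_factor, "scale_factor")
  check_positive(pseudocount, "pseudocount")
  structure(list(scale_factor = scale_factor, pseudocount = pseudocount,
                 log_base = "natural"),
            class = "normalization_params")
}

#' Log-normalize a UMI count matrix
#'
#' value = log(pseudocount + scale_factor * count / cell_total), natural
#' log. Cells with zero total counts are excluded and reported.
#'
#' @param counts genes x cells matrix of non-negative integer counts.
#' @param p a [normalization_params()].
#' @returns list: `normalized` (genes x kept-cells matrix),
#'   `dropped_cells` (names/indices of zero-total cells), `params`.
#' @export
normalize_counts <- function(counts, p = normalization_params()) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  totals <- colSums(counts)
  zero <- totals == 0
  dropped <- if (is.null(colnames(counts))) which(zero) else
    colnames(counts)[zero]
  keep <- counts[, !zero, drop = FALSE]
  totals <- totals[!zero]
  normalized <- log(p$pseudocount +
                      p$scale_factor * sweep(keep, 2, totals, "/"))
  list(normalized = normalized, dropped_cells = dropped, params = p)
}

#' Detect highly variable genes by mean-variance residuals
#'
#' Computes per-gene mean and standard deviation of normalized expression,
#' fits log2(s.d.) on log2(mean) by ordinary least squares over evaluable
#' genes (positive mean and s.d.), and flags genes whose residual exceeds
#' the cutoff (strictly). Genes expressed in no cell or with zero variance
#' are non-evaluable and never flagged.
#'
#' @param normalized genes x cells matrix of normalized expression.
#' @param residual_cutoff residual above which a gene is highly variable
#'   (default 0.5).
#' @returns object of class `hvg_fit`: data frame `genes` (mean, sd,
#'   log2_mean, log2_sd, fitted, residual, evaluable, hvg), `coef`
#'   (intercept, slope), `residual_cutoff`.
#' @export
fit_residuals <- function(normalized, residual_cutoff = 0.5) {
  mu <- rowMeans(normalized)
  sd_ <- apply(normalized, 1, stats::sd)
  evaluable <- mu > 0 & sd_ > 0
  if (sum(evaluable) < 2)
    stop("need at least 2 evaluable genes for the fit", call. = FALSE)
  lm_ <- log2(mu[evaluable])
  ls_ <- log2(sd_[evaluable])
  if (stats::sd(lm_) == 0)
    stop("degenerate fit: all gene means identical", call. = FALSE)
  fit <- stats::lm(ls_ ~ lm_)
  co <- stats::coef(fit)
  genes <- data.frame(
    gene = rownames(normalized) %||% seq_len(nrow(normalized)),
    mean = mu, sd = sd_,
    log2_mean = ifelse(evaluable, log2(mu), NA_real_),
    log2_sd = ifelse(evaluable, log2(sd_), NA_real_),
    evaluable = evaluable)
  genes$fitted <- ifelse(evaluable, co[1] + co[2] * genes$log2_mean, NA_real_)
  genes$residual <- genes$log2_sd - genes$fitted
  genes$hvg <- !is.na(genes$residual) & genes$residual > residual_cutoff
  rownames(genes) <- NULL
  structure(list(genes = genes,
                 coef = c(intercept = unname(co[1]), slope = unname(co[2])),
                 residual_cutoff = residual_cutoff),
            class = "hvg_fit")
}

#' @export
print.hvg_fit <- function(x, ...) {
  g <- x$genes
  cat(sprintf("HVG fit: %d genes (%d evaluable), log2(sd) = %.3f + %.3f * log2(mean)\n",
              nrow(g), sum(g$evaluable), x$coef[1], x$coef[2]))
  cat(sprintf("  %d highly variable (residual > %g)\n",
              sum(g$hvg), x$residual_cutoff))
  invisible(x)
}

# two-sided Fisher exact p for a 2x2 table by full hypergeometric
# enumeration over all tables with the observed margins
fisher_p_enum <- function(a, b, c, d) {
  m <- a + b          # row 1
  n <- c + d          # row 2
  k <- a + c          # col 1
  lo <- max(0L, k - n)
  hi <- min(k, m)
  xs <- lo:hi
  logp <- lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  p_obs <- pr[xs == a]
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

#' Gene-set enrichment among highly variable genes
#'
#' Builds the 2x2 table of HVG status against gene-set membership over the
#' evaluable gene universe and computes the two-sided Fisher exact p-value
#' by hypergeometric enumeration, the sample odds ratio (ad/bc), and a
#' Woolf logit 95% confidence interval (with a 0.5 continuity correction
#' when any cell is zero, flagged).
#'
#' @param hvg_flags logical vector over the gene universe.
#' @param in_set logical vector of gene-set membership, same length/order.
#' @returns object of class `enrichment_result`: `table`, `odds_ratio`,
#'   `p_value`, `ci` (95% for the OR), `continuity_corrected`, `note`.
#' @export
enrichment_test <- function(hvg_flags, in_set) {
  if (length(hvg_flags) != length(in_set))
    stop("flag and membership vectors differ in length", call. = FALSE)
  a <- sum(hvg_flags & in_set)
  b <- sum(hvg_flags & !in_set)
  c <- sum(!hvg_flags & in_set)
  d <- sum(!hvg_flags & !in_set)
  tab <- matrix(c(a, c, b, d), 2, 2,
                dimnames = list(hvg = c("yes", "no"),
                                in_set = c("yes", "no")))
  note <- NULL
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) {
    return(structure(list(table = tab, odds_ratio = NA_real_,
                          p_value = 1, ci = c(NA_real_, NA_real_),
                          continuity_corrected = FALSE,
                          note = "empty margin: odds ratio undefined"),
                     class = "enrichment_result"))
  }
  p <- fisher_p_enum(a, b, c, d)
  cc <- a == 0 || b == 0 || c == 0 || d == 0
  if (cc) {
    aa <- a + 0.5; bb <- b + 0.5; cc_ <- c + 0.5; dd <- d + 0.5
    note <- "0.5 added to all cells (zero cell)"
  } else {
    aa <- a; bb <- b; cc_ <- c; dd <- d
  }
  or <- (aa * dd) / (bb * cc_)
  se <- sqrt(1 / aa + 1 / bb + 1 / cc_ + 1 / dd)
  ci <- exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se)
  structure(list(table = tab, odds_ratio = or, p_value = p, ci = ci,
                 continuity_corrected = cc, note = note),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  print(x$table)
  cat(sprintf("odds ratio %.3f (95%% CI %.3f-%.3f), two-sided exact p = %.3g\n",
              x$odds_ratio, x$ci[1], x$ci[2], x$p_value))
  if (!is.null(x$note)) cat(" note:", x$note, "\n")
  invisible(x)
}

#' Compare highly variable genes between two conditions
#'
#' Set algebra over the HVG flags of two independently fitted conditions:
#' per-condition counts, the intersection, and the genes variable only in
#' condition B (the set used for downstream annotation).
#'
#' @param fit_a,fit_b `hvg_fit` objects for conditions A and B over the
#'   same gene universe.
#' @returns list: `n_a`, `n_b`, `overlap` (gene names), `only_a`, `only_b`.
#' @export
compare_variability <- function(fit_a, fit_b) {
  ga <- fit_a$genes
  gb <- fit_b$genes
  if (!identical(as.character(ga$gene), as.character(gb$gene))) {
    mism <- union(setdiff(ga$gene, gb$gene), setdiff(gb$gene, ga$gene))
    stop(sprintf("gene universes differ (%d mismatches): %s%s",
                 length(mism), paste(utils::head(mism, 5), collapse = ", "),
                 if (length(mism) > 5) ", ..." else ""), call. = FALSE)
  }
  A <- ga$gene[ga$hvg]
  B <- gb$gene[gb$hvg]
  list(n_a = length(A), n_b = length(B),
       overlap = intersect(A, B),
       only_a = setdiff(A, B), only_b = setdiff(B, A))
}
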