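#' geNorm expression-stability measure M
#'
#' For each candidate reference j, `M_j` is the mean over all other
#' candidates k of the standard deviation across subjects of the pairwise
#' log-ratio `log2(x_j) - log2(x_k)`. Perfectly co-regulated candidates
#' (constant ratio) score 0; lower M means a more stable reference.
#'
#' @param log_expr numeric matrix, subjects x candidates, log2 expression
#'   (column names are candidate ids).
#' @return Named numeric vector of M scores.
#' @export
genorm_m <- function(log_expr) {
  log_expr <- as.matrix(log_expr)
  p <- ncol(log_expr)
  if (p < 2L) stop_invalid("geNorm needs >= 2 candidates")
  m <- numeric(p)
  for (j in seq_len(p)) {
    sds <- vapply(seq_len(p)[-j], function(k)
      stats::sd(log_expr[, j] - log_expr[, k]), 0)
    m[j] <- mean(sds)
  }
  stats::setNames(m, colnames(log_expr))
}

#' NormFinder stability value
#'
#' Model-based stability from the NormFinder variance-components
#' construction. Without groups it reduces to the per-candidate variance of
#' the doubly centered residuals `x_ij - rowmean_i - colmean_j + grandmean`
#' (unbiased, with a small-sample correction factor `n/(n-1)` dropped in the
#' ungrouped case in favor of the plain residual variance). With a grouping
#' factor, stability combines the intra-group residual variance with the
#' inter-group bias of the candidate's group-specific level; in both cases
#' lower is more stable.
#'
#' @param log_expr numeric matrix, subjects x candidates (>= 3 candidates).
#' @param groups optional factor of length `nrow(log_expr)`.
#' @return Named numeric vector of stability values.
#' @export
normfinder_stability <- function(log_expr, groups = NULL) {
  log_expr <- as.matrix(log_expr)
  p <- ncol(log_expr)
  if (p < 3L)
    stop_invalid("NormFinder variance decomposition needs >= 3 candidates")
  center2 <- function(m) {
    m - rowMeans(m) - rep(colMeans(m), each = nrow(m)) + mean(m)
  }
  if (is.null(groups)) {
    resid <- center2(log_expr)
    return(stats::setNames(apply(resid, 2L, stats::var),
                           colnames(log_expr)))
  }
  groups <- as.factor(groups)
  if (length(groups) != nrow(log_expr))
    stop_invalid("`groups` must have one label per subject")
  lv <- levels(groups)
  # intra-group residual variance per candidate
  intra <- matrix(NA_real_, length(lv), p)
  gmean <- matrix(NA_real_, length(lv), p) # group-specific candidate level
  for (g in seq_along(lv)) {
    sub <- log_expr[groups == lv[g], , drop = FALSE]
    # candidate level relative to the sample-wise mean removes loading
    rel <- sub - rowMeans(sub)
    gmean[g, ] <- colMeans(rel)
    intra[g, ] <- apply(center2(sub), 2L, stats::var)
  }
  bias <- apply(gmean, 2L, stats::var) # inter-group variability of the level
  stats::setNames(sqrt(colMeans(intra) / mean(table(groups)) + bias),
                  colnames(log_expr))
}

#' Score candidate normalization strategies
#'
#' Builds, for each candidate strategy, the subject-wise normalizer Crt
#' (global mean of amplified non-control wells, a single reference assay, or
#' the mean of a reference set), treats `-r_i` as a pseudo log2 expression,
#' and scores all candidates jointly with [genorm_m()] and
#' [normfinder_stability()]. Ranks (1 = most stable) are averaged over the
#' two algorithms to pick a winner.
#'
#' @param panel a QC'd `crt_panel` (never-amplified assays dropped).
#' @param candidates named list of normalizer descriptors; the default
#'   mirrors a typical screening-phase comparison: global mean, each
#'   endogenous control present, and the average of the four most stable
#'   (lowest-SD) assays.
#' @return data.frame of class `stability_report`: candidate, genorm_m,
#'   normfinder_stability, rank (mean-rank ordinal, 1 best).
#' @export
stability_report <- function(panel, candidates = NULL) {
  if (is.null(panel$expressed))
    stop_invalid("apply_qc() must run before stability_report()")
  if (is.null(candidates)) {
    candidates <- list(global_mean = normalizer_global_mean())
    for (ctl in setdiff(panel$control_ids, "ath-miR159a"))
      candidates[[ctl]] <- normalizer_reference(ctl)
    mir <- setdiff(panel$assay_ids, panel$control_ids)
    full <- mir[colSums(panel$expressed[, mir, drop = FALSE]) == nrow(panel$crt)]
    if (length(full) >= 4L) {
      sds <- apply(panel$crt[, full, drop = FALSE], 2L, stats::sd)
      candidates$stable4 <- normalizer_reference(names(sort(sds))[1:4])
    }
  }
  if (length(candidates) < 2L)
    stop_invalid("need >= 2 candidate strategies to score")
  pseudo <- vapply(candidates, function(s)
    -normalize_expression(panel, s)$normalizer, numeric(nrow(panel$crt)))
  colnames(pseudo) <- names(candidates)
  gm <- genorm_m(pseudo)
  nf <- if (ncol(pseudo) >= 3L) normfinder_stability(pseudo) else
    stats::setNames(rep(NA_real_, ncol(pseudo)), colnames(pseudo))
  mean_rank <- rank((rank(gm) + if (all(is.na(nf))) 0 else rank(nf)) / 2,
                    ties.method = "first")
  out <- data.frame(candidate = names(candidates), genorm_m = gm,
                    normfinder_stability = nf, rank = mean_rank,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("stability_report", "data.frame")
  out[order(out$rank), ]
}
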