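#' Quality-control configuration for Crt panels
#'
#' Defaults encode the standard OpenArray cleaning rule: a well is
#' unamplified when Crt exceeds 28 cycles, the amplification-curve quality
#' score falls below 1.1, or either value is missing; unamplified wells are
#' set to the sentinel Crt of 29.
#'
#' @param crt_max maximum Crt treated as amplified (cycles).
#' @param ampscore_min minimum acceptable AmpScore (0-2 scale).
#' @param unamplified_crt sentinel Crt assigned to unamplified wells; must
#'   exceed `crt_max`.
#' @param expressed_fraction_min candidacy gate: minimum fraction of
#'   subjects in which an assay must be expressed.
#' @return list of class `qc_config`.
#' @export
qc_config <- function(crt_max = 28, ampscore_min = 1.1, unamplified_crt = 29,
                      expressed_fraction_min = 0.5) {
  if (unamplified_crt <= crt_max)
    stop_invalid("unamplified_crt must exceed crt_max")
  check_scalar_number(expressed_fraction_min, "expressed_fraction_min",
                      lower = 0, upper = 1, strict_lower = TRUE)
  structure(list(crt_max = crt_max, ampscore_min = ampscore_min,
                 unamplified_crt = unamplified_crt,
                 expressed_fraction_min = expressed_fraction_min),
            class = "qc_config")
}

#' Apply the unamplified-well rule to a Crt panel
#'
#' Every well with `crt > crt_max`, `ampscore < ampscore_min`, or a missing
#' value in either matrix gets `crt := unamplified_crt` and an expressed flag
#' of `FALSE`; all other wells are untouched. Totally defined and idempotent.
#'
#' @param panel a `crt_panel`.
#' @param cfg a [qc_config()].
#' @return The panel with `crt` rewritten, an `expressed` logical matrix
#'   added, and the applied `qc` config attached.
#' @export
apply_qc <- function(panel, cfg = qc_config()) {
  stopifnot(inherits(panel, "crt_panel"))
  bad <- is.na(panel$crt) | is.na(panel$ampscore) |
    panel$crt > cfg$crt_max | panel$ampscore < cfg$ampscore_min
  panel$crt[bad] <- cfg$unamplified_crt
  panel$expressed <- !bad
  dimnames(panel$expressed) <- dimnames(panel$crt)
  panel$qc <- cfg
  panel
}

#' Drop assays amplified in no subject
#'
#' Removes assays whose expressed flag is `FALSE` for every subject (the
#' "not amplified in all subjects" exclusion applied between QC and
#' normalization). Retained plus dropped counts always equal the input
#' count.
#'
#' @param panel a QC'd `crt_panel` (see [apply_qc()]).
#' @return list with `panel` (assays removed) and `dropped` (assay ids).
#' @export
drop_never_amplified <- function(panel) {
  if (is.null(panel$expressed))
    stop_invalid("apply_qc() must run before drop_never_amplified()")
  dead <- colSums(panel$expressed) == 0L
  if (all(dead)) stop_invalid("all assays would be dropped: empty panel")
  keep <- !dead
  panel$crt <- panel$crt[, keep, drop = FALSE]
  panel$ampscore <- panel$ampscore[, keep, drop = FALSE]
  panel$expressed <- panel$expressed[, keep, drop = FALSE]
  dropped <- panel$assay_ids[dead]
  panel$assay_ids <- panel$assay_ids[keep]
  panel$control_ids <- intersect(panel$control_ids, panel$assay_ids)
  list(panel = panel, dropped = dropped)
}

#' Fraction of subjects in which each assay is expressed
#'
#' @param panel a QC'd `crt_panel`.
#' @return Named numeric vector in \[0, 1\], one entry per assay.
#' @export
expressed_fraction <- function(panel) {
  if (is.null(panel$expressed))
    stop_invalid("apply_qc() must run before expressed_fraction()")
  colMeans(panel$expressed)
}

#' Normalizer descriptors
#'
#' `normalizer_global_mean()` normalizes each subject by the mean Crt of that
#' subject's amplified wells across retained non-control assays.
#' `normalizer_reference(assays)` uses the mean Crt of a fixed reference
#' assay set. `normalizer_control_pair(endogenous, exogenous)` is the
#' validation-phase strategy combining an endogenous control with an
#' exogenous spike-in (arithmetic mean of their Crt).
#'
#' @param assays,endogenous,exogenous assay ids.
#' @return list of class `normalizer`.
#' @export
normalizer_global_mean <- function() {
  structure(list(type = "global_mean", label = "global mean"),
            class = "normalizer")
}

#' @rdname normalizer_global_mean
#' @export
normalizer_reference <- function(assays) {
  stopifnot(length(assays) >= 1L)
  structure(list(type = "reference", assays = as.character(assays),
                 label = paste("reference:", paste(assays, collapse = "+"))),
            class = "normalizer")
}

#' @rdname normalizer_global_mean
#' @export
normalizer_control_pair <- function(endogenous = "U6",
                                    exogenous = "ath-miR159a") {
  structure(list(type = "reference", assays = c(endogenous, exogenous),
                 label = sprintf("controls: %s+%s", endogenous, exogenous)),
            class = "normalizer")
}

#' Relative quantification 2^-DeltaCrt
#'
#' Computes `DeltaCrt_ij = crt_ij - r_i`, where `r_i` is the subject
#' normalizer (global-mean or reference strategy), and expression
#' `2^-DeltaCrt`. The global-mean `r_i` averages amplified wells only, over
#' retained non-control assays: imputed sentinel Crt values would otherwise
#' distort subject means asymmetrically. Unamplified wells propagate the
#' floor value `2^-(unamplified_crt - r_i)`. Under a reference strategy a
#' subject whose reference assay is unamplified is a normalization failure
#' and is listed in the result.
#'
#' @param panel a QC'd (and typically never-amplified-dropped) `crt_panel`.
#' @param strategy a normalizer descriptor.
#' @return An object of class `expression_matrix`: `values` (2^-DeltaCrt),
#'   `log2_values` (-DeltaCrt), `expressed` mask, `normalizer` (subject
#'   normalizer vector r), `strategy`, and `failed_subjects`.
#' @export
normalize_expression <- function(panel, strategy = normalizer_global_mean()) {
  if (is.null(panel$expressed))
    stop_invalid("apply_qc() must run before normalize_expression()")
  stopifnot(inherits(strategy, "normalizer"))
  crt <- panel$crt
  failed <- character()
  if (strategy$type == "global_mean") {
    use <- panel$expressed
    use[, panel$assay_ids %in% panel$control_ids] <- FALSE
    cnt <- rowSums(use)
    if (any(cnt == 0L))
      stop_invalid("subject(s) with no amplified wells: %s",
                   paste(rownames(crt)[cnt == 0L], collapse = ", "))
    r <- rowSums(crt * use) / cnt
  } else {
    ref <- strategy$assays
    missing_ref <- setdiff(ref, panel$assay_ids)
    if (length(missing_ref))
      stop_invalid("reference assay(s) not in panel: %s",
                   paste(missing_ref, collapse = ", "))
    ok <- panel$expressed[, ref, drop = FALSE]
    failed <- rownames(crt)[rowSums(ok) < length(ref)]
    r <- rowMeans(crt[, ref, drop = FALSE])
  }
  log2v <- -(crt - r)
  structure(list(values = 2^log2v, log2_values = log2v,
                 expressed = panel$expressed, normalizer = r,
                 strategy = strategy, failed_subjects = failed,
                 assay_ids = panel$assay_ids,
                 control_ids = panel$control_ids),
            class = "expression_matrix")
}

#' QC and normalization run report
#'
#' Summarizes a preprocessing run: unamplified well counts, dropped assays,
#' expressed fractions, and the chosen normalization, optionally written as
#' JSON.
#'
#' @param panel_raw panel before QC.
#' @param panel_qc panel after [apply_qc()].
#' @param dropped dropped assay ids.
#' @param expr the final `expression_matrix`.
#' @param path optional JSON output path.
#' @return The report list, invisibly when writing.
#' @export
qc_report <- function(panel_raw, panel_qc, dropped, expr, path = NULL) {
  rep <- list(
    n_subjects = nrow(panel_raw$crt),
    n_assays_input = ncol(panel_raw$crt),
    n_wells_unamplified = sum(!panel_qc$expressed),
    n_assays_dropped = length(dropped),
    dropped_assays = dropped,
    n_assays_retained = length(expr$assay_ids),
    normalization = expr$strategy$label,
    n_normalization_failures = length(expr$failed_subjects),
    failed_subjects = expr$failed_subjects
  )
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(rep))
  }
  rep
}
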