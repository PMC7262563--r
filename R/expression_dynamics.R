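# Stage-ordered expression dynamics: log transform, row Z-scores,
# stage aggregation, trajectory-pattern calling (ZGA activation, early
# presence followed by degradation, flat on/off), and panel specificity.

#' Ordered stage grid and ZGA window for an organism
#'
#' Preimplantation grids run zygote to late blastocyst; the zygotic genome
#' activation (ZGA) window is four- to eight-cell in human and two- to
#' four-cell in mouse. The spermatogenesis panel orders pre-meiotic (A-dark,
#' A-pale spermatogonia), meiotic (leptotene/zygotene, early and late
#' pachytene) and post-meiotic (round spermatid) cell types.
#'
#' @param organism `"human"` or `"mouse"`.
#' @param panel `"preimplantation"` or `"spermatogenesis"`.
#' @return A `stage_grid` list: `organism`, `stages`, `zga_window` (NULL for
#'   the spermatogenesis panel).
#' @export
stage_grid <- function(organism = c("human", "mouse"),
                       panel = c("preimplantation", "spermatogenesis")) {
  organism <- match.arg(organism)
  panel <- match.arg(panel)
  if (panel == "spermatogenesis") {
    return(structure(list(
      organism = organism,
      stages = c("A_dark", "A_pale", "leptotene_zygotene", "early_pachytene",
                 "late_pachytene", "round_spermatid"),
      zga_window = NULL), class = "stage_grid"))
  }
  stages <- c("zygote", "2cell", "4cell", "8cell", "morula",
              "late_blastocyst")
  zga <- if (organism == "human") c("4cell", "8cell") else c("2cell", "4cell")
  structure(list(organism = organism, stages = stages, zga_window = zga),
            class = "stage_grid")
}

#' Elementwise log2(TPM + 1) transform
#' @param expr Non-negative numeric matrix or vector.
#' @return Transformed object of the same shape.
#' @export
log_transform <- function(expr) {
  if (any(expr < 0, na.rm = TRUE)) stopf("negative values in TPM input")
  log2p1(expr)
}

#' Row-wise Z scores
#'
#' Per row: subtract the mean and divide by the sample standard deviation
#' (n-1 denominator). Constant rows become all zeros rather than NaN so that
#' heatmap exports stay finite.
#'
#' @param m Numeric matrix with at least two columns.
#' @return Z-score matrix of the same shape.
#' @export
zscore_rows <- function(m) {
  if (is.null(dim(m)) || ncol(m) < 2)
    stopf("zscore_rows needs a matrix with >= 2 columns")
  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  z <- (m - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  z
}

#' Average replicates into a stage-mean matrix
#'
#' @param expr TPM matrix.
#' @param sheet Sample sheet.
#' @param grid A [stage_grid()] (or any list with a `stages` vector).
#' @return Matrix transcripts x stages of mean TPM, columns in grid order.
#' @export
aggregate_stages <- function(expr, sheet, grid) {
  stages <- grid$stages
  out <- matrix(NA_real_, nrow(expr), length(stages),
                dimnames = list(rownames(expr), stages))
  for (s in stages) {
    cols <- sheet$sample_id[sheet$compartment == s]
    if (!length(cols)) stopf("stage '%s' has no samples", s)
    out[, s] <- rowMeans(expr[, cols, drop = FALSE])
  }
  out
}

#' Call per-transcript trajectory patterns over a stage grid
#'
#' Pattern grammar (closed vocabulary, `other` as catch-all):
#' * `zga_activated` - every stage mean before the ZGA window is below
#'   `threshold` and the maximum from the ZGA start onward reaches
#'   `threshold * fold`.
#' * `early_then_degraded` - every stage mean up to and including the ZGA
#'   start is at least `threshold`, the final stage has fallen to at most
#'   the early maximum divided by `fold`, and means are non-increasing from
#'   the ZGA start within a `tol` fractional tolerance (the shared
#'   maternal/paternal transcript-degradation shape).
#' * `flat_on` / `flat_off` - always above / below `threshold` with a
#'   pseudocounted max/min ratio below `fold`.
#'
#' `peak_stage` is the argmax stage; `stage_specific` requires a peak Z score
#' (on log2(TPM+1) stage means) of at least `z_peak` with all other stages
#' below `z_other`.
#'
#' @param stage_means Matrix from [aggregate_stages()].
#' @param grid A [stage_grid()] with a ZGA window.
#' @param threshold Expression threshold (TPM).
#' @param fold Activation/degradation fold requirement.
#' @param tol Fractional tolerance for the non-increasing check.
#' @param z_peak,z_other Stage-specificity Z cutoffs.
#' @return data.frame: `transcript_id`, `pattern`, `peak_stage`,
#'   `stage_specific`.
#' @export
call_trajectory <- function(stage_means, grid, threshold = 1, fold = 2,
                            tol = 0.1, z_peak = 1.5, z_other = 0.5) {
  stages <- grid$stages
  if (length(stages) < 4) stopf("grid must have >= 4 stages")
  if (is.null(grid$zga_window) || !all(grid$zga_window %in% stages))
    stopf("grid ZGA window absent or not contained in the stage grid")
  if (!identical(colnames(stage_means), stages))
    stopf("stage_means columns must match the grid stages in order")
  zi <- match(grid$zga_window[1], stages)
  ns <- length(stages)
  z <- zscore_rows(log2p1(stage_means))
  res <- lapply(seq_len(nrow(stage_means)), function(i) {
    m <- stage_means[i, ]
    pre <- if (zi > 1) m[seq_len(zi - 1)] else numeric()
    early <- m[seq_len(zi)]
    late <- m[zi:ns]
    ratio <- (max(m) + 1) / (min(m) + 1)
    pattern <-
      if (length(pre) && all(pre < threshold) &&
          max(late) >= threshold * fold) "zga_activated"
      else if (all(early >= threshold) && m[ns] <= max(early) / fold &&
               all(diff(late) <= tol * late[-length(late)])) "early_then_degraded"
      else if (all(m >= threshold) && ratio < fold) "flat_on"
      else if (all(m < threshold) && ratio < fold) "flat_off"
      else "other"
    peak <- stages[which.max(m)]
    zz <- z[i, ]
    specific <- max(zz) >= z_peak && all(zz[-which.max(m)] < z_other)
    list(pattern = pattern, peak_stage = peak, stage_specific = specific)
  })
  out <- data.frame(
    transcript_id = rownames(stage_means),
    pattern = factor(vapply(res, `[[`, "", "pattern"),
                     levels = c(TRAJECTORY_CLASSES, "other")),
    peak_stage = vapply(res, `[[`, "", "peak_stage"),
    stage_specific = vapply(res, `[[`, TRUE, "stage_specific"),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Compartment-panel specificity per transcript
#'
#' Computes per-transcript Z scores of mean log2(TPM+1) across a compartment
#' panel, the argmax compartment, and a specificity flag under the same
#' Z-score rule as [call_trajectory()].
#'
#' @param expr TPM matrix.
#' @param sheet Sample sheet.
#' @param panel Character vector of >= 2 compartments.
#' @param z_peak,z_other Specificity Z cutoffs.
#' @return data.frame: `transcript_id`, `top_compartment`, `specific`, and
#'   one Z column per panel member (`z_<compartment>`).
#' @export
panel_specificity <- function(expr, sheet, panel, z_peak = 1.5,
                              z_other = 0.5) {
  if (length(panel) < 2) stopf("panel needs >= 2 compartments")
  miss <- setdiff(panel, sheet$compartment)
  if (length(miss)) stopf("panel compartments absent from sheet: %s",
                          paste(miss, collapse = ", "))
  means <- vapply(panel, function(comp) {
    cols <- sheet$sample_id[sheet$compartment == comp]
    rowMeans(log2p1(expr[, cols, drop = FALSE]))
  }, numeric(nrow(expr)))
  z <- zscore_rows(means)
  top_i <- apply(means, 1, which.max)
  specific <- vapply(seq_len(nrow(z)), function(i)
    max(z[i, ]) >= z_peak && all(z[i, -top_i[i]] < z_other), TRUE)
  out <- data.frame(transcript_id = rownames(expr),
                    top_compartment = panel[top_i],
                    specific = specific, stringsAsFactors = FALSE)
  zdf <- as.data.frame(z)
  names(zdf) <- paste0("z_", panel)
  rownames(out) <- NULL
  cbind(out, zdf)
}
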