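# Partition transcripts into Sp / Oc / SpOc / Misc / NotExpressed from
# gamete TPM matrices by replicate consistency: a transcript belongs to a
# gamete only if it is expressed in every donor replicate of that gamete, and
# is "specific" only if additionally absent from every replicate of the other
# gamete. Any strict partial replicate pattern makes it miscellaneous.

#' Threshold TPM values into an expressed/silent flag matrix
#'
#' @param expr Numeric TPM matrix (transcripts x samples).
#' @param threshold Expression threshold in TPM; a cell is expressed iff
#'   `TPM >= threshold`.
#' @return Logical matrix of the same shape.
#' @export
call_expressed <- function(expr, threshold = 1) {
  if (threshold <= 0) stopf("threshold must be > 0")
  if (any(!is.finite(expr)) || any(expr < 0))
    stopf("expression matrix must be finite and non-negative")
  expr >= threshold
}

#' Classify transcripts by gamete replicate consistency
#'
#' Per transcript: consistent-in(g) means expressed in all replicates of
#' gamete g; absent-in(g) means expressed in none. `Sp` = consistent in sperm
#' and absent in oocyte; `Oc` the mirror image; `SpOc` = consistent in both;
#' `NotExpressed` = absent in both; everything else (an inconsistent donor
#' pattern in either gamete) is `Misc` and conventionally excluded from
#' downstream analysis.
#'
#' @param flags Logical matrix from [call_expressed()].
#' @param sheet Sample sheet covering the flag columns.
#' @param gametes Length-2 character: compartment tokens of the two gametes.
#' @return data.frame: `transcript_id`, `category`, and per-gamete
#'   expressed/total replicate counts.
#' @export
classify_gamete <- function(flags, sheet,
                            gametes = c("sperm", "oocyte")) {
  stopifnot(length(gametes) == 2)
  cols <- lapply(gametes, function(g)
    sheet$sample_id[sheet$compartment == g])
  empty <- lengths(cols) == 0
  if (any(empty))
    stopf("no samples for gamete(s): %s",
          paste(gametes[empty], collapse = ", "))
  miss <- setdiff(unlist(cols), colnames(flags))
  if (length(miss)) stopf("flag matrix missing samples: %s",
                          paste(miss, collapse = ", "))
  n1 <- rowSums(flags[, cols[[1]], drop = FALSE])
  n2 <- rowSums(flags[, cols[[2]], drop = FALSE])
  t1 <- length(cols[[1]]); t2 <- length(cols[[2]])
  cons1 <- n1 == t1; abs1 <- n1 == 0
  cons2 <- n2 == t2; abs2 <- n2 == 0
  category <- rep("Misc", nrow(flags))
  category[cons1 & abs2] <- "Sp"
  category[cons2 & abs1] <- "Oc"
  category[cons1 & cons2] <- "SpOc"
  category[abs1 & abs2] <- "NotExpressed"
  out <- data.frame(
    transcript_id = rownames(flags),
    category = factor(category, levels = GAMETE_CATEGORIES),
    sperm_expressed_reps = n1, sperm_total_reps = t1,
    oocyte_expressed_reps = n2, oocyte_total_reps = t2,
    stringsAsFactors = FALSE)
  names(out)[3:6] <- c(paste0(gametes[1], c("_expressed_reps", "_total_reps")),
                       paste0(gametes[2], c("_expressed_reps", "_total_reps")))
  rownames(out) <- NULL
  class(out) <- c("gamete_classification", "data.frame")
  out
}

#' Summarize expression distributions per category, biotype and compartment
#'
#' For each (category x biotype x compartment) cell: the boxplot statistics
#' (median, quartiles, whisker range at 1.5 IQR) of the per-transcript mean
#' log2(TPM+1) across that compartment's replicates.
#'
#' @param expr TPM matrix.
#' @param classification Output of [classify_gamete()].
#' @param sheet Sample sheet.
#' @param transcripts Transcript table supplying biotypes (optional; without
#'   it biotype is reported as `all`).
#' @param compartments Compartments to summarize (default: all in the sheet).
#' @return data.frame of summaries; empty cells have `n = 0` and missing
#'   statistics.
#' @export
category_expression_summary <- function(expr, classification, sheet,
                                        transcripts = NULL,
                                        compartments = NULL) {
  compartments <- compartments %||% unique(sheet$compartment)
  biotype <- if (is.null(transcripts)) rep("all", nrow(expr)) else
    as.character(transcripts$biotype[match(rownames(expr),
                                           transcripts$transcript_id)])
  cat_of <- as.character(
    classification$category[match(rownames(expr),
                                  classification$transcript_id)])
  out <- list()
  for (comp in compartments) {
    cols <- sheet$sample_id[sheet$compartment == comp]
    if (!length(cols)) next
    mval <- rowMeans(log2p1(expr[, cols, drop = FALSE]))
    for (cat in levels(classification$category)) {
      for (bt in unique(biotype)) {
        sel <- !is.na(cat_of) & cat_of == cat & biotype == bt
        if (!any(sel)) {
          out[[length(out) + 1]] <- data.frame(
            category = cat, biotype = bt, compartment = comp, n = 0L,
            median = NA_real_, q1 = NA_real_, q3 = NA_real_,
            whisker_low = NA_real_, whisker_high = NA_real_)
          next
        }
        v <- mval[sel]
        q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
        iqr <- q[3] - q[1]
        out[[length(out) + 1]] <- data.frame(
          category = cat, biotype = bt, compartment = comp, n = sum(sel),
          median = q[2], q1 = q[1], q3 = q[3],
          whisker_low = min(v[v >= q[1] - 1.5 * iqr]),
          whisker_high = max(v[v <= q[3] + 1.5 * iqr]))
      }
    }
  }
  do.call(rbind, out)
}
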