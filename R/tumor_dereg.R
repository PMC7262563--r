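# Tumor-versus-normal deregulation scoring per gene per cancer type:
# Z score and log2 fold change on log2(TPM+1), rank-sum significance with
# BH-FDR within each cancer code, and a pan-cancer deregulation count.
# Cancer cohorts are identified in the sample sheet by compartment tokens
# "tumor:<code>" and "normal:<code>".

.cohort_cols <- function(sheet, code) {
  list(tumor = sheet$sample_id[sheet$compartment == paste0("tumor:", code)],
       normal = sheet$sample_id[sheet$compartment == paste0("normal:", code)])
}

.check_cohort <- function(cols, code) {
  if (length(cols$tumor) < 2 || length(cols$normal) < 2)
    stopf("cancer code '%s' needs >= 2 tumor and >= 2 normal samples (has %d/%d)",
          code, length(cols$tumor), length(cols$normal))
  cols
}

#' Per-gene tumor-vs-normal Z score for one cancer type
#'
#' On the log2(TPM+1) scale: `z = (mean_tumor - mean_normal) /
#' sqrt(s_t^2/n_t + s_n^2/n_n)` (Welch-style pooling, robust to the very
#' unequal cohort sizes of matched vs consortium normals).
#'
#' @param expr TPM matrix (genes x samples).
#' @param sheet Sample sheet with `tumor:<code>` / `normal:<code>`
#'   compartments.
#' @param code Cancer-type token.
#' @return Named numeric vector of Z scores.
#' @export
cohort_zscore <- function(expr, sheet, code) {
  cols <- .check_cohort(.cohort_cols(sheet, code), code)
  lt <- log2p1(expr[, cols$tumor, drop = FALSE])
  ln <- log2p1(expr[, cols$normal, drop = FALSE])
  vt <- apply(lt, 1, stats::var) / ncol(lt)
  vn <- apply(ln, 1, stats::var) / ncol(ln)
  se <- sqrt(vt + vn)
  z <- (rowMeans(lt) - rowMeans(ln)) / ifelse(se > 0, se, 1)
  z[se == 0] <- 0
  z
}

#' Per-gene log2 fold change for one cancer type
#'
#' Mean log2(TPM+1) over tumors minus mean log2(TPM+1) over normals; the +1
#' pseudocount keeps the statistic defined at zero TPM.
#'
#' @inheritParams cohort_zscore
#' @return Named numeric vector of log2 fold changes.
#' @export
log_fold_change <- function(expr, sheet, code) {
  cols <- .check_cohort(.cohort_cols(sheet, code), code)
  rowMeans(log2p1(expr[, cols$tumor, drop = FALSE])) -
    rowMeans(log2p1(expr[, cols$normal, drop = FALSE]))
}

#' Call per-gene deregulation across cancer types
#'
#' Per (gene x code): a Wilcoxon rank-sum test (normal approximation with
#' tie correction) of tumor vs normal TPM, BH-FDR across genes within the
#' code, and a call of `up` / `down` when `|log2fc| >= lfc_min` and
#' `fdr < alpha`, else `none`. The pan-cancer count per gene is the number
#' of codes with a non-`none` call.
#'
#' @param expr TPM matrix.
#' @param sheet Sample sheet (optionally from [normal_source_merge()]).
#' @param codes Cancer-type tokens to test.
#' @param lfc_min Minimum absolute log2 fold change.
#' @param alpha FDR threshold.
#' @return List with `calls` (per gene x code: `gene_id`, `cancer_code`,
#'   `n_tumor`, `n_normal`, `log2fc`, `z`, `p`, `fdr`, `call`) and
#'   `pan_cancer` (`gene_id`, `n_codes_tested`, `pan_cancer_count`).
#' @export
deregulation_call <- function(expr, sheet, codes, lfc_min = 1, alpha = 0.05) {
  if (!length(codes)) stopf("empty cancer code list")
  per_code <- lapply(codes, function(code) {
    cols <- .check_cohort(.cohort_cols(sheet, code), code)
    lfc <- log_fold_change(expr, sheet, code)
    z <- cohort_zscore(expr, sheet, code)
    tum <- expr[, cols$tumor, drop = FALSE]
    nor <- expr[, cols$normal, drop = FALSE]
    p <- vapply(seq_len(nrow(expr)), function(i)
      stats::wilcox.test(tum[i, ], nor[i, ], exact = FALSE,
                         correct = TRUE)$p.value, 0)
    p[is.na(p)] <- 1  # all-tied rows
    fdr <- stats::p.adjust(p, method = "BH")
    call <- ifelse(fdr < alpha & lfc >= lfc_min, "up",
            ifelse(fdr < alpha & lfc <= -lfc_min, "down", "none"))
    data.frame(gene_id = rownames(expr), cancer_code = code,
               n_tumor = length(cols$tumor), n_normal = length(cols$normal),
               log2fc = unname(lfc), z = unname(z), p = p, fdr = fdr,
               call = call, stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, per_code)
  rownames(calls) <- NULL
  agg <- stats::aggregate(call != "none" ~ gene_id, data = calls, FUN = sum)
  names(agg) <- c("gene_id", "pan_cancer_count")
  agg$n_codes_tested <- length(codes)
  pan <- agg[match(rownames(expr), agg$gene_id),
             c("gene_id", "n_codes_tested", "pan_cancer_count")]
  rownames(pan) <- NULL
  list(calls = calls, pan_cancer = pan)
}

#' Attach fallback normals to cancer codes lacking matched normals
#'
#' Codes with at least two matched normal samples are left unchanged
#' (provenance `matched`); codes with fewer get the fallback rows for their
#' code attached (provenance `fallback`, e.g. consortium normal tissue);
#' codes with neither are excluded with a warning.
#'
#' @param sheet Sample sheet containing `tumor:<code>` rows.
#' @param fallback_normals Sheet rows whose compartments are
#'   `normal:<code>`.
#' @return Augmented sheet with a `normal_provenance` column; excluded codes
#'   are reported via warning and their tumor rows dropped.
#' @export
normal_source_merge <- function(sheet, fallback_normals) {
  sheet$normal_provenance <- ifelse(
    grepl("^normal:", sheet$compartment), "matched", NA_character_)
  codes <- unique(sub("^tumor:", "",
                      grep("^tumor:", sheet$compartment, value = TRUE)))
  out <- sheet
  dropped <- character()
  for (code in codes) {
    n_matched <- sum(sheet$compartment == paste0("normal:", code))
    if (n_matched >= 2) next
    fb <- fallback_normals[fallback_normals$compartment ==
                             paste0("normal:", code), , drop = FALSE]
    if (nrow(fb) + n_matched >= 2) {
      fb$normal_provenance <- "fallback"
      out <- rbind(out, fb[, names(out)])
    } else {
      dropped <- c(dropped, code)
      out <- out[out$compartment != paste0("tumor:", code) &
                   out$compartment != paste0("normal:", code), , drop = FALSE]
    }
  }
  if (length(dropped))
    warning(sprintf("excluded cancer code(s) without usable normals: %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
  rownames(out) <- NULL
  out
}
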