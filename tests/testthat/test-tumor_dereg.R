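# Tumor-vs-normal scoring: closed forms, manual-arithmetic oracle,
# antisymmetry, the call rule, and fallback-normal merging.

mk_sheet <- function(code, n_t, n_n) {
  data.frame(
    sample_id = c(sprintf("t%02d", seq_len(n_t)),
                  sprintf("n%02d", seq_len(n_n))),
    organism = "human",
    compartment = c(rep(paste0("tumor:", code), n_t),
                    rep(paste0("normal:", code), n_n)),
    replicate = as.character(c(seq_len(n_t), seq_len(n_n))),
    stringsAsFactors = FALSE)
}

test_that("identical cohorts give zero z and zero fold change", {
  sheet <- mk_sheet("ACC", 3, 3)
  m <- matrix(rep(c(2, 5, 9), 6), 3, 6,
              dimnames = list(c("g1", "g2", "g3"), sheet$sample_id))
  expect_equal(unname(cohort_zscore(m, sheet, "ACC")), c(0, 0, 0))
  expect_equal(unname(log_fold_change(m, sheet, "ACC")), c(0, 0, 0))
})

test_that("closed-form fold change: mean-log 5 vs 3 gives 2", {
  sheet <- mk_sheet("ACC", 2, 2)
  m <- matrix(c(rep(2^5 - 1, 2), rep(2^3 - 1, 2)), 1, 4,
              dimnames = list("g1", sheet$sample_id))
  expect_equal(unname(log_fold_change(m, sheet, "ACC")), 2)
})

test_that("3v3 z equals spreadsheet-style manual arithmetic", {
  sheet <- mk_sheet("BRCA", 3, 3)
  tv <- c(7, 9, 12); nv <- c(2, 3, 2.5)
  m <- matrix(c(tv, nv), 1, 6, dimnames = list("g1", sheet$sample_id))
  # manual: log2(x+1), means, variances, Welch-style pooled standard error
  lt <- log2(tv + 1); ln <- log2(nv + 1)
  mt <- (lt[1] + lt[2] + lt[3]) / 3
  mn <- (ln[1] + ln[2] + ln[3]) / 3
  vt <- ((lt[1] - mt)^2 + (lt[2] - mt)^2 + (lt[3] - mt)^2) / 2
  vn <- ((ln[1] - mn)^2 + (ln[2] - mn)^2 + (ln[3] - mn)^2) / 2
  z_manual <- (mt - mn) / sqrt(vt / 3 + vn / 3)
  expect_equal(unname(cohort_zscore(m, sheet, "BRCA")), z_manual)
  expect_equal(unname(log_fold_change(m, sheet, "BRCA")), mt - mn)
})

test_that("cohort preconditions name the offending code", {
  sheet <- mk_sheet("KICH", 1, 3)
  m <- matrix(1, 1, 4, dimnames = list("g", sheet$sample_id))
  expect_error(cohort_zscore(m, sheet, "KICH"), "KICH")
})

test_that("swapping tumor and normal labels negates effects and flips calls", {
  tc <- simulate_tumor_cohort(sprintf("g%d", 1:20), "LUAD", n_tumor = 12,
                              n_normal = 12,
                              planted = data.frame(gene_id = "g1",
                                                   code = "LUAD", lfc = 3),
                              seed = 23)
  swapped <- tc$sheet
  swapped$compartment <- ifelse(grepl("^tumor:", swapped$compartment),
                                sub("^tumor:", "normal:", swapped$compartment),
                                sub("^normal:", "tumor:", swapped$compartment))
  expect_equal(cohort_zscore(tc$expr, swapped, "LUAD"),
               -cohort_zscore(tc$expr, tc$sheet, "LUAD"))
  expect_equal(log_fold_change(tc$expr, swapped, "LUAD"),
               -log_fold_change(tc$expr, tc$sheet, "LUAD"))
  up <- deregulation_call(tc$expr, tc$sheet, "LUAD")$calls
  dn <- deregulation_call(tc$expr, swapped, "LUAD")$calls
  expect_equal(up$call[up$gene_id == "g1"], "up")
  expect_equal(dn$call[dn$gene_id == "g1"], "down")
})

test_that("a clean separation with large fold change is called up", {
  sheet <- mk_sheet("OV", 10, 10)
  set.seed(31)
  m <- matrix(c(stats::runif(10, 50, 60), stats::runif(10, 2, 3)), 1, 20,
              dimnames = list("g1", sheet$sample_id))
  res <- deregulation_call(m, sheet, "OV", lfc_min = 3)
  expect_equal(res$calls$call, "up")
  expect_equal(res$pan_cancer$pan_cancer_count, 1)
  expect_error(deregulation_call(m, sheet, character()), "empty")
})

test_that("call outcomes are not invariant to rescaling all TPMs", {
  # log2(TPM+1) is not scale-free; a global rescale changes the fold change
  sheet <- mk_sheet("GBM", 5, 5)
  m <- matrix(c(rep(10, 5), rep(2, 5)), 1, 10,
              dimnames = list("g1", sheet$sample_id))
  l1 <- unname(log_fold_change(m, sheet, "GBM"))
  l2 <- unname(log_fold_change(m * 100, sheet, "GBM"))
  expect_false(isTRUE(all.equal(l1, l2)))
})

test_that("fallback normals attach only where matched normals are missing", {
  sheet <- rbind(mk_sheet("ACC", 3, 5), mk_sheet("BLCA", 3, 0),
                 mk_sheet("CHOL", 3, 1))
  sheet$sample_id <- make.unique(sheet$sample_id)
  fb <- data.frame(
    sample_id = sprintf("gtex%02d", 1:4), organism = "human",
    compartment = c(rep("normal:BLCA", 4)),
    replicate = as.character(1:4), stringsAsFactors = FALSE)
  expect_warning(out <- normal_source_merge(sheet, fb), "CHOL")
  # matched code untouched
  expect_equal(sum(out$compartment == "normal:ACC"), 5)
  expect_true(all(out$normal_provenance[out$compartment == "normal:ACC"] ==
                    "matched"))
  # fallback code gains the consortium normals
  expect_equal(sum(out$compartment == "normal:BLCA"), 4)
  expect_true(all(out$normal_provenance[out$compartment == "normal:BLCA"] ==
                    "fallback"))
  # code with neither is excluded entirely
  expect_false(any(grepl("CHOL", out$compartment)))
})

test_that("planted fold change is recovered and the null stays quiet", {
  genes <- sprintf("g%03d", 1:40)
  planted <- data.frame(gene_id = genes[1:20], code = "LUAD", lfc = 2)
  tc <- simulate_tumor_cohort(genes, "LUAD", n_tumor = 50, n_normal = 50,
                              planted = planted, sd = 0.5, seed = 13)
  lfc <- log_fold_change(tc$expr, tc$sheet, "LUAD")
  expect_lt(abs(mean(lfc[1:20]) - 2), 0.1)
  # small null panel: no calls at all
  tcn <- simulate_tumor_cohort(genes, c("ACC", "BLCA"), n_tumor = 30,
                               n_normal = 30, planted = NULL, seed = 5)
  res <- deregulation_call(tcn$expr, tcn$sheet, c("ACC", "BLCA"))
  expect_lte(mean(res$calls$call != "none"), 0.01)
})
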