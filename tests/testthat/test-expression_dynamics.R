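# Log transform, row Z-scores, stage aggregation, trajectory grammar and
# panel specificity.

human <- stage_grid("human")

profile_matrix <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  rownames(m) <- sprintf("t%d", seq_len(nrow(m)))
  colnames(m) <- human$stages
  m
}

test_that("log transform is log2(x+1), rejects negatives, and is monotone", {
  expect_equal(log_transform(0), 0)
  expect_equal(log_transform(3), 2)
  expect_error(log_transform(-0.1), "negative")
  set.seed(2)
  x <- sort(stats::rexp(50))
  expect_true(all(diff(log_transform(x)) > 0))
})

test_that("row Z-scores use the n-1 convention and zero-fill constant rows", {
  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5))
  z <- zscore_rows(m)
  expect_equal(unname(z["a", ]), c(-1, 0, 1))
  expect_equal(unname(z["b", ]), c(0, 0, 0))
  expect_error(zscore_rows(m[, 1, drop = FALSE]), "2 columns")
  set.seed(4)
  r <- matrix(stats::rnorm(500), 20, 25)
  zr <- zscore_rows(r)
  expect_true(all(abs(rowMeans(zr)) < 1e-12))
  expect_true(all(abs(apply(zr, 1, stats::sd) - 1) < 1e-12))
  # affine invariance: Z(a*x + b) = Z(x) for a > 0
  expect_equal(zscore_rows(3.7 * r + 11), zr)
})

test_that("stage aggregation equals the brute-force group mean", {
  set.seed(5)
  sheet <- data.frame(
    sample_id = sprintf("s%d", 1:12), organism = "human",
    compartment = rep(human$stages, each = 2),
    replicate = as.character(rep(1:2, 6)), stringsAsFactors = FALSE)
  m <- matrix(stats::rexp(5 * 12), 5, 12,
              dimnames = list(sprintf("t%d", 1:5), sheet$sample_id))
  ag <- aggregate_stages(m, sheet, human)
  for (s in human$stages) {
    cols <- sheet$sample_id[sheet$compartment == s]
    for (i in 1:5)
      expect_equal(ag[i, s], mean(c(m[i, cols[1]], m[i, cols[2]])))
  }
  expect_equal(unname(ag["t1", "zygote"]),
               mean(m["t1", c("s1", "s2")]))
  # two replicates (2, 4) average to 3
  m2 <- m; m2["t1", c("s1", "s2")] <- c(2, 4)
  expect_equal(unname(aggregate_stages(m2, sheet, human)["t1", "zygote"]), 3)
  # stages without samples are an error
  expect_error(aggregate_stages(m, sheet[-(1:2), ], human), "zygote")
})

test_that("trajectory grammar matches the rule table on canonical profiles", {
  sm <- profile_matrix(
    c(0, 0, 5, 8, 6, 6),          # ZGA activation
    c(6, 6, 5, 1, 0.4, 0.2),      # early presence then degradation
    c(8, 8, 8, 8, 8, 8),          # flat on
    c(0.2, 0.2, 0.2, 0.2, 0.2, 0.2),  # flat off
    c(9, 0.1, 9, 0.1, 9, 0.1))    # none of the above
  tc <- call_trajectory(sm, human, threshold = 1, fold = 2)
  expect_equal(as.character(tc$pattern),
               c("zga_activated", "early_then_degraded", "flat_on",
                 "flat_off", "other"))
  expect_equal(tc$peak_stage[1], "8cell")
  expect_error(call_trajectory(sm, stage_grid("human", "spermatogenesis")),
               "ZGA")
})

test_that("mouse grid shifts the ZGA window one stage earlier", {
  mouse <- stage_grid("mouse")
  expect_equal(mouse$zga_window, c("2cell", "4cell"))
  sm <- profile_matrix(c(0.2, 3, 12, 10, 8, 6))
  tc <- call_trajectory(sm, mouse)
  expect_equal(as.character(tc$pattern), "zga_activated")
  # the same profile on the human grid fails the pre-ZGA silence rule
  tc_h <- call_trajectory(sm, human)
  expect_false(as.character(tc_h$pattern) == "zga_activated")
})

test_that("trajectory calls recover the planted classes on the bundle", {
  b <- default_bundle()
  ex <- default_expression()
  sm <- aggregate_stages(ex$expr, ex$sheet, human)
  tc <- call_trajectory(sm, human, threshold = b$config$threshold)
  acc <- mean(as.character(tc$pattern) == b$truth$trajectory_class)
  expect_gte(acc, 0.95)
  # the crossing pattern: Sp transcripts peak in/after the ZGA window,
  # shared lincRNAs decline from it
  zi <- match(human$zga_window[1], human$stages)
  sp <- b$truth$gamete_category == "Sp"
  expect_true(all(match(tc$peak_stage[sp], human$stages) >= zi))
  spoc_l <- b$truth$gamete_category == "SpOc" & b$truth$biotype == "lincRNA"
  early_max <- apply(sm[spoc_l, seq_len(zi), drop = FALSE], 1, max)
  expect_true(all(sm[spoc_l, length(human$stages)] < early_max))
})

test_that("trajectory calls are invariant to replicate order and duplication", {
  ex <- default_expression()
  sm1 <- aggregate_stages(ex$expr, ex$sheet, human)
  # shuffle columns
  set.seed(7)
  perm <- sample(ncol(ex$expr))
  sm2 <- aggregate_stages(ex$expr[, perm], ex$sheet[perm, ], human)
  expect_equal(sm1, sm2)
  # duplicating every replicate leaves stage means unchanged
  ex2 <- cbind(ex$expr, ex$expr)
  colnames(ex2) <- c(colnames(ex$expr), paste0(colnames(ex$expr), "_dup"))
  sheet2 <- rbind(ex$sheet,
                  transform(ex$sheet, sample_id = paste0(sample_id, "_dup")))
  sm3 <- aggregate_stages(ex2, sheet2, human)
  expect_equal(sm1, sm3)
  expect_equal(call_trajectory(sm1, human), call_trajectory(sm3, human))
})

test_that("panel specificity flags planted round-spermatid restriction", {
  b <- default_bundle()
  ex <- default_expression()
  tr <- b$truth
  panel <- stage_grid("human", "spermatogenesis")$stages
  ps <- panel_specificity(ex$expr, ex$sheet, panel)
  planted <- tr$gamete_category %in% c("Sp", "SpOc") &
    tr$chromatin_state %in% c("high_K4", "low_K4")
  expect_gte(mean(ps$top_compartment[planted] == "round_spermatid"), 0.95)
  expect_gte(mean(ps$specific[planted]), 0.95)
  # uniform expression is never specific
  flat <- matrix(5, 3, ncol(ex$expr), dimnames = list(letters[1:3],
                                                      colnames(ex$expr)))
  ps_flat <- panel_specificity(flat, ex$sheet, panel)
  expect_false(any(ps_flat$specific))
  expect_error(panel_specificity(ex$expr, ex$sheet, "sperm"), ">= 2")
})
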