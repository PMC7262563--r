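# Promoter windows, signal binning (checked against the per-base oracle in
# helper-oracles.R), k-means clustering, state labeling, and persistence
# tracing.

test_that("promoter windows obey the +/-flank geometry and clamping", {
  tx <- data.frame(transcript_id = c("a", "b", "c"), gene_id = c("a", "b", "c"),
                   biotype = "lincRNA", chrom = "chr1",
                   start = c(50000, 48001, 4000), end = c(52000, 50001, 6000),
                   strand = c("+", "-", "+"),
                   tss = c(50000, 50000, 4000), stringsAsFactors = FALSE)
  w <- promoter_windows(tx, flank = 10000, bin_size = 100)
  expect_equal(w$window_start[1:2], c(40000, 40000))
  expect_equal(w$window_end[1:2], c(60000, 60000))
  expect_equal(w$bins[1], 200)
  # overhanging window keeps 60 leading out-of-range bins flagged
  expect_equal(w$window_start[3], -6000)
  expect_equal(w$clipped_bins[3], 60)
  expect_error(promoter_windows(tx, flank = -1), "positive")
  expect_error(promoter_windows(tx, flank = 10000, bin_size = 3000),
               "divisible")
})

test_that("uniform coverage gives the closed-form bin value everywhere", {
  iv <- data.frame(chrom = "chr1", start = 0, end = 100000, value = 2.5)
  tk <- gametrace:::new_coverage_track("H3K4me3", "sperm", iv)
  tx <- make_tx(2, start = 20000)
  w <- promoter_windows(tx, flank = 5000, bin_size = 100)
  sm <- signal_matrix(tk, w)
  expect_equal(unname(sm$signal),
               matrix(log2(1 + 2.5 * 1e6 / tk$library_size), 2, 100),
               tolerance = 1e-12)
  # region with no coverage: zero bins
  tx2 <- make_tx(1, chrom = "chr2")
  w2 <- promoter_windows(tx2, flank = 5000, bin_size = 100)
  expect_true(all(signal_matrix(tk, w2)$signal == 0))
  # zero library size is rejected
  tk0 <- gametrace:::new_coverage_track("H3K4me3", "sperm", iv[0, ])
  expect_error(signal_matrix(tk0, w), "library size")
})

test_that("binned signal equals the per-base brute-force average", {
  iv <- random_track(seed = 7)
  tk <- gametrace:::new_coverage_track("H3K4me3", "sperm", iv)
  set.seed(8)
  n <- 10
  tss <- sample(500:3500, n)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  tx <- data.frame(transcript_id = sprintf("r%02d", 1:n),
                   gene_id = sprintf("r%02d", 1:n), biotype = "lincRNA",
                   chrom = "chr1", start = tss, end = tss + 10,
                   strand = strand, tss = tss, stringsAsFactors = FALSE)
  tx$tss <- ifelse(strand == "+", tx$start, tx$end - 1)
  tx$end <- ifelse(strand == "-", tx$tss + 1, tx$end)
  w <- promoter_windows(tx, flank = 400, bin_size = 40)
  sm <- signal_matrix(tk, w)
  expect_equal(sm$signal, oracle_signal(tk, w), tolerance = 1e-9)
})

test_that("signal is linear in coverage before the log transform", {
  iv <- random_track(seed = 3)
  tk1 <- gametrace:::new_coverage_track("H3K4me3", "sperm", iv)
  iv2 <- iv; iv2$value <- iv2$value * 2
  tk2 <- gametrace:::new_coverage_track("H3K4me3", "sperm", iv2)
  tk2$library_size <- tk1$library_size  # fixed normalization
  tx <- make_tx(1, start = 1000, spacing = 0)
  tx$tss <- 2000; tx$start <- 2000; tx$end <- 4000
  w <- promoter_windows(tx, flank = 1000, bin_size = 100)
  pre1 <- 2^signal_matrix(tk1, w)$signal - 1
  pre2 <- 2^signal_matrix(tk2, w)$signal - 1
  expect_equal(pre2, 2 * pre1, tolerance = 1e-9)
})

test_that("reversing a transcript's strand reverses its bin vector exactly", {
  iv <- random_track(seed = 5)
  tk <- gametrace:::new_coverage_track("H3K27me3", "sperm", iv)
  tx <- data.frame(transcript_id = c("fwd", "rev"), gene_id = c("g", "g"),
                   biotype = "lincRNA", chrom = "chr1",
                   start = c(2000, 1), end = c(2500, 2001),
                   strand = c("+", "-"), tss = c(2000, 2000),
                   stringsAsFactors = FALSE)
  w <- promoter_windows(tx, flank = 500, bin_size = 50)
  sm <- signal_matrix(tk, w)
  expect_equal(unname(sm$signal["rev", ]), unname(rev(sm$signal["fwd", ])))
})

test_that("clustering is seed-deterministic and recovers two planted states", {
  set.seed(9)
  m <- rbind(matrix(stats::rnorm(50 * 20, 5), 50, 20),
             matrix(stats::rnorm(50 * 20, 0), 50, 20))
  rownames(m) <- sprintf("t%03d", 1:100)
  k4 <- make_signal(pmax(m, 0)); k27 <- make_signal(matrix(0.1, 100, 20,
    dimnames = dimnames(m)), mark = "H3K27me3")
  cl1 <- cluster_promoters(k4, k27, k = 2, seed = 42)
  cl2 <- cluster_promoters(k4, k27, k = 2, seed = 42)
  expect_identical(cl1, cl2)
  truth <- rep(1:2, each = 50)
  expect_equal(mclust::adjustedRandIndex(cl1, truth), 1)
  expect_error(cluster_promoters(k4, k27, k = 200, seed = 1), "exceeds")
})

test_that("identical profiles collapse to one cluster with a warning", {
  m <- matrix(1, 30, 10, dimnames = list(sprintf("t%d", 1:30), NULL))
  k4 <- make_signal(m); k27 <- make_signal(m, mark = "H3K27me3")
  expect_warning(cl <- cluster_promoters(k4, k27, k = 2, seed = 1),
                 "identical")
  expect_equal(attr(cl, "k"), 1L)
  expect_true(all(cl == 1))
})

test_that("cluster labeling applies the quantile rule table", {
  # 4 clusters with engineered central K4/K27 levels; the unmarked cluster
  # is the majority, as in the promoter population the rule is designed for
  sizes <- c(15, 20, 15, 50)
  lv_k4 <- rep(c(3, 1.5, 2, 0.1), times = sizes)
  lv_k27 <- rep(c(0.1, 0.1, 2.5, 0.1), times = sizes)
  set.seed(6)
  mk <- function(lv) {
    m <- matrix(stats::rnorm(100 * 20, rep(lv, 20), 0.05), 100, 20)
    rownames(m) <- sprintf("t%03d", 1:100)
    pmax(m, 0)
  }
  k4 <- make_signal(mk(lv_k4)); k27 <- make_signal(mk(lv_k27),
                                                   mark = "H3K27me3")
  cl <- stats::setNames(rep(1:4, times = sizes), rownames(k4$signal))
  asg <- label_clusters(cl, k4, k27)
  lab <- unique(asg[, c("cluster_id", "state_label")])
  expect_equal(as.character(lab$state_label[order(lab$cluster_id)]),
               c("high_K4", "low_K4", "bivalent", "K4minus_K27minus"))
  expect_error(label_clusters(cl[0], k4, k27))
})

test_that("raising K4 never demotes a cluster below its label", {
  s <- default_sperm_signal()
  a <- default_assignment("lincRNA", k = 3)
  k4 <- subset_signal(s$k4, a$ids); k27 <- subset_signal(s$k27, a$ids)
  ref <- list(k4 = s$k4, k27 = s$k27)
  asg1 <- label_clusters(a$clusters, k4, k27, reference = ref)
  k4_up <- k4; k4_up$signal <- k4$signal + 1
  asg2 <- label_clusters(a$clusters, k4_up, k27, reference = ref)
  rank_of <- c(K4minus_K27minus = 0, low_K4 = 1, bivalent = 2, high_K4 = 2)
  expect_true(all(rank_of[as.character(asg2$state_label)] >=
                    rank_of[as.character(asg1$state_label)]))
})

test_that("expression tracks chromatin state in sperm and dies under permutation", {
  b <- default_bundle()
  ex <- default_expression()
  a <- default_assignment("lincRNA", k = 3)
  ebs <- expression_by_state(ex$expr, ex$sheet, a$assignment,
                             compartments = "sperm")
  med <- stats::setNames(ebs$summary$median, ebs$summary$state)
  expect_gt(med[["high_K4"]], med[["low_K4"]])
  expect_gt(med[["low_K4"]], med[["K4minus_K27minus"]])
  expect_gt(ebs$spearman, 0.5)
  # permuting the promoter signal against expression kills the correlation
  # (population-wide, n = 1200)
  set.seed(21)
  perm <- full_assignment()
  perm$central_K4 <- sample(perm$central_K4)
  ebs_p <- expression_by_state(ex$expr, ex$sheet, perm,
                               compartments = "sperm")
  expect_lt(abs(ebs_p$spearman), 0.1)
})

test_that("tracing against the sperm matrices reports all clusters maintained", {
  s <- default_sperm_signal()
  a <- default_assignment("lincRNA", k = 3)
  tr <- trace_states(a$assignment,
                     list(sperm2 = list(k4 = s$k4, k27 = s$k27)))
  expect_true(all(tr$status == "maintained"))
  expect_error(trace_states(a$assignment, list()), "missing")
})

test_that("germ-layer tracing matches the planted retention design", {
  b <- default_bundle()
  s <- default_sperm_signal()
  tr <- b$truth
  mats <- list()
  for (comp in c("ectoderm", "heart")) {
    mats[[comp]] <- list(
      k4 = signal_matrix(read_coverage(b$paths$coverage[[comp]]$H3K4me3,
                                       "H3K4me3", comp), s$win),
      k27 = signal_matrix(read_coverage(b$paths$coverage[[comp]]$H3K27me3,
                                        "H3K27me3", comp), s$win))
  }
  for (bt in c("lincRNA", "protein_coding")) {
    a <- default_assignment(bt)
    sp_ids <- tr$transcript_id[tr$gamete_category == "Sp"]
    asg_sp <- a$assignment[a$assignment$transcript_id %in% sp_ids, ]
    res <- trace_states(asg_sp, mats)
    # sperm-specific high/low K4 marks are planted lost, the rest kept
    expected <- ifelse(res$sperm_label %in% c("high_K4", "low_K4"),
                       "lost", "maintained")
    expect_equal(res$status, expected, label = bt)
  }
})
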