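# Hypergeometric machinery against exhaustive enumeration (oracles in
# helper-oracles.R), term enrichment contracts, promoter sequence
# extraction, and the PWM scanner.

test_that("hypergeometric p matches draw-by-draw enumeration at N=20", {
  # enumerate all C(20,6) draws explicitly
  N <- 20; K <- 5; n <- 6; k <- 4
  draws <- utils::combn(N, n)
  overlap <- colSums(draws <= K)  # items 1..K are the annotated set
  p_enum <- mean(overlap >= k)
  expect_equal(hypergeom_test(k, K, n, N), p_enum, tolerance = 1e-12)
})

test_that("hypergeometric p matches the summation oracle for all N <= 25", {
  for (N in c(5, 10, 17, 25)) {
    for (K in seq(0, N, by = 2)) {
      for (n in seq(1, N, by = 3)) {
        for (k in seq(0, min(K, n))) {
          expect_equal(hypergeom_test(k, K, n, N), enum_hyper(k, K, n, N),
                       tolerance = 1e-12,
                       label = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
        }
      }
    }
  }
})

test_that("hypergeometric degenerate cases and argument validation", {
  expect_equal(hypergeom_test(0, 5, 6, 20), 1)       # P(X >= 0)
  expect_equal(hypergeom_test(6, 20, 6, 20), 1)      # K = N forces k = n
  expect_error(hypergeom_test(7, 5, 6, 20), "invalid")
  expect_error(hypergeom_test(2, 25, 6, 20), "invalid")
  # monotone non-increasing in k
  p <- hypergeom_test(0:5, 5, 6, 20)
  expect_true(all(diff(p) <= 0))
})

test_that("term enrichment orders, filters and FDR-adjusts correctly", {
  universe <- sprintf("g%02d", 1:40)
  terms <- list(
    hit = list(name = "fully contained", genes = universe[1:8]),
    part = list(name = "partial", genes = universe[c(1:4, 21:28)]),
    out = list(name = "disjoint", genes = universe[31:40]))
  query <- universe[1:10]
  res <- term_enrichment(query, terms, universe)
  expect_equal(res$term_id[1], "hit")      # smallest p
  expect_false("out" %in% res$term_id)     # k = 0 dropped
  expect_true(all(diff(res$fdr[order(res$p_value)]) >= -1e-15))
  expect_error(term_enrichment(query, terms, character()), "universe")
  expect_error(term_enrichment(c(query, "novel"), terms, universe), "novel")
})

test_that("BH adjustment is the step-up procedure (monotone after sorting)", {
  set.seed(10)
  p <- stats::runif(50)^2
  res <- term_enrichment(
    sprintf("g%d", 1:5),
    stats::setNames(lapply(1:3, function(i)
      list(name = "t", genes = sprintf("g%d", i:(i + 6)))),
      c("a", "b", "c")),
    sprintf("g%d", 1:50))
  expect_true(all(res$fdr >= res$p_value - 1e-15))
})

test_that("promoter sequences extract by strand with the slice oracle", {
  set.seed(12)
  chr <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
               collapse = "")
  genome <- Biostrings::DNAStringSet(c(chrT = chr))
  tx <- data.frame(transcript_id = c("p", "m"), gene_id = c("p", "m"),
                   biotype = "lincRNA", chrom = "chrT",
                   start = c(600, 100), end = c(800, 1001),
                   strand = c("+", "-"), tss = c(600, 1000),
                   stringsAsFactors = FALSE)
  seqs <- extract_promoter_seqs(tx, genome, flank = 50)
  expect_equal(seqs[["p"]], substr(chr, 551, 650))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(chr, 951, 1050))))
  expect_equal(seqs[["m"]], rc)
  # random-coordinate slice oracle on the plus strand
  for (tss in sample(200:1800, 5)) {
    tx1 <- tx[1, ]; tx1$tss <- tss; tx1$start <- tss; tx1$end <- tss + 10
    expect_equal(unname(extract_promoter_seqs(tx1, genome, flank = 20)),
                 substr(chr, tss - 19, tss + 20))
  }
  tx_bad <- tx; tx_bad$chrom <- "chrMissing"
  expect_error(extract_promoter_seqs(tx_bad, genome), "chrMissing")
})

test_that("a background-equal PWM yields no hits at a positive threshold", {
  pwm <- matrix(0.25, 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL))
  hits <- scan_pwm(c(s1 = "ACGTACGTACGTACGT"), pwm)
  expect_equal(nrow(hits), 0)
})

test_that("a consensus PWM finds exactly the planted occurrence", {
  cons <- "ACGGTCAT"  # not reverse-complement palindromic
  pwm <- matrix(0.02, 4, 8, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in 1:8) pwm[substr(cons, j, j), j] <- 0.94
  seq <- paste0(strrep("T", 20), cons, strrep("T", 20))
  hits <- scan_pwm(c(s = seq), pwm)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$offset, 20)
  expect_equal(hits$strand, "+")
  # reverse-complementing the sequence moves the hit to the minus strand
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  hits_rc <- scan_pwm(c(s = rc), pwm)
  expect_equal(nrow(hits_rc), 1)
  expect_equal(hits_rc$strand, "-")
  expect_equal(hits_rc$offset, 20)  # symmetric layout: same forward offset
  # prepending background bases shifts offsets by exactly that length
  hits_shift <- scan_pwm(c(s = paste0(strrep("T", 7), seq)), pwm)
  expect_equal(hits_shift$offset, 27)
  # N bases score as background: consensus with N still reaches threshold
  seqN <- paste0(strrep("T", 20), sub("G", "N", cons), strrep("T", 20))
  expect_equal(nrow(scan_pwm(c(s = seqN), pwm, score_fraction = 0.7)), 1)
})

test_that("motif enrichment: planted single hit has the enumerable p-value", {
  cons <- "ACGGTCAT"
  pwm <- matrix(0.02, 4, 8, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in 1:8) pwm[substr(cons, j, j), j] <- 0.94
  fg <- c(f1 = paste0(strrep("T", 10), cons, strrep("T", 10)))
  bg <- stats::setNames(rep(strrep("T", 28), 100), sprintf("b%03d", 1:100))
  res <- motif_enrichment(fg, bg, list(M = pwm))
  # k = K = n = 1, N = 101: P = n/N = 1/101
  expect_equal(res$p_value, 1 / 101, tolerance = 1e-12)
  expect_error(motif_enrichment(fg, bg, list()), "empty PWM")
  expect_error(motif_enrichment(character(), bg, list(M = pwm)), "non-empty")
})

test_that("identical foreground and background show no enriched motif", {
  ms <- simulate_motif_sets(n_fg = 60, n_bg = 60, frac_fg = 0.3,
                            frac_bg = 0.3, seed = 19)
  res <- motif_enrichment(ms$fg, ms$bg[seq_along(ms$fg)], ms$pwms)
  expect_false(any(res$fdr < 0.05))
})

test_that("TF-target correlation matches direct computation", {
  tf <- c(1, 3, 5, 7)
  targets <- rbind(c(2, 4, 6, 8), c(0, 1, 2, 3))
  expect_equal(tf_target_correlation(tf, targets),
               stats::cor(tf, colMeans(targets), method = "spearman"))
})
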