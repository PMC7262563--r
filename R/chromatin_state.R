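# Promoter chromatin-state analysis: +/-10 kb binned H3K4me3/H3K27me3 signal
# matrices around the TSS, k-means clustering of the concatenated standardized
# profiles, quantile-based state labeling (high-K4 / low-K4 / bivalent /
# K4-K27-), and tracing of state persistence across compartments.

#' Build promoter windows around each TSS
#'
#' Windows span `[tss - flank, tss + flank)`; bin index increases in the
#' direction of transcription, so for minus-strand transcripts bin 0 covers
#' the most downstream genomic bin. Windows overhanging the chromosome start
#' are kept; out-of-range bins are flagged via `clipped_bins` and filled with
#' zero signal.
#'
#' @param transcripts Transcript table (see [read_annotation()]).
#' @param flank Half-window in bp (default 10 kb).
#' @param bin_size Bin width in bp; `2*flank` must be divisible by it.
#' @return data.frame: `transcript_id`, `chrom`, `window_start`,
#'   `window_end`, `strand`, `bins`, `bin_size`, `tss`, `clipped_bins`.
#' @export
promoter_windows <- function(transcripts, flank = 10000, bin_size = 100) {
  if (flank <= 0) stopf("flank must be positive")
  if ((2 * flank) %% bin_size != 0)
    stopf("2*flank must be divisible by bin_size")
  bins <- as.integer(2 * flank / bin_size)
  ws <- transcripts$tss - flank
  out <- data.frame(
    transcript_id = transcripts$transcript_id,
    chrom = transcripts$chrom,
    window_start = ws,
    window_end = transcripts$tss + flank,
    strand = transcripts$strand,
    bins = bins,
    bin_size = as.integer(bin_size),
    tss = transcripts$tss,
    clipped_bins = pmax(0L, as.integer(ceiling(pmax(0, -ws) / bin_size))),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Bin coverage over promoter windows into a normalized signal matrix
#'
#' Per bin: the mean interval value over the bin (uncovered bases count as
#' zero), scaled to counts-per-million by `1e6 / library_size`, then
#' `log2(1 + x)`. Rows of minus-strand windows are reversed so bins run in
#' the transcription direction.
#'
#' @param track A `coverage_track` (see [read_coverage()]).
#' @param windows Window table from [promoter_windows()].
#' @return A `promoter_signal` list: `mark`, `compartment`, `signal`
#'   (transcripts x bins matrix), `windows`, `normalization = "cpm_log2"`.
#' @export
signal_matrix <- function(track, windows) {
  stopifnot(inherits(track, "coverage_track"))
  if (track$library_size <= 0)
    stopf("cannot normalize: coverage track has zero library size")
  nb <- windows$bins[1]
  bw <- windows$bin_size[1]
  stopifnot(all(windows$bins == nb), all(windows$bin_size == bw))
  n <- nrow(windows)
  sig <- matrix(0, n, nb, dimnames = list(windows$transcript_id, NULL))
  iv <- track$intervals
  for (chr in unique(windows$chrom)) {
    wsel <- which(windows$chrom == chr)
    isel <- iv$chrom == chr
    if (!any(isel)) next
    civ <- iv[isel, , drop = FALSE]
    # genomic-orientation bins for every window on this chromosome
    bin_start <- rep(windows$window_start[wsel], each = nb) +
      rep((seq_len(nb) - 1L) * bw, length(wsel))
    ok <- bin_start + bw > 0  # bins fully before base 0 stay zero
    q <- IRanges::IRanges(start = pmax(bin_start[ok], 0) + 1L,
                          end = bin_start[ok] + bw)
    s <- IRanges::IRanges(start = civ$start + 1L, end = civ$end)
    hits <- IRanges::findOverlaps(q, s)
    if (length(hits)) {
      qh <- S4Vectors::queryHits(hits)
      sh <- S4Vectors::subjectHits(hits)
      ov <- pmin(BiocGenerics::end(q)[qh], BiocGenerics::end(s)[sh]) -
        pmax(BiocGenerics::start(q)[qh], BiocGenerics::start(s)[sh]) + 1L
      sums <- rep(0, sum(ok))
      acc <- tapply(ov * civ$value[sh], qh, sum)
      sums[as.integer(names(acc))] <- acc
      full <- rep(0, length(wsel) * nb)
      full[ok] <- sums / bw
      m <- matrix(full, nrow = length(wsel), ncol = nb, byrow = TRUE)
      sig[wsel, ] <- m
    }
  }
  sig <- log2(1 + sig * 1e6 / track$library_size)
  flip <- windows$strand == "-"
  if (any(flip)) sig[flip, ] <- sig[flip, nb:1, drop = FALSE]
  structure(list(mark = track$mark, compartment = track$compartment,
                 signal = sig, windows = windows,
                 normalization = "cpm_log2"),
            class = "promoter_signal")
}

#' @export
print.promoter_signal <- function(x, ...) {
  cat(sprintf("<promoter_signal> %s / %s: %d transcripts x %d bins (%s)\n",
              x$mark, x$compartment, nrow(x$signal), ncol(x$signal),
              x$normalization))
  invisible(x)
}

# k-means++-style initialization: spread starting centers by sampling
# points with probability proportional to squared distance from the chosen set
.kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1)
  centers[1, ] <- x[idx, ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in seq_len(k - 1)) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx <- sample.int(n, 1, prob = p)
    centers[j + 1, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j + 1, ])^2))
  }
  centers
}

.kmeans_seeded <- function(x, k, n_init = 10, max_iter = 300) {
  best <- NULL
  for (r in seq_len(n_init)) {
    init <- .kmeanspp_init(x, k)
    init <- init[!duplicated(init), , drop = FALSE]
    fit <- suppressWarnings(
      stats::kmeans(x, centers = init, iter.max = max_iter,
                    algorithm = "Lloyd"))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best
}

#' Cluster promoters on concatenated H3K4me3/H3K27me3 profiles
#'
#' k-means (Lloyd, k-means++-style initialization, `n_init` restarts,
#' seed-deterministic) on the per-transcript vector `[K4 bins || K27 bins]`
#' after per-bin standardization. With `k = "auto"`, k in `k_range` is chosen
#' to maximize the mean silhouette width on a subsample.
#'
#' @param k4,k27 `promoter_signal` objects sharing transcript ids.
#' @param k Integer number of clusters, or `"auto"`.
#' @param seed RNG seed for initialization and subsampling.
#' @param k_range Candidate k values for auto selection.
#' @param n_init Number of k-means restarts.
#' @param max_iter Lloyd iteration cap.
#' @param subsample Max rows used for silhouette evaluation.
#' @return Integer cluster ids named by transcript id, with attributes `k`
#'   and (in auto mode) `silhouette` (named vector of mean widths).
#' @export
cluster_promoters <- function(k4, k27, k = "auto", seed = 1,
                              k_range = 2:6, n_init = 10, max_iter = 300,
                              subsample = 500) {
  stopifnot(inherits(k4, "promoter_signal"), inherits(k27, "promoter_signal"))
  ids <- rownames(k4$signal)
  if (!identical(ids, rownames(k27$signal)))
    stopf("K4 and K27 matrices must share transcript ids in order")
  x <- cbind(k4$signal, k27$signal)
  n <- nrow(x)
  sds <- apply(x, 2, stats::sd)
  mns <- colMeans(x)
  x <- sweep(x, 2, mns)
  # per-bin standardization with a variance floor: bins whose spread is far
  # below the typical bin (flank bins carrying only background noise) are
  # scaled by the mean bin sd instead of their own, so near-constant bins do
  # not get noise-amplified to unit variance and drown the informative bins
  floor_sd <- mean(sds)
  scale <- pmax(sds, floor_sd)
  if (all(scale == 0)) scale[] <- 1
  x <- sweep(x, 2, scale, "/")
  if (all(stats::dist(x[seq_len(min(n, 50)), , drop = FALSE]) == 0) &&
      nrow(unique(x)) == 1) {
    warning("all promoter profiles identical; returning a single cluster",
            call. = FALSE)
    out <- stats::setNames(rep(1L, n), ids)
    attr(out, "k") <- 1L
    return(out)
  }
  with_seed(seed, {
    sil <- NULL
    if (identical(k, "auto")) {
      sub <- if (n > subsample) sort(sample.int(n, subsample)) else seq_len(n)
      d <- stats::dist(x[sub, , drop = FALSE])
      sil <- vapply(k_range, function(kk) {
        if (kk >= length(sub)) return(-Inf)
        fit <- .kmeans_seeded(x[sub, , drop = FALSE], kk, n_init, max_iter)
        mean(cluster::silhouette(fit$cluster, d)[, "sil_width"])
      }, 0)
      names(sil) <- as.character(k_range)
      k <- k_range[which.max(sil)]
    }
    k <- as.integer(k)
    if (k > n) stopf("k = %d exceeds number of transcripts (%d)", k, n)
    if (k < 1) stopf("k must be >= 1")
    fit <- .kmeans_seeded(x, k, n_init, max_iter)
  })
  out <- stats::setNames(as.integer(fit$cluster), ids)
  attr(out, "k") <- k
  if (!is.null(sil)) attr(out, "silhouette") <- sil
  out
}

# Central-window bin indices (in transcription orientation the central bins
# are symmetric around the TSS, so orientation does not matter)
.central_bins <- function(nb, bin_size, central_bp) {
  half <- central_bp / (2 * bin_size)
  lo <- floor(nb / 2 - half) + 1L
  hi <- ceiling(nb / 2 + half)
  seq(max(1L, lo), min(nb, hi))
}

#' Subset a promoter signal matrix to a set of transcripts
#' @param sigmat A `promoter_signal`.
#' @param ids Transcript ids to keep (order preserved).
#' @return A `promoter_signal` over the requested transcripts.
#' @export
subset_signal <- function(sigmat, ids) {
  miss <- setdiff(ids, rownames(sigmat$signal))
  if (length(miss)) stopf("transcripts absent from signal matrix: %s",
                          paste(utils::head(miss, 5), collapse = ", "))
  sigmat$signal <- sigmat$signal[ids, , drop = FALSE]
  sigmat$windows <- sigmat$windows[
    match(ids, sigmat$windows$transcript_id), , drop = FALSE]
  sigmat
}

#' Per-transcript mean signal over the central promoter window
#' @param sigmat A `promoter_signal`.
#' @param central_bp Width of the central window in bp (default 2 kb).
#' @return Named numeric vector.
#' @export
central_signal <- function(sigmat, central_bp = 2000) {
  idx <- .central_bins(ncol(sigmat$signal), sigmat$windows$bin_size[1],
                       central_bp)
  rowMeans(sigmat$signal[, idx, drop = FALSE])
}

.label_from_means <- function(k4_mean, k27_mean, thr) {
  if (k4_mean >= thr["k4_mid"] && k27_mean >= thr["k27_high"]) "bivalent"
  else if (k4_mean >= thr["k4_high"]) "high_K4"
  else if (k4_mean >= thr["k4_mid"]) "low_K4"
  else "K4minus_K27minus"
}

.state_thresholds <- function(central_k4, central_k27,
                              q_mid = 0.5, q_high = 0.75) {
  c(k4_mid = unname(stats::quantile(central_k4, q_mid)),
    k4_high = unname(stats::quantile(central_k4, q_high)),
    k27_high = unname(stats::quantile(central_k27, q_high)))
}

#' Label promoter clusters as chromatin states
#'
#' Per cluster, the mean central (default 2 kb) signal of each mark is
#' compared with promoter-wide quantile thresholds: bivalent if K4 is above
#' its median and K27 above its upper quartile; otherwise high-K4 / low-K4 by
#' the K4 upper quartile and median; otherwise K4-K27-.
#'
#' @param clusters Cluster id vector from [cluster_promoters()].
#' @param k4,k27 `promoter_signal` objects for the same transcripts.
#' @param central_bp Central window width in bp.
#' @param q_mid,q_high Quantile levels for the mid/high thresholds.
#' @param reference Optional list(`k4`, `k27`) of `promoter_signal` objects
#'   from which the quantile thresholds are computed (defaults to the input
#'   matrices themselves; pass a genome-wide set to label a subset).
#' @return A `chromatin_assignment` data.frame: `transcript_id`,
#'   `cluster_id`, `state_label`, `central_K4`, `central_K27`; cluster-level
#'   means and thresholds as attributes.
#' @export
label_clusters <- function(clusters, k4, k27, central_bp = 2000,
                           q_mid = 0.5, q_high = 0.75, reference = NULL) {
  ids <- names(clusters)
  stopifnot(identical(ids, rownames(k4$signal)),
            identical(ids, rownames(k27$signal)))
  ck4 <- central_signal(k4, central_bp)
  ck27 <- central_signal(k27, central_bp)
  ref_k4 <- if (is.null(reference)) ck4 else
    central_signal(reference$k4, central_bp)
  ref_k27 <- if (is.null(reference)) ck27 else
    central_signal(reference$k27, central_bp)
  thr <- .state_thresholds(ref_k4, ref_k27, q_mid, q_high)
  ks <- sort(unique(clusters))
  if (!length(ks)) stopf("no clusters to label")
  cl_means <- t(vapply(ks, function(cc) {
    sel <- clusters == cc
    if (!any(sel)) stopf("empty cluster %s", cc)
    c(k4 = mean(ck4[sel]), k27 = mean(ck27[sel]))
  }, c(k4 = 0, k27 = 0)))
  labels <- vapply(seq_along(ks), function(i)
    .label_from_means(cl_means[i, "k4"], cl_means[i, "k27"], thr), "")
  out <- data.frame(
    transcript_id = ids,
    cluster_id = as.integer(clusters),
    state_label = factor(labels[match(clusters, ks)], levels = STATE_LEVELS),
    central_K4 = unname(ck4),
    central_K27 = unname(ck27),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "thresholds") <- thr
  attr(out, "cluster_means") <- data.frame(cluster_id = ks, cl_means,
                                           state_label = labels)
  class(out) <- c("chromatin_assignment", "data.frame")
  out
}

#' Summarize expression by chromatin state and correlate with promoter K4
#'
#' @param expr TPM matrix.
#' @param sheet Sample sheet.
#' @param assignment A `chromatin_assignment`.
#' @param compartments Compartments to summarize (default all in sheet).
#' @param cor_compartment Compartment used for the Spearman correlation
#'   between central K4 signal and expression (default `"sperm"`).
#' @return List: `summary` (per state x compartment boxplot statistics of
#'   per-transcript mean log2(TPM+1)) and `spearman` (correlation between
#'   central K4 and expression in `cor_compartment`).
#' @export
expression_by_state <- function(expr, sheet, assignment,
                                compartments = NULL,
                                cor_compartment = "sperm") {
  compartments <- compartments %||% unique(sheet$compartment)
  common <- intersect(rownames(expr), assignment$transcript_id)
  st <- assignment$state_label[match(common, assignment$transcript_id)]
  rows <- list()
  for (comp in compartments) {
    cols <- sheet$sample_id[sheet$compartment == comp]
    if (!length(cols)) next
    v <- rowMeans(log2p1(expr[common, cols, drop = FALSE]))
    for (s in levels(st)) {
      sel <- st == s
      if (!any(sel)) next
      q <- stats::quantile(v[sel], c(0.25, 0.5, 0.75), names = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        state = s, compartment = comp, n = sum(sel),
        median = q[2], q1 = q[1], q3 = q[3])
    }
  }
  rho <- NA_real_
  cols <- sheet$sample_id[sheet$compartment == cor_compartment]
  if (length(cols)) {
    v <- rowMeans(log2p1(expr[common, cols, drop = FALSE]))
    ck4 <- assignment$central_K4[match(common, assignment$transcript_id)]
    rho <- stats::cor(ck4, v, method = "spearman")
  }
  list(summary = do.call(rbind, rows), spearman = rho)
}

#' Trace sperm-derived chromatin states across compartments
#'
#' For each sperm cluster and each compartment, the cluster's transcripts are
#' relabeled from that compartment's signal using quantile thresholds
#' recomputed on the compartment's own promoter-wide central signal. Status
#' is `maintained` if the sperm label re-derives, `lost` if the promoters
#' have fallen to `K4minus_K27minus`, and `changed:<label>` otherwise.
#'
#' @param sperm_assignment A `chromatin_assignment` from sperm signal.
#' @param compartment_matrices Named list: per compartment, a list with
#'   `k4` and `k27` `promoter_signal` objects. These may cover a superset of
#'   the assignment's transcripts; thresholds use all rows.
#' @param central_bp,q_mid,q_high As in [label_clusters()].
#' @return data.frame: `cluster_id`, `sperm_label`, `compartment`,
#'   `new_label`, `status`, `central_K4`, `central_K27`.
#' @export
trace_states <- function(sperm_assignment, compartment_matrices,
                         central_bp = 2000, q_mid = 0.5, q_high = 0.75) {
  bad <- vapply(compartment_matrices, function(m)
    !all(c("k4", "k27") %in% names(m)), TRUE)
  if (any(bad) || !length(compartment_matrices))
    stopf("missing k4/k27 matrices for compartment(s): %s",
          paste(if (length(compartment_matrices))
            names(compartment_matrices)[bad] else "<none>", collapse = ", "))
  cl_tab <- unique(sperm_assignment[, c("cluster_id", "state_label")])
  rows <- list()
  for (comp in names(compartment_matrices)) {
    m <- compartment_matrices[[comp]]
    ck4 <- central_signal(m$k4, central_bp)
    ck27 <- central_signal(m$k27, central_bp)
    thr <- .state_thresholds(ck4, ck27, q_mid, q_high)
    for (i in seq_len(nrow(cl_tab))) {
      cid <- cl_tab$cluster_id[i]
      tx <- sperm_assignment$transcript_id[sperm_assignment$cluster_id == cid]
      tx <- intersect(tx, names(ck4))
      if (!length(tx))
        stopf("compartment '%s' matrices lack cluster %d transcripts",
              comp, cid)
      mk4 <- mean(ck4[tx]); mk27 <- mean(ck27[tx])
      new_label <- .label_from_means(mk4, mk27, thr)
      sperm_label <- as.character(cl_tab$state_label[i])
      status <- if (new_label == sperm_label) "maintained"
        else if (new_label == "K4minus_K27minus") "lost"
        else paste0("changed:", new_label)
      rows[[length(rows) + 1]] <- data.frame(
        cluster_id = cid, sperm_label = sperm_label, compartment = comp,
        new_label = new_label, status = status,
        central_K4 = mk4, central_K27 = mk27, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
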