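# Over-representation machinery: one-sided hypergeometric term enrichment
# with Benjamini-Hochberg FDR, promoter sequence extraction, and a generic
# PWM log-odds scanner with binary promoter-hit motif enrichment.

#' One-sided hypergeometric over-representation p-value
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of drawing at
#' least `k` annotated genes when `n` genes are drawn from a universe of `N`
#' containing `K` annotated ones.
#'
#' @param k Observed overlap.
#' @param K Annotated-set size.
#' @param n Query size.
#' @param N Universe size.
#' @return p-value in (0, 1]. Vectorized over its arguments.
#' @export
hypergeom_test <- function(k, K, n, N) {
  bad <- k < 0 | K < 0 | n < 0 | N < 0 | k > pmin(K, n) | K > N | n > N
  if (any(bad)) stopf("invalid hypergeometric arguments (need 0 <= k <= min(K, n) <= N)")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Term over-representation for a query gene set
#'
#' Tests each term's gene set (intersected with the universe) against the
#' query by [hypergeom_test()]. BH-FDR is computed across all terms with a
#' nonempty universe intersection; terms with zero query overlap are then
#' dropped from the report. The conventional report filter is `p < 0.05`;
#' both raw p and FDR are emitted so callers can apply either.
#'
#' @param query Character vector of query genes (must lie in `universe`).
#' @param terms Term list from [read_gmt()].
#' @param universe Character vector of background genes.
#' @return data.frame: `term_id`, `term_name`, `k`, `K`, `n`, `N`,
#'   `p_value`, `fdr`, sorted by p-value.
#' @export
term_enrichment <- function(query, terms, universe) {
  universe <- unique(universe)
  if (!length(universe)) stopf("empty universe")
  query <- unique(query)
  out_q <- setdiff(query, universe)
  if (length(out_q)) stopf("query genes outside the universe: %s",
                           paste(utils::head(out_q, 5), collapse = ", "))
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(terms), function(id) {
    genes <- intersect(terms[[id]]$genes, universe)
    K <- length(genes)
    if (K == 0) return(NULL)
    k <- length(intersect(genes, query))
    data.frame(term_id = id, term_name = terms[[id]]$name,
               k = k, K = K, n = n, N = N,
               p_value = hypergeom_test(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) return(data.frame(term_id = character(), term_name = character(),
                                      k = integer(), K = integer(), n = integer(),
                                      N = integer(), p_value = numeric(),
                                      fdr = numeric()))
  res$fdr <- stats::p.adjust(res$p_value, method = "BH")
  res <- res[res$k >= 1, , drop = FALSE]
  res <- res[order(res$p_value), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Extract promoter sequences around each TSS
#'
#' Returns the `[tss - flank, tss + flank)` genomic sequence for each
#' transcript, reverse-complemented for minus-strand transcripts so all
#' promoters read in the transcription direction.
#'
#' @param transcripts Transcript table.
#' @param genome A `DNAStringSet` (named by chromosome) or FASTA path.
#' @param flank Half-window in bp (default 250, i.e. +/-250 bp promoters).
#' @return Named character vector of sequences (names = transcript ids).
#' @export
extract_promoter_seqs <- function(transcripts, genome, flank = 250) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  miss <- setdiff(unique(transcripts$chrom), names(genome))
  if (length(miss)) stopf("chromosome(s) missing from genome: %s",
                          paste(miss, collapse = ", "))
  seqs <- vapply(seq_len(nrow(transcripts)), function(i) {
    chrom <- transcripts$chrom[i]
    s0 <- transcripts$tss[i] - flank      # 0-based half-open
    e0 <- transcripts$tss[i] + flank
    if (s0 < 0 || e0 > length(genome[[chrom]]))
      stopf("promoter window of %s out of chromosome range",
            transcripts$transcript_id[i])
    x <- Biostrings::subseq(genome[[chrom]], s0 + 1, e0)
    if (transcripts$strand[i] == "-")
      x <- Biostrings::reverseComplement(x)
    as.character(x)
  }, "")
  stats::setNames(seqs, transcripts$transcript_id)
}

# Log-odds matrix (log2 p/background); rows A,C,G,T plus an all-zero N row
.pwm_logodds <- function(pwm, background) {
  m <- if (inherits(pwm, "pwm")) pwm$matrix else pwm
  if (abs(sum(m[, 1]) - 1) > 1e-6) stopf("PWM columns must sum to 1")
  lo <- log2(m / background)
  rbind(lo, N = 0)
}

.encode_seq <- function(seq) {
  v <- strsplit(toupper(seq), "")[[1]]
  i <- match(v, c("A", "C", "G", "T"))
  i[is.na(i)] <- 5L  # N and anything else scores as background
  i
}

.revcomp_chr <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Scan sequences with a PWM on both strands
#'
#' Scores every offset with the log2 odds of the PWM against a background
#' base composition; positions with `N` contribute zero. A hit is any offset
#' whose score reaches `score_fraction` of the maximum attainable score.
#' Offsets are 0-based in forward-sequence coordinates on both strands.
#'
#' @param seqs Named character vector of sequences (A/C/G/T/N).
#' @param pwm A `pwm` object or 4 x L probability matrix.
#' @param background Background base probabilities (A, C, G, T).
#' @param score_fraction Fraction of the maximum attainable score required.
#' @return data.frame: `sequence_id`, `offset`, `strand`, `score`.
#' @export
scan_pwm <- function(seqs, pwm, background = rep(0.25, 4),
                     score_fraction = 0.8) {
  lo <- .pwm_logodds(pwm, background)
  L <- ncol(lo)
  max_score <- sum(apply(lo[1:4, , drop = FALSE], 2, max))
  # an uninformative PWM (max attainable log-odds <= 0) admits no positive
  # hit threshold, so it can never produce hits
  if (max_score <= 0)
    return(data.frame(sequence_id = character(), offset = integer(),
                      strand = character(), score = numeric()))
  cutoff <- score_fraction * max_score
  if (is.null(names(seqs)))
    names(seqs) <- sprintf("seq%04d", seq_along(seqs))
  hits <- list()
  score_strand <- function(enc, len) {
    n_off <- len - L + 1L
    if (n_off < 1) return(numeric())
    idx <- outer(seq_len(n_off) - 1L, seq_len(L), "+")  # 1-based positions
    base <- matrix(enc[idx], n_off, L)
    rowSums(matrix(lo[cbind(as.vector(base), rep(seq_len(L), each = n_off))],
                   n_off, L))
  }
  for (id in names(seqs)) {
    s <- seqs[[id]]
    len <- nchar(s)
    if (len < L) next
    fs <- score_strand(.encode_seq(s), len)
    fwd <- which(fs >= cutoff)
    rs <- score_strand(.encode_seq(.revcomp_chr(s)), len)
    rev <- which(rs >= cutoff)
    if (length(fwd))
      hits[[length(hits) + 1]] <- data.frame(
        sequence_id = id, offset = fwd - 1L, strand = "+",
        score = fs[fwd], stringsAsFactors = FALSE)
    if (length(rev))
      hits[[length(hits) + 1]] <- data.frame(
        sequence_id = id, offset = len - L - (rev - 1L), strand = "-",
        score = rs[rev], stringsAsFactors = FALSE)
  }
  if (!length(hits))
    return(data.frame(sequence_id = character(), offset = integer(),
                      strand = character(), score = numeric()))
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' Motif over-representation in foreground vs background promoters
#'
#' Counts promoters with at least one hit (binary, HOMER-style known-motif
#' framing) and tests foreground enrichment by [hypergeom_test()] over the
#' combined universe, with BH-FDR across PWMs.
#'
#' @param fg,bg Named character vectors of foreground / background sequences.
#' @param pwms Named list of PWMs.
#' @param background Background base probabilities for scoring.
#' @param score_fraction Hit threshold as a fraction of the max score.
#' @return data.frame: `pwm`, `k` (foreground promoters hit), `K` (universe
#'   promoters hit), `n`, `N`, `p_value`, `fdr`, sorted by p-value.
#' @export
motif_enrichment <- function(fg, bg, pwms, background = rep(0.25, 4),
                             score_fraction = 0.8) {
  if (!length(fg) || !length(bg)) stopf("foreground and background must be non-empty")
  if (!length(pwms)) stopf("empty PWM list")
  if (is.null(names(fg))) names(fg) <- sprintf("fg%04d", seq_along(fg))
  if (is.null(names(bg))) names(bg) <- sprintf("bg%04d", seq_along(bg))
  n <- length(fg)
  N <- n + length(bg)
  rows <- lapply(names(pwms), function(nm) {
    h_fg <- scan_pwm(fg, pwms[[nm]], background, score_fraction)
    h_bg <- scan_pwm(bg, pwms[[nm]], background, score_fraction)
    k <- length(unique(h_fg$sequence_id))
    K <- k + length(unique(h_bg$sequence_id))
    data.frame(pwm = nm, k = k, K = K, n = n, N = N,
               p_value = if (K == 0) 1 else hypergeom_test(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$fdr <- stats::p.adjust(res$p_value, method = "BH")
  res <- res[order(res$p_value), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Spearman correlation between a TF's stage profile and its targets' mean
#' trajectory
#'
#' @param tf_profile Numeric vector of the transcription factor's stage means.
#' @param target_profiles Matrix of target stage means (targets x stages).
#' @return Spearman correlation coefficient.
#' @export
tf_target_correlation <- function(tf_profile, target_profiles) {
  if (is.null(dim(target_profiles)))
    target_profiles <- matrix(target_profiles, nrow = 1)
  if (length(tf_profile) != ncol(target_profiles))
    stopf("profile lengths differ")
  stats::cor(tf_profile, colMeans(target_profiles), method = "spearman")
}
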