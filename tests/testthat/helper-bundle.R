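# Shared fixtures, generated once per test session and cached.
# The default bundle is the study condition every recovery test runs under:
# 1200 transcripts, seed 7, zero dropout.

.fixtures <- new.env(parent = emptyenv())

default_bundle <- function() {
  if (is.null(.fixtures$bundle)) {
    .fixtures$bundle <- simulate_bundle(sim_config(),
                                        dir = file.path(tempdir(), "gt_bundle"))
  }
  .fixtures$bundle
}

# Expression + sheet of the default bundle
default_expression <- function() {
  if (is.null(.fixtures$expr)) {
    b <- default_bundle()
    .fixtures$expr <- read_expression(b$paths$expression, b$paths$samples)
  }
  .fixtures$expr
}

# Genome-wide sperm signal matrices of the default bundle
default_sperm_signal <- function() {
  if (is.null(.fixtures$sig)) {
    b <- default_bundle()
    tx <- read_annotation(b$paths$annotation)
    win <- promoter_windows(tx)
    .fixtures$sig <- list(
      tx = tx,
      win = win,
      k4 = signal_matrix(read_coverage(b$paths$coverage$sperm$H3K4me3,
                                       "H3K4me3", "sperm"), win),
      k27 = signal_matrix(read_coverage(b$paths$coverage$sperm$H3K27me3,
                                        "H3K27me3", "sperm"), win))
  }
  .fixtures$sig
}

# Per-biotype chromatin assignment on the Sp/SpOc subset, genome-wide
# quantile reference (the pipeline's own construction)
default_assignment <- function(biotype, k = "auto") {
  key <- paste0("asg_", biotype, "_", k)
  if (is.null(.fixtures[[key]])) {
    b <- default_bundle()
    s <- default_sperm_signal()
    tr <- b$truth
    ids <- s$tx$transcript_id[s$tx$biotype == biotype &
                                tr$gamete_category %in% c("Sp", "SpOc")]
    cl <- cluster_promoters(subset_signal(s$k4, ids),
                            subset_signal(s$k27, ids), k = k, seed = 7)
    asg <- label_clusters(cl, subset_signal(s$k4, ids),
                          subset_signal(s$k27, ids),
                          reference = list(k4 = s$k4, k27 = s$k27))
    .fixtures[[key]] <- list(ids = ids, clusters = cl, assignment = asg)
  }
  .fixtures[[key]]
}

# Promoter-population-wide pseudo-assignment (all 1200 transcripts): used
# for permutation nulls of the signal-expression correlation, where the
# sampling noise of a small subset would dominate
full_assignment <- function() {
  if (is.null(.fixtures$full_asg)) {
    s <- default_sperm_signal()
    .fixtures$full_asg <- structure(data.frame(
      transcript_id = rownames(s$k4$signal),
      cluster_id = 1L,
      state_label = factor("high_K4",
                           levels = gametrace:::STATE_LEVELS),
      central_K4 = unname(central_signal(s$k4)),
      central_K27 = unname(central_signal(s$k27)),
      stringsAsFactors = FALSE),
      class = c("chromatin_assignment", "data.frame"))
  }
  .fixtures$full_asg
}

read_tsv_file <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                  na.strings = "."))
}

# Tiny transcript table helper
make_tx <- function(n = 3, chrom = "chr1", start = 20000, spacing = 25000,
                    strand = NULL, biotype = "lincRNA") {
  strand <- strand %||% rep(c("+", "-"), length.out = n)
  st <- start + (seq_len(n) - 1) * spacing
  data.frame(
    transcript_id = sprintf("TX%02d", seq_len(n)),
    gene_id = sprintf("GX%02d", seq_len(n)),
    biotype = rep_len(biotype, n),
    chrom = chrom, start = st, end = st + 2000, strand = strand,
    tss = ifelse(strand == "+", st, st + 2000 - 1),
    stringsAsFactors = FALSE)
}

# Build a promoter_signal object directly from a signal matrix (for unit
# tests that need full control of the bin values)
make_signal <- function(mat, bin_size = 100, mark = "H3K4me3",
                        compartment = "sperm") {
  n <- nrow(mat)
  win <- data.frame(
    transcript_id = rownames(mat), chrom = "chr1",
    window_start = 0, window_end = ncol(mat) * bin_size,
    strand = "+", bins = ncol(mat), bin_size = bin_size,
    tss = ncol(mat) * bin_size / 2, clipped_bins = 0L)
  structure(list(mark = mark, compartment = compartment, signal = mat,
                 windows = win, normalization = "cpm_log2"),
            class = "promoter_signal")
}
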