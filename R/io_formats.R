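# Readers and writers for the standard formats the pipeline touches.
#
# All internal coordinates are 0-based half-open; conversions to and from the
# 1-based inclusive conventions of GTF happen only at the parse/serialize
# boundary.

BIOTYPE_LEVELS <- c("lincRNA", "protein_coding", "other_ncRNA")
STATE_LEVELS   <- c("high_K4", "low_K4", "bivalent", "K4minus_K27minus")
MARK_LEVELS    <- c("H3K4me3", "H3K27me3")

#' Default annotation biotype mapping
#'
#' Maps annotation transcript biotypes onto the three-way partition used
#' throughout the pipeline: `lincRNA`, `protein_coding`, and everything else
#' collapsed into `other_ncRNA` so the mapping is total.
#'
#' @return Named character vector; names are annotation biotypes, values are
#'   internal biotypes. Unlisted biotypes map to `other_ncRNA`.
#' @export
default_biotype_map <- function() {
  c(lincRNA = "lincRNA", protein_coding = "protein_coding")
}

map_biotype <- function(x, biotype_map = default_biotype_map()) {
  out <- unname(biotype_map[x])
  out[is.na(out)] <- "other_ncRNA"
  factor(out, levels = BIOTYPE_LEVELS)
}

#' Read transcript records from a GTF annotation
#'
#' Parses `transcript` features from an Ensembl-dialect GTF into a transcript
#' table with 0-based half-open coordinates and the transcription start site
#' (TSS) resolved per strand. Transcripts without a strand are dropped with a
#' warning; malformed lines raise an error naming the line number.
#'
#' @param path Path to a GTF file.
#' @param biotype_map Named character vector mapping annotation biotypes to
#'   the internal three-way partition; unknown biotypes become `other_ncRNA`.
#' @return A `data.frame` with columns `transcript_id`, `gene_id`, `biotype`,
#'   `chrom`, `start`, `end` (0-based half-open), `strand`, `tss`.
#' @export
read_annotation <- function(path, biotype_map = default_biotype_map()) {
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(lines)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9)) {
    bad <- which(keep)[which(nf < 9)[1]]
    stopf("malformed GTF line %d: expected 9 tab-separated columns, got %d",
          bad, nf[which(nf < 9)[1]])
  }
  starts <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L)))
  ends   <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
  if (anyNA(starts) || anyNA(ends)) {
    bad <- which(keep)[which(is.na(starts) | is.na(ends))[1]]
    stopf("malformed GTF line %d: non-numeric coordinates", bad)
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[as.character(gr$type) == "transcript"]
  if (length(gr) == 0) stopf("no transcript features in %s", path)
  strand <- as.character(BiocGenerics::strand(gr))
  unstranded <- strand == "*"
  if (any(unstranded)) {
    warning(sprintf("dropping %d transcript(s) without strand: %s",
                    sum(unstranded),
                    paste(utils::head(gr$transcript_id[unstranded], 5),
                          collapse = ", ")), call. = FALSE)
    gr <- gr[!unstranded]
    strand <- strand[!unstranded]
  }
  bt_col <- intersect(c("transcript_biotype", "gene_biotype", "biotype"),
                      names(S4Vectors::mcols(gr)))
  bt <- if (length(bt_col)) as.character(S4Vectors::mcols(gr)[[bt_col[1]]])
        else rep(NA_character_, length(gr))
  start0 <- BiocGenerics::start(gr) - 1L
  end0   <- BiocGenerics::end(gr)
  out <- data.frame(
    transcript_id = as.character(gr$transcript_id),
    gene_id = as.character(gr$gene_id),
    biotype = map_biotype(bt, biotype_map),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = start0,
    end = end0,
    strand = strand,
    tss = ifelse(strand == "+", start0, end0 - 1L),
    stringsAsFactors = FALSE
  )
  validate_transcripts(out)
  out
}

validate_transcripts <- function(tx) {
  stopifnot(is.data.frame(tx))
  need <- c("transcript_id", "gene_id", "biotype", "chrom", "start", "end",
            "strand", "tss")
  miss <- setdiff(need, names(tx))
  if (length(miss)) stopf("transcript table missing columns: %s",
                          paste(miss, collapse = ", "))
  if (anyDuplicated(tx$transcript_id))
    stopf("duplicate transcript ids in annotation")
  if (any(tx$start >= tx$end)) stopf("transcript with start >= end")
  if (!all(tx$strand %in% c("+", "-"))) stopf("strand must be '+' or '-'")
  exp_tss <- ifelse(tx$strand == "+", tx$start, tx$end - 1L)
  if (any(tx$tss != exp_tss)) stopf("tss inconsistent with strand convention")
  invisible(tx)
}

#' Write a transcript table as GTF
#'
#' @param tx Transcript table as returned by [read_annotation()].
#' @param path Output path.
#' @export
write_annotation <- function(tx, path) {
  validate_transcripts(tx)
  attrs <- sprintf('gene_id "%s"; transcript_id "%s"; transcript_biotype "%s";',
                   tx$gene_id, tx$transcript_id, as.character(tx$biotype))
  lines <- paste(tx$chrom, "gametrace", "transcript",
                 tx$start + 1L, tx$end, ".", tx$strand, ".", attrs,
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a TPM expression matrix and its sample sheet
#'
#' The matrix file is a TSV whose first column is `transcript_id` and whose
#' remaining columns are sample ids; the sheet is a TSV with columns
#' `sample_id`, `organism`, `compartment`, `replicate`. Every matrix column
#' must have exactly one sheet row.
#'
#' @param matrix_path,sheet_path Paths to the two TSVs.
#' @return A list with `expr` (numeric matrix, transcripts x samples) and
#'   `sheet` (data.frame), columns ordered as in the file.
#' @export
read_expression <- function(matrix_path, sheet_path) {
  m <- data.table::fread(matrix_path, sep = "\t", header = TRUE)
  m <- as.data.frame(m)
  if (names(m)[1] != "transcript_id")
    stopf("first column of %s must be 'transcript_id'", matrix_path)
  ids <- as.character(m[[1]])
  expr <- as.matrix(m[, -1, drop = FALSE])
  storage.mode(expr) <- "double"
  rownames(expr) <- ids
  sheet <- read_tsv(sheet_path)
  validate_expression(expr, sheet)
  list(expr = expr, sheet = sheet)
}

validate_expression <- function(expr, sheet) {
  if (anyDuplicated(rownames(expr))) stopf("duplicate transcript ids")
  if (anyDuplicated(colnames(expr))) stopf("duplicate sample ids")
  if (any(!is.finite(expr))) stopf("expression matrix has non-finite values")
  if (any(expr < 0)) stopf("negative TPM values in expression matrix")
  need <- c("sample_id", "organism", "compartment", "replicate")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) stopf("sample sheet missing columns: %s",
                          paste(miss, collapse = ", "))
  if (anyDuplicated(sheet$sample_id)) stopf("duplicate sample ids in sheet")
  absent <- setdiff(colnames(expr), sheet$sample_id)
  if (length(absent))
    stopf("samples in matrix missing from sheet: %s",
          paste(absent, collapse = ", "))
  invisible(TRUE)
}

#' Write an expression matrix and sample sheet
#' @param expr Numeric TPM matrix with transcript ids as rownames.
#' @param sheet Sample sheet data.frame.
#' @param matrix_path,sheet_path Output paths.
#' @export
write_expression <- function(expr, sheet, matrix_path, sheet_path) {
  validate_expression(expr, sheet)
  df <- data.frame(transcript_id = rownames(expr), expr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, matrix_path)
  write_tsv(sheet, sheet_path)
  invisible(c(matrix_path, sheet_path))
}

#' Read a histone ChIP-seq coverage track from bedGraph
#'
#' Intervals are validated to be sorted and non-overlapping within each
#' chromosome; `library_size` is the total signal
#' \eqn{\sum value \cdot (end - start)}, used downstream for counts-per-million
#' scaling.
#'
#' @param path Path to a 4-column bedGraph.
#' @param mark One of `"H3K4me3"`, `"H3K27me3"`.
#' @param compartment Compartment token (e.g. `"sperm"`, `"ectoderm"`).
#' @return A `coverage_track` list: `mark`, `compartment`, `intervals`
#'   (data.frame `chrom`, `start`, `end`, `value`, 0-based half-open),
#'   `library_size`.
#' @export
read_coverage <- function(path, mark, compartment) {
  mark <- match.arg(mark, MARK_LEVELS)
  if (!file.exists(path)) stopf("coverage file not found: %s", path)
  if (file.size(path) == 0) {
    iv <- data.frame(chrom = character(), start = integer(),
                     end = integer(), value = numeric())
    return(new_coverage_track(mark, compartment, iv))
  }
  dt <- data.table::fread(path, sep = "\t", header = FALSE)
  if (ncol(dt) != 4) stopf("%s: expected 4 bedGraph columns, got %d",
                           path, ncol(dt))
  if (!is.numeric(dt[[4]])) stopf("%s: non-numeric coverage value", path)
  iv <- data.frame(chrom = as.character(dt[[1]]), start = as.numeric(dt[[2]]),
                   end = as.numeric(dt[[3]]), value = as.numeric(dt[[4]]))
  new_coverage_track(mark, compartment, iv)
}

new_coverage_track <- function(mark, compartment, intervals) {
  iv <- intervals[order(intervals$chrom, intervals$start), , drop = FALSE]
  rownames(iv) <- NULL
  if (any(iv$value < 0)) stopf("negative coverage values")
  if (any(iv$end <= iv$start)) stopf("coverage interval with end <= start")
  if (nrow(iv) > 1) {
    same <- iv$chrom[-1] == iv$chrom[-nrow(iv)]
    if (any(same & iv$start[-1] < iv$end[-nrow(iv)]))
      stopf("overlapping coverage intervals within a chromosome")
  }
  structure(list(mark = mark, compartment = compartment, intervals = iv,
                 library_size = sum(iv$value * (iv$end - iv$start))),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %s / %s: %d intervals, library_size %.4g\n",
              x$mark, x$compartment, nrow(x$intervals), x$library_size))
  invisible(x)
}

#' Write a coverage track as bedGraph
#' @param track A `coverage_track`.
#' @param path Output path.
#' @export
write_coverage <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  data.table::fwrite(track$intervals, path, sep = "\t", col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read JASPAR-style position weight matrices
#'
#' Each block is a `>name` header followed by four rows (A, C, G, T) of
#' counts, optionally bracketed. Counts are converted to column-normalized
#' probabilities after adding a pseudocount of 0.5 to every cell.
#'
#' @param path Path to the PWM text file.
#' @param pseudocount Per-cell pseudocount added before normalization.
#' @return A named list of `pwm` objects; each has `name` and `matrix`
#'   (4 x L probabilities, rows A, C, G, T, columns summing to 1).
#' @export
read_pwms <- function(path, pseudocount = 0.5) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (!length(heads)) stopf("no PWM blocks in %s", path)
  out <- list()
  bounds <- c(heads, length(lines) + 1L)
  for (i in seq_along(heads)) {
    name <- sub("^>\\s*", "", lines[heads[i]])
    name <- strsplit(name, "\\s+")[[1]][1]
    body <- lines[(heads[i] + 1L):(bounds[i + 1L] - 1L)]
    if (length(body) != 4)
      stopf("PWM '%s': expected 4 matrix rows, got %d", name, length(body))
    rows <- lapply(body, function(ln) {
      ln <- gsub("^[ACGTacgt]\\s*", "", trimws(ln))
      ln <- gsub("[\\[\\]]", "", ln, perl = TRUE)
      as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
    })
    L <- unique(lengths(rows))
    if (length(L) != 1) stopf("PWM '%s': ragged matrix rows", name)
    if (L < 4) stopf("PWM '%s': length %d < 4", name, L)
    counts <- do.call(rbind, rows)
    rownames(counts) <- c("A", "C", "G", "T")
    if (any(colSums(counts) == 0))
      stopf("PWM '%s': column with zero total count", name)
    counts <- counts + pseudocount
    prob <- sweep(counts, 2, colSums(counts), "/")
    out[[name]] <- structure(list(name = name, matrix = prob), class = "pwm")
  }
  out
}

#' Write PWMs in JASPAR-style count format
#'
#' Probabilities are scaled to counts (x100) for readability; reading them
#' back recovers the same probabilities up to the pseudocount contract.
#'
#' @param pwms List of `pwm` objects or raw 4 x L matrices.
#' @param path Output path.
#' @export
write_pwms <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(pwms)) {
    m <- if (inherits(pwms[[nm]], "pwm")) pwms[[nm]]$matrix else pwms[[nm]]
    writeLines(paste0(">", nm), con)
    for (b in c("A", "C", "G", "T")) {
      writeLines(paste0(b, "  [ ",
                        paste(formatC(m[b, ] * 100, format = "f", digits = 2),
                              collapse = " "), " ]"), con)
    }
  }
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' @param path Path to a GMT file (term id, description, then member genes,
#'   tab-separated).
#' @return A named list of terms; each element is a list with `name`
#'   (description) and `genes` (character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stopf("GMT line %d: fewer than 3 fields", i)
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stopf("GMT line %d: empty gene set '%s'", i, f[1])
    out[[f[1]]] <- list(name = f[2], genes = genes)
  }
  out
}

#' Write gene sets to a GMT file
#' @param terms Named list as returned by [read_gmt()].
#' @param path Output path.
#' @export
write_gmt <- function(terms, path) {
  lines <- vapply(names(terms), function(id) {
    t <- terms[[id]]
    paste(c(id, t$name, t$genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Export promoter windows as BED6
#' @param windows Window table from [promoter_windows()].
#' @param path Output path.
#' @export
write_windows_bed <- function(windows, path) {
  bed <- data.frame(chrom = windows$chrom,
                    start = pmax(0, windows$window_start),
                    end = windows$window_end,
                    name = windows$transcript_id,
                    score = 0L,
                    strand = windows$strand)
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}
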