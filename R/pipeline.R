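# End-to-end orchestration: a single run configuration, per-stage entry
# points that communicate through documented TSVs (inspectability, partial
# reruns), and a run manifest with content hashes. The command-line wrapper
# in inst/scripts/gametrace exposes each stage as a subcommand.

log_line <- function(level, fmt, ...) {
  message(sprintf("%s\t%s\t%s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  level, sprintf(fmt, ...)))
}

#' Build a pipeline run configuration
#'
#' @param annotation GTF path.
#' @param expression,samples Expression matrix / sample sheet TSV paths.
#' @param coverage Named list: per compartment, a list with `H3K4me3` and
#'   `H3K27me3` bedGraph paths. Must include `sperm`; additional
#'   compartments are traced for state persistence.
#' @param pwms,gmt PWM / GMT paths (optional; enable the enrichment stage).
#' @param fg_fasta,bg_fasta Foreground/background promoter FASTAs for motif
#'   enrichment (optional).
#' @param tumor_expression,tumor_samples Tumor cohort TSV paths (optional;
#'   enable the deregulation stage).
#' @param outdir Output directory.
#' @param organism `"human"` or `"mouse"`.
#' @param seed Seed for the clustering stage.
#' @param threshold Expression threshold (TPM).
#' @param flank,bin_size Promoter window geometry (bp).
#' @param k Cluster count or `"auto"`.
#' @param central_bp,q_mid,q_high State-labeling parameters.
#' @param fold,traj_tol Trajectory-calling parameters.
#' @param lfc_min,alpha Deregulation-call parameters.
#' @return A `run_config` list.
#' @export
run_config <- function(annotation, expression, samples, coverage,
                       pwms = NULL, gmt = NULL, fg_fasta = NULL,
                       bg_fasta = NULL, tumor_expression = NULL,
                       tumor_samples = NULL, outdir,
                       organism = "human", seed = 1, threshold = 1,
                       flank = 10000, bin_size = 100, k = "auto",
                       central_bp = 2000, q_mid = 0.5, q_high = 0.75,
                       fold = 2, traj_tol = 0.1, lfc_min = 1, alpha = 0.05) {
  cfg <- list(annotation = annotation, expression = expression,
              samples = samples, coverage = coverage, pwms = pwms,
              gmt = gmt, fg_fasta = fg_fasta, bg_fasta = bg_fasta,
              tumor_expression = tumor_expression,
              tumor_samples = tumor_samples, outdir = outdir,
              organism = organism, seed = as.integer(seed),
              threshold = threshold, flank = flank, bin_size = bin_size,
              k = k, central_bp = central_bp, q_mid = q_mid,
              q_high = q_high, fold = fold, traj_tol = traj_tol,
              lfc_min = lfc_min, alpha = alpha)
  class(cfg) <- "run_config"
  cfg
}

#' Reconstruct the file map of a bundle directory
#'
#' Inverse of the layout written by [simulate_bundle()]: returns the same
#' `paths` structure from an existing bundle directory, so stages can be
#' driven from files alone.
#'
#' @param dir Bundle directory.
#' @return Named list of paths (`annotation`, `expression`, `samples`,
#'   `coverage` per compartment/mark, `pwms`, `gmt`, FASTAs, tumor TSVs,
#'   `truth` if present).
#' @export
bundle_paths <- function(dir) {
  if (!dir.exists(dir)) stopf("bundle directory not found: %s", dir)
  p <- list(dir = dir,
            annotation = file.path(dir, "annotation.gtf"),
            expression = file.path(dir, "expression.tsv"),
            samples = file.path(dir, "samples.tsv"),
            pwms = file.path(dir, "pwms.txt"),
            fg_fasta = file.path(dir, "promoters_fg.fa"),
            bg_fasta = file.path(dir, "promoters_bg.fa"),
            gmt = file.path(dir, "terms.gmt"),
            tumor_expression = file.path(dir, "tumor_expression.tsv"),
            tumor_samples = file.path(dir, "tumor_samples.tsv"),
            truth = file.path(dir, "truth.tsv"))
  covs <- list.files(file.path(dir, "coverage"), pattern = "\\.bedGraph$",
                     full.names = TRUE)
  p$coverage <- list()
  for (f in covs) {
    parts <- strsplit(sub("\\.bedGraph$", "", basename(f)), "_")[[1]]
    p$coverage[[parts[2]]][[parts[1]]] <- f
  }
  p
}

#' Run configuration wired to a simulated bundle's files
#' @param bundle Result of [simulate_bundle()].
#' @param outdir Output directory.
#' @param ... Parameter overrides passed to [run_config()].
#' @export
bundle_run_config <- function(bundle, outdir, ...) {
  p <- bundle$paths
  cov <- lapply(p$coverage, function(x)
    list(H3K4me3 = x$H3K4me3, H3K27me3 = x$H3K27me3))
  run_config(annotation = p$annotation, expression = p$expression,
             samples = p$samples, coverage = cov, pwms = p$pwms,
             gmt = p$gmt, fg_fasta = p$fg_fasta, bg_fasta = p$bg_fasta,
             tumor_expression = p$tumor_expression,
             tumor_samples = p$tumor_samples, outdir = outdir,
             organism = bundle$config$organism, seed = bundle$config$seed,
             threshold = bundle$config$threshold, ...)
}

#' Validate that a run configuration's inputs exist
#' @param config A `run_config`.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "run_config"))
  paths <- c(config$annotation, config$expression, config$samples,
             unlist(config$coverage), config$pwms, config$gmt,
             config$fg_fasta, config$bg_fasta, config$tumor_expression,
             config$tumor_samples)
  miss <- paths[!file.exists(paths)]
  if (length(miss)) stopf("missing input file(s): %s",
                          paste(miss, collapse = ", "))
  if (is.null(config$coverage$sperm))
    stopf("coverage map must include the 'sperm' compartment")
  if (config$threshold <= 0) stopf("threshold must be > 0")
  if (config$alpha <= 0 || config$alpha >= 1) stopf("alpha must be in (0,1)")
  invisible(TRUE)
}

# --- stages ---------------------------------------------------------------

#' Classification stage: gamete categories from replicate TPM matrices
#' @param config A `run_config`.
#' @return Paths of the written TSVs.
#' @export
stage_classify <- function(config) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  tx <- read_annotation(config$annotation)
  ex <- read_expression(config$expression, config$samples)
  flags <- call_expressed(ex$expr, config$threshold)
  cls <- classify_gamete(flags, ex$sheet)
  cls$biotype <- as.character(
    tx$biotype[match(cls$transcript_id, tx$transcript_id)])
  out <- file.path(config$outdir, "classification.tsv")
  write_tsv(cls, out)
  summ <- category_expression_summary(ex$expr, cls, ex$sheet, tx,
                                      compartments = c("sperm", "oocyte"))
  out2 <- file.path(config$outdir, "category_summary.tsv")
  write_tsv(summ, out2)
  log_line("INFO", "classify: %d transcripts, %d Misc excluded",
           nrow(cls), sum(cls$category == "Misc"))
  c(classification = out, category_summary = out2)
}

#' Chromatin stage: promoter state clustering and persistence tracing
#' @param config A `run_config`.
#' @return Paths of the written TSVs.
#' @export
stage_chromatin <- function(config) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  tx <- read_annotation(config$annotation)
  cls <- read_tsv(file.path(config$outdir, "classification.tsv"))
  keep_ids <- cls$transcript_id[cls$category %in% c("Sp", "SpOc")]
  comps <- names(config$coverage)
  tracks <- lapply(comps, function(comp) list(
    k4 = read_coverage(config$coverage[[comp]]$H3K4me3, "H3K4me3", comp),
    k27 = read_coverage(config$coverage[[comp]]$H3K27me3, "H3K27me3", comp)))
  names(tracks) <- comps
  # genome-wide matrices: quantile thresholds for labeling and tracing are
  # taken over all annotated promoters, not just the clustered subset
  win <- promoter_windows(tx, config$flank, config$bin_size)
  mats <- lapply(tracks, function(tk) list(
    k4 = signal_matrix(tk$k4, win), k27 = signal_matrix(tk$k27, win)))
  assigns <- list(); traces <- list()
  for (bt in c("lincRNA", "protein_coding")) {
    ids <- tx$transcript_id[tx$biotype == bt &
                              tx$transcript_id %in% keep_ids]
    if (length(ids) < 10) next
    k4 <- subset_signal(mats$sperm$k4, ids)
    k27 <- subset_signal(mats$sperm$k27, ids)
    cl <- cluster_promoters(k4, k27, k = config$k, seed = config$seed)
    asg <- label_clusters(cl, k4, k27, config$central_bp,
                          config$q_mid, config$q_high,
                          reference = mats$sperm)
    asg$biotype <- bt
    asg$category <- cls$category[match(asg$transcript_id,
                                       cls$transcript_id)]
    assigns[[bt]] <- asg
    others <- setdiff(comps, "sperm")
    # persistence is traced per gamete category: germ-layer retention
    # differs between sperm-specific and shared promoters, and pooling them
    # would average away category-specific mark loss
    if (length(others)) {
      for (cat in c("Sp", "SpOc")) {
        sub_asg <- asg[asg$category == cat, , drop = FALSE]
        if (!nrow(sub_asg)) next
        tr <- trace_states(sub_asg, mats[others], config$central_bp,
                           config$q_mid, config$q_high)
        tr$biotype <- bt
        tr$category <- cat
        traces[[paste(bt, cat)]] <- tr
      }
    }
    log_line("INFO", "chromatin[%s]: k=%d over %d promoters",
             bt, attr(cl, "k"), length(ids))
  }
  out <- file.path(config$outdir, "chromatin_assignment.tsv")
  write_tsv(do.call(rbind, assigns), out)
  paths <- c(chromatin_assignment = out)
  if (length(traces)) {
    out2 <- file.path(config$outdir, "persistence.tsv")
    write_tsv(do.call(rbind, traces), out2)
    paths <- c(paths, persistence = out2)
  }
  paths
}

#' Dynamics stage: trajectories, Z matrices and panel specificity
#' @param config A `run_config`.
#' @return Paths of the written TSVs.
#' @export
stage_dynamics <- function(config) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  ex <- read_expression(config$expression, config$samples)
  grid <- stage_grid(config$organism)
  sm <- aggregate_stages(ex$expr, ex$sheet, grid)
  traj <- call_trajectory(sm, grid, threshold = config$threshold,
                          fold = config$fold, tol = config$traj_tol)
  z <- zscore_rows(log_transform(sm))
  colnames(z) <- paste0("z_", colnames(z))
  traj <- cbind(traj, as.data.frame(z))
  out <- file.path(config$outdir, "trajectory.tsv")
  write_tsv(traj, out)
  paths <- c(trajectory = out)
  sperma <- stage_grid(config$organism, panel = "spermatogenesis")$stages
  if (all(sperma %in% ex$sheet$compartment)) {
    spec <- panel_specificity(ex$expr, ex$sheet, sperma)
    out2 <- file.path(config$outdir, "panel_specificity.tsv")
    write_tsv(spec, out2)
    paths <- c(paths, panel_specificity = out2)
  }
  log_line("INFO", "dynamics: %d ZGA-activated, %d degraded",
           sum(traj$pattern == "zga_activated"),
           sum(traj$pattern == "early_then_degraded"))
  paths
}

#' Enrichment stage: term and motif over-representation
#' @param config A `run_config`.
#' @return Paths of the written TSVs (empty if no enrichment inputs).
#' @export
stage_enrich <- function(config) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  tx <- read_annotation(config$annotation)
  cls <- read_tsv(file.path(config$outdir, "classification.tsv"))
  if (!is.null(config$gmt)) {
    terms <- read_gmt(config$gmt)
    universe <- unique(tx$gene_id)
    sp_genes <- unique(tx$gene_id[match(
      cls$transcript_id[cls$category == "Sp"], tx$transcript_id)])
    res <- term_enrichment(sp_genes, terms, universe)
    out <- file.path(config$outdir, "term_enrichment.tsv")
    write_tsv(res, out)
    paths <- c(paths, term_enrichment = out)
  }
  if (!is.null(config$pwms) && !is.null(config$fg_fasta) &&
      !is.null(config$bg_fasta)) {
    pwms <- read_pwms(config$pwms)
    fa <- function(p) {
      x <- Biostrings::readDNAStringSet(p)
      stats::setNames(as.character(x), names(x))
    }
    res <- motif_enrichment(fa(config$fg_fasta), fa(config$bg_fasta), pwms)
    out <- file.path(config$outdir, "motif_enrichment.tsv")
    write_tsv(res, out)
    paths <- c(paths, motif_enrichment = out)
  }
  paths
}

#' Tumor stage: deregulation calls and pan-cancer counts
#' @param config A `run_config`.
#' @return Paths of the written TSVs (empty if no tumor inputs).
#' @export
stage_tumor <- function(config) {
  if (is.null(config$tumor_expression)) return(character())
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  ex <- read_expression(config$tumor_expression, config$tumor_samples)
  codes <- sort(unique(sub("^tumor:", "",
                           grep("^tumor:", ex$sheet$compartment,
                                value = TRUE))))
  res <- deregulation_call(ex$expr, ex$sheet, codes,
                           lfc_min = config$lfc_min, alpha = config$alpha)
  out1 <- file.path(config$outdir, "deregulation.tsv")
  out2 <- file.path(config$outdir, "pan_cancer.tsv")
  write_tsv(res$calls, out1)
  write_tsv(res$pan_cancer, out2)
  log_line("INFO", "tumor: %d codes, max pan-cancer count %d",
           length(codes), max(res$pan_cancer$pan_cancer_count))
  c(deregulation = out1, pan_cancer = out2)
}

# --- orchestration --------------------------------------------------------

.write_manifest <- function(outdir, stage_files, failed_stage = NA) {
  files <- unlist(stage_files, use.names = FALSE)
  stage_of <- rep(names(stage_files), lengths(stage_files))
  rows <- data.frame(stage = stage_of, file = basename(files),
                     md5 = unname(tools::md5sum(files)),
                     n_rows = vapply(files, function(f)
                       length(readLines(f, warn = FALSE)) - 1L, 0L),
                     stringsAsFactors = FALSE)
  if (!is.na(failed_stage))
    rows <- rbind(rows, data.frame(stage = failed_stage, file = "<FAILED>",
                                   md5 = NA_character_, n_rows = NA_integer_))
  write_tsv(rows, file.path(outdir, "manifest.tsv"))
}

#' Run the full pipeline from a configuration
#'
#' Executes classify, chromatin, dynamics, enrich and tumor stages in order,
#' writing per-stage TSVs and a manifest with content hashes. A stage
#' failure stops the run with the partial outputs retained and the failed
#' stage recorded in the manifest. Deterministic given the configuration
#' seed: reruns produce byte-identical TSVs.
#'
#' @param config A `run_config`.
#' @return Named vector of output file paths, invisibly.
#' @export
run_all <- function(config) {
  validate_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  cfg_txt <- file.path(config$outdir, "config.txt")
  echo <- unclass(config)
  echo$outdir <- NULL  # keep the echo identical across output locations
  writeLines(utils::capture.output(utils::str(echo)), cfg_txt)
  stages <- list(classify = stage_classify, chromatin = stage_chromatin,
                 dynamics = stage_dynamics, enrich = stage_enrich,
                 tumor = stage_tumor)
  done <- list(config = cfg_txt)
  for (nm in names(stages)) {
    log_line("INFO", "stage %s: start", nm)
    res <- tryCatch(stages[[nm]](config), error = function(e) e)
    if (inherits(res, "error")) {
      .write_manifest(config$outdir, done, failed_stage = nm)
      stopf("stage '%s' failed: %s", nm, conditionMessage(res))
    }
    if (length(res)) done[[nm]] <- res
    log_line("INFO", "stage %s: done", nm)
  }
  .write_manifest(config$outdir, done)
  invisible(unlist(done))
}

#' Write a promoter signal matrix as a dense TSV
#' @param sigmat A `promoter_signal`.
#' @param path Output path.
#' @export
write_signal_matrix <- function(sigmat, path) {
  df <- data.frame(transcript_id = rownames(sigmat$signal),
                   sigmat$signal, check.names = FALSE)
  names(df)[-1] <- paste0("bin", seq_len(ncol(sigmat$signal)))
  write_tsv(df, path)
  invisible(path)
}
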