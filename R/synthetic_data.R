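# Synthetic data generator with planted truth labels.
#
# Emulates the statistical structure the downstream analysis assumes: donor
# replicates with consistent/inconsistent gamete expression, promoter-centered
# H3K4me3/H3K27me3 coverage peaks in four planted chromatin states,
# stage-ordered preimplantation trajectories (ZGA activation, shared-transcript
# degradation), germ-layer/tissue retention or loss of sperm-derived marks, and
# tumor/normal cohorts with planted fold changes. All randomness flows from a
# single seeded stream in documented order, so a given seed yields
# byte-identical bundles.

GAMETE_CATEGORIES <- c("Sp", "Oc", "SpOc", "Misc", "NotExpressed")
TRAJECTORY_CLASSES <- c("zga_activated", "early_then_degraded",
                        "flat_on", "flat_off")

#' The 26 cancer-type tokens of the default tumor design
#' @return Character vector of 26 cancer-type codes.
#' @export
default_cancer_codes <- function() {
  c("ACC", "BLCA", "BRCA", "CESC", "CHOL", "COAD", "ESCA", "GBM", "HNSC",
    "KICH", "KIRC", "KIRP", "LGG", "LIHC", "LUAD", "LUSC", "OV", "PAAD",
    "PRAD", "READ", "SARC", "SKCM", "STAD", "TGCT", "THCA", "UCEC")
}

#' Configuration for the synthetic bundle
#'
#' Defaults define the study conditions every test and the acceptance suite
#' run under: 1200 transcripts (80 per biotype x gamete-category cell), two
#' donor replicates per gamete, an expression threshold of 1 TPM, log-normal
#' noise on the log2(TPM+1) scale, Gaussian promoter peaks with
#' narrow-H3K4me3 / broad-H3K27me3 geometry, and a 26-code tumor design with
#' one focal gene deregulated in 21 codes.
#'
#' @param seed Integer seed driving every stochastic draw.
#' @param organism `"human"` or `"mouse"` (sets the stage grid and ZGA window).
#' @param n_per_group Transcripts per (biotype x gamete-category) cell.
#' @param n_replicates Donor replicates per gamete.
#' @param threshold Expression threshold in TPM separating on from off.
#' @param on_sd,off_sd Log2-scale noise for expressed / silent gamete cells.
#' @param stage_sd Log2-scale noise for stage/panel samples.
#' @param misc_dropout Probability that an expressed cell of a planted-Misc
#'   transcript drops to silence (0 = clean bundle).
#' @param amplitudes Named list of per-state peak amplitudes `c(k4=, k27=)`
#'   over background.
#' @param background Baseline coverage value inside promoter windows.
#' @param k4_width Gaussian H3K4me3 peak standard deviation (bp); narrow
#'   active peaks. May be a named per-state vector.
#' @param k27_width Gaussian H3K27me3 domain standard deviation (bp); the
#'   repressive mark forms broad domains.
#' @param cov_noise_sd Log2-scale multiplicative noise on per-transcript peak
#'   amplitude.
#' @param cov_interval_sd Log2-scale multiplicative noise per coverage
#'   interval (ChIP background is never flat).
#' @param state_props_sperm Named list (per biotype) of chromatin-state
#'   proportions for sperm-expressed transcripts (Sp, SpOc): balanced across
#'   the marked states, mirroring the several comparably sized promoter
#'   clusters seen among sperm-expressed transcripts.
#' @param state_props_other Named list (per biotype) of state proportions
#'   for transcripts not expressed in sperm (Oc, Misc, NotExpressed):
#'   overwhelmingly unmarked, since sperm promoter H3K4me3 tracks sperm
#'   expression and only a small fraction of the sperm genome retains
#'   marked nucleosomes. These promoters dominate the genome-wide quantile
#'   reference used for state labeling.
#' @param flank Promoter half-window (bp) covered by the generated tracks.
#' @param gen_bin Resolution (bp) of the piecewise-constant coverage output.
#' @param tumor_codes Cancer-type tokens for the tumor design.
#' @param n_tumor,n_normal Cohort sizes per code in the bundle.
#' @param tumor_sd Log2-scale noise in tumor/normal cohorts.
#' @param focal_lfc Planted log2 fold change of the focal gene.
#' @param n_focal_codes Number of codes the focal gene is deregulated in.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 7L, organism = "human", n_per_group = 80L,
                       n_replicates = 2L, threshold = 1,
                       on_sd = 0.5, off_sd = 0.1, stage_sd = 0.15,
                       misc_dropout = 0,
                       amplitudes = list(
                         high_K4 = c(k4 = 30, k27 = 0),
                         low_K4 = c(k4 = 8, k27 = 0),
                         bivalent = c(k4 = 10, k27 = 20),
                         K4minus_K27minus = c(k4 = 0, k27 = 0)),
                       background = 1, k4_width = 1000, k27_width = 4000,
                       cov_noise_sd = 0.2, cov_interval_sd = 0.01,
                       state_props_sperm = list(
                         lincRNA = c(high_K4 = 1/3, low_K4 = 1/3,
                                     K4minus_K27minus = 1/3),
                         protein_coding = c(high_K4 = 0.25, low_K4 = 0.25,
                                            bivalent = 0.25,
                                            K4minus_K27minus = 0.25),
                         other_ncRNA = c(high_K4 = 0.25, low_K4 = 0.25,
                                         bivalent = 0.25,
                                         K4minus_K27minus = 0.25)),
                       state_props_other = list(
                         lincRNA = c(high_K4 = 0.10, low_K4 = 0.15,
                                     K4minus_K27minus = 0.75),
                         protein_coding = c(high_K4 = 0.08, low_K4 = 0.09,
                                            bivalent = 0.08,
                                            K4minus_K27minus = 0.75),
                         other_ncRNA = c(high_K4 = 0.08, low_K4 = 0.09,
                                         bivalent = 0.08,
                                         K4minus_K27minus = 0.75)),
                       flank = 10000, gen_bin = 200,
                       tumor_codes = default_cancer_codes(),
                       n_tumor = 30L, n_normal = 20L, tumor_sd = 0.5,
                       focal_lfc = 2, n_focal_codes = 21L) {
  if (n_replicates < 1) stopf("n_replicates must be >= 1")
  if (on_sd < 0 || off_sd < 0 || stage_sd < 0 || cov_noise_sd < 0 ||
      tumor_sd < 0) stopf("sd values must be >= 0")
  if (misc_dropout < 0 || misc_dropout > 1) stopf("misc_dropout must be in [0,1]")
  cfg <- list(seed = as.integer(seed), organism = organism,
              n_per_group = as.integer(n_per_group),
              n_replicates = as.integer(n_replicates), threshold = threshold,
              on_sd = on_sd, off_sd = off_sd, stage_sd = stage_sd,
              misc_dropout = misc_dropout, amplitudes = amplitudes,
              background = background, k4_width = k4_width,
              k27_width = k27_width, cov_noise_sd = cov_noise_sd,
              cov_interval_sd = cov_interval_sd,
              state_props_sperm = state_props_sperm,
              state_props_other = state_props_other,
              flank = flank, gen_bin = gen_bin, tumor_codes = tumor_codes,
              n_tumor = as.integer(n_tumor), n_normal = as.integer(n_normal),
              tumor_sd = tumor_sd, focal_lfc = focal_lfc,
              n_focal_codes = as.integer(n_focal_codes))
  grid <- stage_grid(organism)
  if (!length(grid$stages)) stopf("empty stage grid")
  cfg$grid <- grid
  class(cfg) <- "sim_config"
  cfg
}

# --- planted design -------------------------------------------------------

# Expressed-in-sperm log2(TPM+1) means by chromatin state: expression tracks
# promoter H3K4me3, the correlation the clustering stage must recover.
.sperm_mean_by_state <- c(high_K4 = 6.5, low_K4 = 5, bivalent = 4,
                          K4minus_K27minus = 3.5)
.oocyte_mean <- c(Oc = 5.5, SpOc = 6.5, Misc = 5.5)
.off_mean <- log2(1.2)  # ~0.2 TPM

# Stage profiles in TPM per trajectory class (human/mouse 6-stage grid)
.trajectory_profiles <- list(
  zga_activated       = c(0.2, 0.2, 3, 12, 10, 8),
  early_then_degraded = c(6, 6, 5, 1.5, 0.5, 0.2),
  flat_on             = rep(8, 6),
  flat_off            = rep(0.2, 6))

# Mouse ZGA starts one stage earlier; shift the planted profiles accordingly
.profile_for <- function(class, organism) {
  p <- .trajectory_profiles[[class]]
  if (organism == "mouse" && class == "zga_activated") c(0.2, 3, 12, 10, 8, 6)
  else if (organism == "mouse" && class == "early_then_degraded")
    c(6, 5, 1.5, 0.5, 0.3, 0.2)
  else p
}

#' Planted truth labels for a configuration
#'
#' Deterministic given the configuration (no random draws): transcripts are
#' laid out 80-per-cell over biotype x gamete category, chromatin states cycle
#' within each biotype (lincRNAs over the three lincRNA states, coding and
#' other transcripts over all four), trajectory classes follow the category
#' (Sp activates at ZGA, SpOc-lincRNAs and Oc degrade, SpOc coding stays on,
#' Misc and NotExpressed stay off), and the focal gene carries planted tumor
#' fold changes.
#'
#' @param config A [sim_config()] (supplies block sizes and state
#'   proportions).
#' @return data.frame of per-transcript truth: ids, coordinates, biotype,
#'   `gamete_category`, `chromatin_state`, `trajectory_class`, `misc_gamete`,
#'   `misc_expressed_rep`.
#' @export
truth_labels <- function(config) {
  n_cell <- config$n_per_group
  design <- expand.grid(biotype = BIOTYPE_LEVELS,
                        gamete_category = GAMETE_CATEGORIES,
                        stringsAsFactors = FALSE)
  tr <- design[rep(seq_len(nrow(design)), each = n_cell), ]
  n <- nrow(tr)
  i <- seq_len(n)
  tr$transcript_id <- sprintf("T%04d", i)
  tr$gene_id <- sprintf("G%04d", i)
  per_chrom <- 100L
  tr$chrom <- paste0("chr", (i - 1L) %/% per_chrom + 1L)
  slot <- (i - 1L) %% per_chrom
  tr$start <- 20000L + slot * 25000L
  tr$end <- tr$start + 2000L
  tr$strand <- ifelse(i %% 2L == 1L, "+", "-")
  tr$tss <- ifelse(tr$strand == "+", tr$start, tr$end - 1L)
  # chromatin states: deterministic proportional assignment within each
  # (biotype x category) block; sperm-expressed categories get the balanced
  # marked-state mix, the rest the background-dominated mix
  tr$chromatin_state <- NA_character_
  for (bt in BIOTYPE_LEVELS) {
    for (cat in GAMETE_CATEGORIES) {
      props <- if (cat %in% c("Sp", "SpOc"))
        config$state_props_sperm[[bt]] else config$state_props_other[[bt]]
      sel <- which(tr$biotype == bt & tr$gamete_category == cat)
      counts <- diff(c(0, round(cumsum(props) * length(sel))))
      tr$chromatin_state[sel] <- rep(names(props), times = counts)
    }
  }
  tr$trajectory_class <- ifelse(
    tr$gamete_category == "Sp", "zga_activated",
    ifelse(tr$gamete_category == "Oc", "early_then_degraded",
    ifelse(tr$gamete_category == "SpOc" & tr$biotype == "lincRNA",
           "early_then_degraded",
    ifelse(tr$gamete_category == "SpOc", "flat_on", "flat_off"))))
  # Misc transcripts: partial pattern in one gamete (alternating), one
  # expressed replicate, absent in the other gamete
  misc <- tr$gamete_category == "Misc"
  tr$misc_gamete <- NA_character_
  tr$misc_gamete[misc] <- rep(c("sperm", "oocyte"), length.out = sum(misc))
  tr$misc_expressed_rep <- NA_integer_
  tr$misc_expressed_rep[misc] <- 1L
  rownames(tr) <- NULL
  tr[, c("transcript_id", "gene_id", "biotype", "chrom", "start", "end",
         "strand", "tss", "gamete_category", "chromatin_state",
         "trajectory_class", "misc_gamete", "misc_expressed_rep")]
}

# --- expression -----------------------------------------------------------

.gamete_samples <- function(config) {
  reps <- seq_len(config$n_replicates)
  data.frame(
    sample_id = c(paste0("sperm_rep", reps), paste0("oocyte_rep", reps)),
    organism = config$organism,
    compartment = rep(c("sperm", "oocyte"), each = length(reps)),
    replicate = as.character(c(reps, reps)), stringsAsFactors = FALSE)
}

.stage_samples <- function(config) {
  stages <- config$grid$stages
  data.frame(
    sample_id = paste0(rep(stages, each = 2), "_rep", 1:2),
    organism = config$organism,
    compartment = rep(stages, each = 2),
    replicate = as.character(rep(1:2, length(stages))),
    stringsAsFactors = FALSE)
}

.soma_samples <- function(config) {
  comps <- c("ectoderm", "mesoderm", "endoderm", "brain", "heart", "thyroid")
  data.frame(
    sample_id = paste0(rep(comps, each = 2), "_rep", 1:2),
    organism = config$organism,
    compartment = rep(comps, each = 2),
    replicate = as.character(rep(1:2, length(comps))),
    stringsAsFactors = FALSE)
}

.sperma_samples <- function(config) {
  stages <- stage_grid(config$organism, panel = "spermatogenesis")$stages
  data.frame(
    sample_id = paste0(rep(stages, each = 2), "_rep", 1:2),
    organism = config$organism,
    compartment = rep(stages, each = 2),
    replicate = as.character(rep(1:2, length(stages))),
    stringsAsFactors = FALSE)
}

# Mean log2(TPM+1) per transcript for one sample; the planted design in
# closed form (used both by the generator and by zero-noise tests)
.planted_mean <- function(truth, compartment, replicate, config) {
  n <- nrow(truth)
  mu <- rep(.off_mean, n)
  state_mu <- .sperm_mean_by_state[truth$chromatin_state]
  if (compartment == "sperm") {
    on <- truth$gamete_category %in% c("Sp", "SpOc") |
      (truth$gamete_category == "Misc" & truth$misc_gamete == "sperm" &
         !is.na(truth$misc_expressed_rep) &
         truth$misc_expressed_rep == as.integer(replicate))
    on[is.na(on)] <- FALSE
    mu[on] <- state_mu[on]
  } else if (compartment == "oocyte") {
    on <- truth$gamete_category %in% c("Oc", "SpOc") |
      (truth$gamete_category == "Misc" & truth$misc_gamete == "oocyte" &
         !is.na(truth$misc_expressed_rep) &
         truth$misc_expressed_rep == as.integer(replicate))
    on[is.na(on)] <- FALSE
    mu[on] <- .oocyte_mean[truth$gamete_category[on]]
  } else if (compartment %in% config$grid$stages) {
    si <- match(compartment, config$grid$stages)
    tpm <- vapply(truth$trajectory_class, function(cl)
      .profile_for(cl, config$organism)[si], 0)
    mu <- log2p1(tpm)
  } else if (compartment %in% c("ectoderm", "mesoderm", "endoderm",
                                "brain", "heart", "thyroid")) {
    mu <- rep(.off_mean, n)
    mu[truth$gamete_category == "SpOc"] <- log2p1(6)
    biv_sp <- truth$gamete_category == "Sp" &
      truth$chromatin_state == "bivalent" &
      truth$biotype == "protein_coding"
    mu[biv_sp] <- log2p1(4)
  } else {  # spermatogenesis panel
    stages <- stage_grid(config$organism, panel = "spermatogenesis")$stages
    si <- match(compartment, stages)
    if (is.na(si)) stopf("unknown compartment '%s'", compartment)
    spermatid <- c(0.5, 0.5, 1, 2, 3, 15)
    meiotic <- c(2, 3, 8, 6, 4, 0.5)
    gam <- truth$gamete_category %in% c("Sp", "SpOc")
    hi <- truth$chromatin_state %in% c("high_K4", "low_K4")
    tpm <- rep(0.2, n)
    tpm[gam & hi] <- spermatid[si]
    tpm[gam & !hi] <- meiotic[si]
    mu <- log2p1(tpm)
  }
  unname(mu)
}

.simulate_expression <- function(truth, config) {
  sheet <- rbind(.gamete_samples(config), .stage_samples(config),
                 .soma_samples(config), .sperma_samples(config))
  n <- nrow(truth)
  expr <- matrix(0, n, nrow(sheet),
                 dimnames = list(truth$transcript_id, sheet$sample_id))
  for (j in seq_len(nrow(sheet))) {
    comp <- sheet$compartment[j]
    mu <- .planted_mean(truth, comp, sheet$replicate[j], config)
    gamete <- comp %in% c("sperm", "oocyte")
    on <- mu > .off_mean + 1e-9
    sd_vec <- ifelse(on, if (gamete) config$on_sd else config$stage_sd,
                     if (gamete) config$off_sd else config$stage_sd)
    # dropout applies only to expressed gamete cells of planted-Misc
    if (gamete && config$misc_dropout > 0) {
      cand <- which(on & truth$gamete_category == "Misc")
      if (length(cand)) {
        drop <- cand[stats::runif(length(cand)) < config$misc_dropout]
        mu[drop] <- .off_mean
        sd_vec[drop] <- config$off_sd
        on[drop] <- FALSE
      }
    }
    x <- stats::rnorm(n, mu, ifelse(sd_vec == 0, 1, sd_vec))
    x[sd_vec == 0] <- mu[sd_vec == 0]
    tpm <- pmax(2^pmax(x, 0) - 1, 0)
    # keep the planted on/off contract exact in gametes: noise never crosses
    # the threshold (truncated log-normal)
    if (gamete) {
      tpm[on] <- pmax(tpm[on], config$threshold)
      tpm[!on] <- pmin(tpm[!on], config$threshold * 0.999)
    }
    expr[, j] <- tpm
  }
  list(expr = expr, sheet = sheet)
}

# --- coverage -------------------------------------------------------------

# Piecewise-constant Gaussian peak track over each promoter window.
# amp is a per-transcript amplitude vector (already noised); width is a
# per-transcript peak sd (bp), recycled if scalar. Returns bedGraph intervals.
.peak_intervals <- function(truth, amp, width, config) {
  step <- config$gen_bin
  flank <- config$flank
  nb <- as.integer(2 * flank / step)
  rel <- (seq_len(nb) - 0.5) * step - flank  # bin centers relative to TSS
  n <- nrow(truth)
  width <- rep_len(width, n)
  gauss <- exp(-0.5 * (rep(rel, n) / rep(width, each = nb))^2)
  starts <- rep(truth$tss - flank, each = nb) +
    rep((seq_len(nb) - 1L) * step, n)
  vals <- config$background + rep(amp, each = nb) * gauss
  if (config$cov_interval_sd > 0)
    vals <- vals * 2^stats::rnorm(length(vals), 0, config$cov_interval_sd)
  data.frame(chrom = rep(truth$chrom, each = nb),
             start = as.integer(starts),
             end = as.integer(starts + step),
             value = round(vals, 6))
}

.simulate_coverage <- function(truth, config, retain_k4 = NULL,
                               retain_k27 = NULL, compartment = "sperm") {
  amps <- config$amplitudes
  a_k4 <- vapply(truth$chromatin_state, function(s) amps[[s]]["k4"], 0)
  a_k27 <- vapply(truth$chromatin_state, function(s) amps[[s]]["k27"], 0)
  if (!is.null(retain_k4)) a_k4[!retain_k4] <- 0
  if (!is.null(retain_k27)) a_k27[!retain_k27] <- 0
  noise <- function(n) 2^stats::rnorm(n, 0, config$cov_noise_sd)
  a_k4 <- a_k4 * noise(nrow(truth))
  a_k27 <- a_k27 * noise(nrow(truth))
  w_k4 <- if (length(config$k4_width) > 1)
    unname(config$k4_width[truth$chromatin_state]) else config$k4_width
  list(
    H3K4me3 = new_coverage_track("H3K4me3", compartment,
      .peak_intervals(truth, a_k4, w_k4, config)),
    H3K27me3 = new_coverage_track("H3K27me3", compartment,
      .peak_intervals(truth, a_k27, config$k27_width, config)))
}

#' Default chromatin retention map for post-implantation compartments
#'
#' Encodes which sperm-derived promoter marks survive into germ layers and
#' somatic tissues: sperm-specific lincRNA and coding high-K4/low-K4 promoters
#' lose their H3K4me3 (background only), bivalent coding promoters retain both
#' marks, and everything else retains its sperm configuration.
#'
#' @param compartments Compartment tokens the map should cover.
#' @return data.frame with `gamete_category`, `biotype`, `chromatin_state`,
#'   `compartment`, `retain_k4`, `retain_k27`.
#' @export
default_retention_map <- function(compartments = c("ectoderm", "mesoderm",
                                                   "endoderm", "brain",
                                                   "heart", "thyroid")) {
  base <- expand.grid(gamete_category = GAMETE_CATEGORIES,
                      biotype = BIOTYPE_LEVELS,
                      chromatin_state = STATE_LEVELS,
                      compartment = compartments,
                      stringsAsFactors = FALSE)
  base$retain_k4 <- TRUE
  base$retain_k27 <- TRUE
  lose <- base$gamete_category == "Sp" &
    base$chromatin_state %in% c("high_K4", "low_K4")
  base$retain_k4[lose] <- FALSE
  base
}

#' Generate germ-layer and tissue coverage tracks under a retention map
#'
#' @param truth Truth table from [truth_labels()].
#' @param config A [sim_config()].
#' @param dir Output directory for the bedGraph files.
#' @param compartments Compartments to generate.
#' @param retention Retention map (default [default_retention_map()]).
#' @return Named list: per compartment, paths for `H3K4me3` and `H3K27me3`.
#' @export
simulate_germlayer_coverage <- function(truth, config, dir,
                                        compartments = c("ectoderm",
                                                         "mesoderm",
                                                         "endoderm", "brain",
                                                         "heart", "thyroid"),
                                        retention = default_retention_map(compartments)) {
  if (nrow(truth) == 0) return(stats::setNames(list(), character()))
  missing_c <- setdiff(compartments, unique(retention$compartment))
  if (length(missing_c))
    stopf("compartments not in retention map: %s",
          paste(missing_c, collapse = ", "))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  for (ci in seq_along(compartments)) {
    comp <- compartments[ci]
    rmap <- retention[retention$compartment == comp, ]
    key <- paste(truth$gamete_category, truth$biotype, truth$chromatin_state)
    rkey <- paste(rmap$gamete_category, rmap$biotype, rmap$chromatin_state)
    idx <- match(key, rkey)
    if (anyNA(idx)) stopf("retention map does not cover all truth rows")
    tracks <- .simulate_coverage(truth, config,
                                 retain_k4 = rmap$retain_k4[idx],
                                 retain_k27 = rmap$retain_k27[idx],
                                 compartment = comp)
    paths <- list()
    for (mark in names(tracks)) {
      p <- file.path(dir, sprintf("%s_%s.bedGraph", mark, comp))
      write_coverage(tracks[[mark]], p)
      paths[[mark]] <- p
    }
    out[[comp]] <- paths
  }
  out
}

# --- motifs and terms -----------------------------------------------------

# Strong planted consensus motif plus moderate-information decoys
.make_pwms <- function(n_decoys = 9, L = 8) {
  consensus <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  planted <- matrix(0.04, 4, L, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_len(L)) planted[consensus[j], j] <- 0.88
  pwms <- list(PLANTED = planted)
  for (d in seq_len(n_decoys)) {
    m <- matrix(stats::runif(4 * L, 0.5, 2), 4, L,
                dimnames = list(c("A", "C", "G", "T"), NULL))
    # sharpen one base per column so decoys have real information content
    for (j in seq_len(L)) m[sample(4, 1), j] <- stats::runif(1, 4, 6)
    pwms[[paste0("DECOY", d)]] <- sweep(m, 2, colSums(m), "/")
  }
  list(pwms = pwms, consensus = paste(consensus, collapse = ""))
}

.random_seqs <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    "")
}

#' Simulate foreground/background promoter sequence sets with a planted motif
#'
#' @param n_fg,n_bg Number of foreground / background sequences.
#' @param frac_fg,frac_bg Fraction of each set carrying the planted consensus.
#' @param len Sequence length (a +/-250 bp promoter by default).
#' @param n_decoys Number of decoy PWMs alongside the planted one.
#' @param motif_len Planted motif length.
#' @param seed Seed for this experiment.
#' @return List: `fg`, `bg` (named character vectors), `pwms` (probability
#'   matrices, first one planted), `consensus`, `planted_fg`, `planted_bg`
#'   (logical vectors of which sequences carry the motif).
#' @export
simulate_motif_sets <- function(n_fg = 200, n_bg = 200, frac_fg = 0.8,
                                frac_bg = 0.05, len = 500, n_decoys = 9,
                                motif_len = 8, seed = 11) {
  with_seed(seed, {
    pw <- .make_pwms(n_decoys, motif_len)
    fg <- .random_seqs(n_fg, len)
    bg <- .random_seqs(n_bg, len)
    plant <- function(seqs, frac) {
      has <- seq_along(seqs) <= round(frac * length(seqs))
      for (i in which(has)) {
        pos <- sample(nchar(seqs[i]) - motif_len + 1, 1)
        substr(seqs[i], pos, pos + motif_len - 1) <- pw$consensus
      }
      list(seqs = seqs, has = has)
    }
    f <- plant(fg, frac_fg)
    b <- plant(bg, frac_bg)
    names(f$seqs) <- sprintf("fg%03d", seq_len(n_fg))
    names(b$seqs) <- sprintf("bg%03d", seq_len(n_bg))
    list(fg = f$seqs, bg = b$seqs, pwms = pw$pwms, consensus = pw$consensus,
         planted_fg = f$has, planted_bg = b$has)
  })
}

# GO-style term sets: one term concentrated in each planted gene group plus
# uniform decoy terms
.make_terms <- function(truth, n_random = 8, seed_offset = 0) {
  terms <- list()
  grp <- function(sel) truth$gene_id[sel]
  terms[["T_SPERMATOGENESIS"]] <- list(
    name = "spermatogenesis-like set (high-K4 coding)",
    genes = grp(truth$biotype == "protein_coding" &
                  truth$chromatin_state == "high_K4" &
                  truth$gamete_category == "Sp"))
  terms[["T_DEVELOPMENT"]] <- list(
    name = "developmental set (bivalent coding)",
    genes = grp(truth$biotype == "protein_coding" &
                  truth$chromatin_state == "bivalent"))
  terms[["T_IMMUNE"]] <- list(
    name = "immune-like set (mark-free coding)",
    genes = grp(truth$biotype == "protein_coding" &
                  truth$chromatin_state == "K4minus_K27minus"))
  for (i in seq_len(n_random)) {
    terms[[sprintf("T_RANDOM%02d", i)]] <- list(
      name = sprintf("random set %d", i),
      genes = sample(truth$gene_id, 60))
  }
  terms
}

# --- tumor cohorts --------------------------------------------------------

#' Simulate tumor/normal cohorts with planted log2 fold changes
#'
#' Expression is drawn on the log2(TPM+1) scale around a shared baseline;
#' tumors of planted (gene, code) pairs are shifted by the planted log2 fold
#' change. Some codes are designed without matched normals so that fallback
#' normal attachment is exercised.
#'
#' @param genes Gene ids to simulate.
#' @param codes Cancer-type tokens.
#' @param n_tumor,n_normal Samples per code.
#' @param planted data.frame (`gene_id`, `code`, `lfc`) of planted shifts;
#'   `NULL` for a pure null design.
#' @param baseline Baseline mean log2(TPM+1).
#' @param sd Log2-scale noise.
#' @param seed Seed for this experiment.
#' @param organism Organism token for the sheet.
#' @return List: `expr` (genes x samples TPM), `sheet`, `planted`.
#' @export
simulate_tumor_cohort <- function(genes, codes, n_tumor = 10, n_normal = 10,
                                  planted = NULL, baseline = 4, sd = 0.5,
                                  seed = 13, organism = "human") {
  with_seed(seed, {
    sheets <- lapply(codes, function(code) {
      data.frame(
        sample_id = c(sprintf("%s_tumor%02d", code, seq_len(n_tumor)),
                      sprintf("%s_normal%02d", code, seq_len(n_normal))),
        organism = organism,
        compartment = c(rep(paste0("tumor:", code), n_tumor),
                        rep(paste0("normal:", code), n_normal)),
        replicate = as.character(c(seq_len(n_tumor), seq_len(n_normal))),
        stringsAsFactors = FALSE)
    })
    sheet <- do.call(rbind, sheets)
    mu <- matrix(baseline, length(genes), nrow(sheet),
                 dimnames = list(genes, sheet$sample_id))
    if (!is.null(planted) && nrow(planted)) {
      for (r in seq_len(nrow(planted))) {
        cols <- sheet$compartment == paste0("tumor:", planted$code[r])
        mu[planted$gene_id[r], cols] <-
          mu[planted$gene_id[r], cols] + planted$lfc[r]
      }
    }
    x <- matrix(stats::rnorm(length(mu), mu, sd), nrow(mu), ncol(mu),
                dimnames = dimnames(mu))
    expr <- pmax(2^pmax(x, 0) - 1, 0)
    list(expr = expr, sheet = sheet, planted = planted)
  })
}

# --- bundle ---------------------------------------------------------------

#' Simulate a complete analysis bundle with planted truth
#'
#' Writes, under `dir`: a GTF annotation, TPM expression TSVs with a sample
#' sheet (gametes with donor replicates, preimplantation stages, germ layers,
#' tissues, spermatogenesis panel), sperm plus germ-layer/tissue
#' H3K4me3/H3K27me3 bedGraph tracks, a JASPAR-style PWM file, promoter
#' sequence FASTAs for motif enrichment, a GMT term file, tumor cohort TSVs,
#' and the planted truth-label table. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return List of file paths plus the in-memory `truth` table and `config`.
#' @export
simulate_bundle <- function(config = sim_config(), dir = tempfile("bundle")) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  covdir <- file.path(dir, "coverage")
  dir.create(covdir, showWarnings = FALSE)
  truth <- truth_labels(config)
  paths <- list(dir = dir)

  with_seed(config$seed, {
    # 1. expression (gametes, stages, soma, spermatogenesis)
    ex <- .simulate_expression(truth, config)
    # 2. sperm coverage
    sperm_tracks <- .simulate_coverage(truth, config, compartment = "sperm")
    # 3. germ-layer / tissue coverage under the retention map
    soma_comps <- c("ectoderm", "mesoderm", "endoderm",
                    "brain", "heart", "thyroid")
    soma_paths <- simulate_germlayer_coverage(truth, config, covdir,
                                              compartments = soma_comps)
    # 4. motif sets and PWMs
    motifs <- simulate_motif_sets(seed = config$seed + 101L)
    # 5. term sets
    terms <- .make_terms(truth)
    # 6. tumor cohorts: lincRNA genes, focal gene deregulated in
    #    n_focal_codes codes (up in two-thirds, down in the rest)
    linc_genes <- truth$gene_id[truth$biotype == "lincRNA"]
    focal <- truth$gene_id[truth$biotype == "lincRNA" &
                             truth$gamete_category == "Sp" &
                             truth$chromatin_state == "high_K4"][1]
    k <- config$n_focal_codes
    n_up <- ceiling(2 * k / 3)
    planted <- data.frame(gene_id = focal,
                          code = config$tumor_codes[seq_len(k)],
                          lfc = c(rep(config$focal_lfc, n_up),
                                  rep(-config$focal_lfc, k - n_up)))
    tumor <- simulate_tumor_cohort(linc_genes, config$tumor_codes,
                                   n_tumor = config$n_tumor,
                                   n_normal = config$n_normal,
                                   planted = planted, sd = config$tumor_sd,
                                   seed = config$seed + 202L,
                                   organism = config$organism)
  })

  paths$annotation <- file.path(dir, "annotation.gtf")
  write_annotation(truth[, c("transcript_id", "gene_id", "biotype", "chrom",
                             "start", "end", "strand", "tss")],
                   paths$annotation)
  paths$expression <- file.path(dir, "expression.tsv")
  paths$samples <- file.path(dir, "samples.tsv")
  write_expression(ex$expr, ex$sheet, paths$expression, paths$samples)
  paths$coverage <- list(sperm = list())
  for (mark in names(sperm_tracks)) {
    p <- file.path(covdir, sprintf("%s_sperm.bedGraph", mark))
    write_coverage(sperm_tracks[[mark]], p)
    paths$coverage$sperm[[mark]] <- p
  }
  for (comp in names(soma_paths)) paths$coverage[[comp]] <- soma_paths[[comp]]
  paths$pwms <- file.path(dir, "pwms.txt")
  write_pwms(motifs$pwms, paths$pwms)
  paths$fg_fasta <- file.path(dir, "promoters_fg.fa")
  paths$bg_fasta <- file.path(dir, "promoters_bg.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(motifs$fg),
                              paths$fg_fasta)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(motifs$bg),
                              paths$bg_fasta)
  paths$gmt <- file.path(dir, "terms.gmt")
  write_gmt(terms, paths$gmt)
  paths$tumor_expression <- file.path(dir, "tumor_expression.tsv")
  paths$tumor_samples <- file.path(dir, "tumor_samples.tsv")
  write_expression(tumor$expr, tumor$sheet,
                   paths$tumor_expression, paths$tumor_samples)
  paths$truth <- file.path(dir, "truth.tsv")
  write_tsv(truth, paths$truth)

  list(paths = paths, truth = truth, config = config,
       planted_tumor = tumor$planted, motif_truth = motifs["consensus"])
}
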