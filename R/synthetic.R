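#' Synthetic study configuration
#'
#' Defines a seeded synthetic study mirroring the structure the analysis
#' assumes: a reference atlas of `n_somatic_tissues` somatic tissues plus
#' germline / placenta / embryonic-stem target tissues, and a small
#' case/control cohort. All levels are on the log2 scale; noise is additive
#' Gaussian (log-normal intensities). Somatic tissues carry a global
#' per-tissue baseline offset (`tissue_effect_sd`) shared across genes,
#' modelling systematic tissue-to-tissue intensity differences; target
#' tissues sit at the global baseline so specificity calls arise only from
#' planted signal.
#'
#' Planted structure: `n_restricted_planted` genes are silent
#' (`silent_level`) in every somatic tissue and expressed at
#' `restricted_target_level` in one target class (alternating germline /
#' placenta); `n_predominant_planted` genes sit at baseline in somatic
#' tissues and `predominant_fold` log2 units above baseline in one target
#' class (cycling through all target classes). In the cohort,
#' `n_activated_genes` of the planted genes are ectopically activated in
#' case samples, shifted by `activation_shift` control SDs above their
#' control level.
#'
#' @param n_somatic_tissues number of somatic tissues (default 112).
#' @param samples_per_tissue atlas samples per tissue (default 3).
#' @param target_tissue_counts named integer vector: tissues per target
#'   class (default germline 2, placenta 1, embryonic_stem 1).
#' @param n_genes total genes (default 1000).
#' @param n_restricted_planted,n_predominant_planted planted gene counts
#'   (defaults 30 and 40).
#' @param baseline_mean,noise_sd global baseline and per-cell Gaussian noise
#'   SD, log2 scale (defaults 5 and 0.5).
#' @param tissue_effect_sd SD of the somatic per-tissue baseline offsets,
#'   log2 scale (default 1).
#' @param silent_level expression level of silenced genes (default 1).
#' @param restricted_target_level target-class level of restricted planted
#'   genes (default 10).
#' @param predominant_fold log2 fold elevation of predominant planted genes
#'   in their target class (default 6).
#' @param n_cases,n_controls cohort sizes (defaults 3 and 3, as in a minimal
#'   case/control array study).
#' @param n_activated_genes planted genes ectopically activated in the
#'   cohort; default: all planted genes.
#' @param activation_shift activation effect size in units of the control
#'   noise SD (default 10); 0 gives a null cohort with no true activation.
#' @param seed integer seed fixing the full generation stream.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_somatic_tissues = 112,
                             samples_per_tissue = 3,
                             target_tissue_counts = c(germline = 2,
                                                      placenta = 1,
                                                      embryonic_stem = 1),
                             n_genes = 1000,
                             n_restricted_planted = 30,
                             n_predominant_planted = 40,
                             baseline_mean = 5, noise_sd = 0.5,
                             tissue_effect_sd = 1, silent_level = 1,
                             restricted_target_level = 10,
                             predominant_fold = 6,
                             n_cases = 3, n_controls = 3,
                             n_activated_genes = NULL,
                             activation_shift = 10,
                             seed = 1L) {
  cfg <- list(n_somatic_tissues = n_somatic_tissues,
              samples_per_tissue = samples_per_tissue,
              target_tissue_counts = target_tissue_counts,
              n_genes = n_genes,
              n_restricted_planted = n_restricted_planted,
              n_predominant_planted = n_predominant_planted,
              baseline_mean = baseline_mean, noise_sd = noise_sd,
              tissue_effect_sd = tissue_effect_sd,
              silent_level = silent_level,
              restricted_target_level = restricted_target_level,
              predominant_fold = predominant_fold,
              n_cases = n_cases, n_controls = n_controls,
              n_activated_genes = n_activated_genes,
              activation_shift = activation_shift,
              seed = as.integer(seed))
  counts <- c(n_somatic_tissues, samples_per_tissue, n_genes, n_cases,
              n_controls, target_tissue_counts)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("all tissue/sample/gene counts must be positive integers",
         call. = FALSE)
  if (n_somatic_tissues < 2)
    stop("need >= 2 somatic tissues", call. = FALSE)
  if (is.null(names(target_tissue_counts)) ||
      !all(names(target_tissue_counts) %in%
             c("germline", "placenta", "embryonic_stem")))
    stop("target_tissue_counts must be named with target classes",
         call. = FALSE)
  if (n_restricted_planted + n_predominant_planted > n_genes)
    stop("planted genes exceed n_genes", call. = FALSE)
  if (noise_sd < 0 || tissue_effect_sd < 0 || activation_shift < 0)
    stop("noise_sd, tissue_effect_sd and activation_shift must be >= 0",
         call. = FALSE)
  n_planted <- n_restricted_planted + n_predominant_planted
  if (is.null(cfg$n_activated_genes)) cfg$n_activated_genes <- n_planted
  if (cfg$n_activated_genes > n_planted)
    stop("n_activated_genes (", cfg$n_activated_genes,
         ") exceeds the number of planted (atlas-flagged) genes (",
         n_planted, ")", call. = FALSE)
  class(cfg) <- "synthetic_config"
  cfg
}

target_tissue_names <- function(counts) {
  nm <- list(germline = c("testis", "ovary"),
             placenta = "placenta",
             embryonic_stem = "es_cells")
  out <- list()
  for (cl in names(counts)) {
    k <- counts[[cl]]
    base <- nm[[cl]]
    lab <- if (k <= length(base)) base[seq_len(k)]
           else c(base, paste0(cl, "_", seq_len(k - length(base)) +
                                 length(base)))
    out[[cl]] <- lab
  }
  out
}

#' Generate a synthetic reference atlas
#'
#' @param config a `synthetic_config`.
#' @return list with `expr` (log2 `expr_matrix`), `annotation`
#'   (`tissue_annotation`) and `truth` — a list holding the planted per-gene
#'   `status`/`class` table and the somatic tissue offsets used.
#' @export
generate_atlas <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  som_tissues <- sprintf("somatic_%03d", seq_len(config$n_somatic_tissues))
  tgt <- target_tissue_names(config$target_tissue_counts)
  tissues <- c(som_tissues, unlist(tgt, use.names = FALSE))
  tclass <- c(rep("somatic", length(som_tissues)),
              rep(names(tgt), lengths(tgt)))
  spt <- config$samples_per_tissue
  samples <- paste0(rep(tissues, each = spt), "_s", seq_len(spt))
  ann <- tissue_annotation(sample_id = samples,
                           tissue_label = rep(tissues, each = spt),
                           class = rep(tclass, each = spt))

  offsets <- stats::setNames(
    c(stats::rnorm(length(som_tissues), 0, config$tissue_effect_sd),
      rep(0, length(tissues) - length(som_tissues))), tissues)

  # planted labels: restricted genes alternate germline/placenta, predominant
  # genes cycle through every target class present
  n_r <- config$n_restricted_planted
  n_p <- config$n_predominant_planted
  r_classes <- intersect(c("germline", "placenta"), names(tgt))
  if (n_r > 0 && !length(r_classes))
    stop("restricted genes need a germline or placenta tissue", call. = FALSE)
  status <- rep("unrestricted", config$n_genes)
  pclass <- rep("none", config$n_genes)
  if (n_r > 0) {
    status[seq_len(n_r)] <- "restricted"
    pclass[seq_len(n_r)] <- rep_len(r_classes, n_r)
  }
  if (n_p > 0) {
    idx <- n_r + seq_len(n_p)
    status[idx] <- "predominant"
    pclass[idx] <- rep_len(names(tgt), n_p)
  }

  # per-gene per-sample mean: baseline + somatic offset, overwritten for
  # planted genes (restricted: silent somatic, high target; predominant:
  # baseline somatic, elevated target)
  sample_offsets <- offsets[rep(tissues, each = spt)]
  sample_class <- rep(tclass, each = spt)
  mu <- matrix(config$baseline_mean + rep(sample_offsets,
                                          each = config$n_genes),
               nrow = config$n_genes, ncol = length(samples),
               dimnames = list(genes, samples))
  for (i in which(status == "restricted")) {
    mu[i, ] <- config$silent_level
    mu[i, sample_class == pclass[i]] <- config$restricted_target_level
  }
  for (i in which(status == "predominant")) {
    mu[i, sample_class == pclass[i]] <-
      config$baseline_mean + config$predominant_fold
  }
  values <- mu + stats::rnorm(length(mu), 0, config$noise_sd)
  expr <- expression_matrix(values, scale = "log2")
  truth_table <- data.frame(gene = genes, status = status, class = pclass,
                            row.names = NULL, stringsAsFactors = FALSE)
  list(expr = expr, annotation = ann,
       truth = list(genes = truth_table, tissue_offsets = offsets,
                    config = config))
}

#' Generate a synthetic case/control cohort
#'
#' Control and case samples share the per-gene somatic profile of the atlas
#' (silent level for restricted planted genes, baseline otherwise); a chosen
#' subset of planted genes is ectopically activated in every case sample,
#' shifted `activation_shift` noise-SDs above its control level.
#'
#' @param config a `synthetic_config`.
#' @param truth the `truth` element returned by [generate_atlas()] for the
#'   same config.
#' @param seed seed for the cohort stream; defaults to `config$seed + 1` so
#'   that atlas and cohort draws are distinct but jointly reproducible.
#' @return list with `cases`, `controls` (log2 `expr_matrix`) and
#'   `truth_calls` (logical genes x case-samples matrix of planted
#'   activations).
#' @export
generate_cohort <- function(config, truth, seed = config$seed + 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(as.integer(seed))
  tt <- truth$genes
  genes <- tt$gene
  planted <- genes[tt$status != "unrestricted"]
  if (config$n_activated_genes > length(planted))
    stop("n_activated_genes exceeds the number of planted genes",
         call. = FALSE)
  base_level <- ifelse(tt$status == "restricted", config$silent_level,
                       config$baseline_mean)
  ctrl_ids <- paste0("control_", seq_len(config$n_controls))
  case_ids <- paste0("case_", seq_len(config$n_cases))
  controls <- matrix(base_level + stats::rnorm(length(genes) *
                                                 config$n_controls, 0,
                                               config$noise_sd),
                     nrow = length(genes),
                     dimnames = list(genes, ctrl_ids))
  cases <- matrix(base_level + stats::rnorm(length(genes) * config$n_cases,
                                            0, config$noise_sd),
                  nrow = length(genes),
                  dimnames = list(genes, case_ids))
  activated <- sample(planted, config$n_activated_genes)
  truth_calls <- matrix(FALSE, nrow = length(genes), ncol = config$n_cases,
                        dimnames = list(genes, case_ids))
  if (config$activation_shift > 0) {
    truth_calls[activated, ] <- TRUE
    cases[activated, ] <- cases[activated, , drop = FALSE] +
      config$activation_shift * config$noise_sd
  }
  list(cases = expression_matrix(cases, scale = "log2"),
       controls = expression_matrix(controls, scale = "log2"),
       truth_calls = truth_calls)
}

#' Null-calibration experiment for the mean + k * SD rule
#'
#' Draws i.i.d. Gaussian controls and a Gaussian case value per replicate,
#' runs the package's control-threshold and calling code, and reports the
#' fraction of null draws flagged with its Monte-Carlo standard error. Under
#' this null the exact flag rate is a Student-t tail,
#' P(t_{n-1} > k / sqrt(1 + 1/n)), approaching the Gaussian tail as the
#' number of controls grows.
#'
#' @param n_controls controls per replicate (>= 2).
#' @param k SD multiplier (default 3).
#' @param n_draws number of null (gene, case) replicates (>= 10000).
#' @param seed integer seed.
#' @param chunk_size replicates simulated per block, a memory/speed knob.
#' @return list: `rate` (empirical flag rate), `se` (Monte-Carlo SE),
#'   `n_flagged`, `n_draws`, `n_controls`, `k`.
#' @export
calibration_experiment <- function(n_controls, k = 3, n_draws = 200000,
                                   seed = 1L, chunk_size = 20000L) {
  if (n_controls < 2) stop("n_controls must be >= 2", call. = FALSE)
  if (n_draws < 10000) stop("n_draws must be >= 10000", call. = FALSE)
  set.seed(as.integer(seed))
  params <- call_params(k_control = k, epsilon = 0)
  n_flagged <- 0L
  done <- 0L
  while (done < n_draws) {
    m <- as.integer(min(chunk_size, n_draws - done))
    g <- paste0("d", seq_len(m))
    ctrl <- expression_matrix(
      matrix(stats::rnorm(m * n_controls), nrow = m,
             dimnames = list(g, paste0("c", seq_len(n_controls)))),
      scale = "log2")
    cs <- expression_matrix(
      matrix(stats::rnorm(m), nrow = m, dimnames = list(g, "case_1")),
      scale = "log2")
    thr <- control_thresholds(ctrl, params)
    calls <- call_ectopic(cs, thr)
    n_flagged <- n_flagged + sum(calls$flags)
    done <- done + m
  }
  rate <- n_flagged / n_draws
  list(rate = rate, se = sqrt(rate * (1 - rate) / n_draws),
       n_flagged = n_flagged, n_draws = n_draws,
       n_controls = n_controls, k = k)
}

#' Planted-recovery experiment
#'
#' Runs the full pipeline on a seeded synthetic study: classifies the atlas,
#' then repeatedly generates cohorts until at least `n_events_min` planted
#' activation events have been scored, measuring how the ectopic caller
#' recovers the planted truth.
#'
#' @param config a `synthetic_config` with a positive `activation_shift`.
#'   Configuring fewer activated genes than planted genes leaves null
#'   candidate cells from which the false-flag rate is estimated.
#' @param n_events_min minimum planted (gene, case) events to accumulate.
#' @param seed seed for the replicate cohort streams.
#' @param params a `call_params` for the ectopic stage.
#' @return list: `sensitivity` (flagged fraction of planted events),
#'   `false_flag_rate` (flagged fraction of non-activated candidate cells),
#'   `n_events`, `n_null_cells`, `n_replicates`, `status_accuracy` (fraction
#'   of genes whose specificity status matches the planted truth) and the
#'   `spec_table`.
#' @export
recovery_experiment <- function(config, n_events_min = 10000,
                                seed = config$seed, params = call_params()) {
  atlas <- generate_atlas(config)
  spec <- build_specificity_table(atlas$expr, atlas$annotation)
  truth_status <- atlas$truth$genes$status
  status_accuracy <- mean(spec$status == truth_status)
  candidates <- spec$gene[spec$status != "unrestricted"]
  hits <- 0L; events <- 0L; false_flags <- 0L; null_cells <- 0L; reps <- 0L
  while (events < n_events_min) {
    reps <- reps + 1L
    cohort <- generate_cohort(config, atlas$truth,
                              seed = as.integer(seed) + reps)
    thr <- control_thresholds(cohort$controls, params)
    calls <- call_ectopic(cohort$cases, thr, candidates)
    tc <- cohort$truth_calls[candidates, , drop = FALSE]
    hits <- hits + sum(calls$flags & tc)
    events <- events + sum(tc)
    false_flags <- false_flags + sum(calls$flags & !tc)
    null_cells <- null_cells + sum(!tc)
    if (reps > 10000L) stop("no planted events accumulating; is activation_shift 0?",
                            call. = FALSE)
  }
  list(sensitivity = hits / events,
       false_flag_rate = if (null_cells) false_flags / null_cells else NA_real_,
       n_events = events, n_null_cells = null_cells, n_replicates = reps,
       status_accuracy = status_accuracy, spec_table = spec)
}
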