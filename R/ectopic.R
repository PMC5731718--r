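#' Ectopic-call parameters
#'
#' The detection rule flags a case value as ectopic when it strictly exceeds
#' the per-gene control threshold `control mean + k_control * SD`. `epsilon`
#' is a pseudo-SD floor guarding against zero-variance controls (where the
#' threshold would collapse onto the control mean and any noise would flag
#' the gene); when `NULL` it resolves to 0.01 times the median of all control
#' values on the working scale.
#'
#' @param k_control positive SD multiplier (default 3).
#' @param epsilon non-negative pseudo-SD floor, or `NULL` to resolve from the
#'   controls. Use 0 to reproduce the bare mean + k * SD rule.
#' @param aggregation_mode default aggregation over case samples, `"all"`
#'   (flagged in every case) or `"any"` (flagged in at least one).
#' @return a `call_params` list.
#' @export
call_params <- function(k_control = 3, epsilon = NULL,
                        aggregation_mode = c("all", "any")) {
  aggregation_mode <- match.arg(aggregation_mode)
  if (!is.numeric(k_control) || length(k_control) != 1 || k_control <= 0)
    stop("k_control must be a single positive number", call. = FALSE)
  if (!is.null(epsilon) &&
      (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon < 0))
    stop("epsilon must be NULL or a single non-negative number",
         call. = FALSE)
  structure(list(k_control = k_control, epsilon = epsilon,
                 aggregation_mode = aggregation_mode),
            class = "call_params")
}

resolve_epsilon <- function(controls, params) {
  if (!is.null(params$epsilon)) return(params$epsilon)
  0.01 * stats::median(unclass(controls))
}

#' Per-gene control thresholds
#'
#' tau(g) = control mean + k_control * max(SD, epsilon), SD with the n-1
#' denominator over control samples.
#'
#' @param controls control `expr_matrix` (genes x control samples, >= 2
#'   samples).
#' @param params a `call_params`.
#' @return data frame: gene, control_mean, control_sd, threshold; the
#'   resolved epsilon is attached as an attribute.
#' @export
control_thresholds <- function(controls, params = call_params()) {
  n <- ncol(controls)
  if (n < 2)
    stop("need >= 2 control samples to estimate a control SD (found ", n,
         ")", call. = FALSE)
  v <- unclass(controls)
  if (any(!is.finite(v))) {
    bad <- rownames(v)[rowSums(!is.finite(v)) > 0]
    stop("non-finite control values for gene(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  eps <- resolve_epsilon(controls, params)
  m <- rowMeans(v)
  sdv <- sqrt(rowSums((v - m)^2) / (n - 1))
  out <- data.frame(gene = rownames(v), control_mean = m, control_sd = sdv,
                    threshold = m + params$k_control * pmax(sdv, eps),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "epsilon") <- eps
  attr(out, "k_control") <- params$k_control
  out
}

#' Call ectopic activation in case samples
#'
#' Flags (gene, case sample) cells whose value strictly exceeds the gene's
#' control threshold. Calls are made only for the candidate genes — in the
#' intended use, the atlas-flagged (restricted or predominant) genes.
#'
#' @param cases case `expr_matrix`.
#' @param thresholds data frame from [control_thresholds()].
#' @param candidates character vector of genes to test; defaults to every
#'   gene with a threshold.
#' @return an `ectopic_calls` object: list with `stats` (per-gene threshold
#'   table restricted to candidates) and `flags` (logical candidates x case
#'   samples matrix).
#' @export
call_ectopic <- function(cases, thresholds, candidates = thresholds$gene) {
  candidates <- unique(as.character(candidates))
  miss_case <- setdiff(candidates, rownames(cases))
  if (length(miss_case))
    stop("candidate gene(s) missing from the case matrix: ",
         paste(utils::head(miss_case, 10), collapse = ", "), call. = FALSE)
  miss_thr <- setdiff(candidates, thresholds$gene)
  if (length(miss_thr))
    stop("candidate gene(s) without a control threshold: ",
         paste(utils::head(miss_thr, 10), collapse = ", "), call. = FALSE)
  stats <- thresholds[match(candidates, thresholds$gene), , drop = FALSE]
  v <- unclass(cases)[candidates, , drop = FALSE]
  flags <- v > stats$threshold
  dimnames(flags) <- list(candidates, colnames(cases))
  structure(list(stats = stats, flags = flags), class = "ectopic_calls")
}

#' @export
print.ectopic_calls <- function(x, ...) {
  cat(sprintf("<ectopic_calls> %d candidate genes x %d case samples; %d flagged cells\n",
              nrow(x$flags), ncol(x$flags), sum(x$flags)))
  invisible(x)
}

#' Aggregate per-sample flags into a gene set
#'
#' @param calls an `ectopic_calls` object.
#' @param mode `"all"`: genes flagged in every case sample; `"any"`: genes
#'   flagged in at least one. `any` always contains `all`.
#' @return character vector of gene ids.
#' @export
aggregate_calls <- function(calls, mode = c("all", "any")) {
  mode <- match.arg(mode)
  if (ncol(calls$flags) < 1)
    stop("need at least one case sample to aggregate", call. = FALSE)
  keep <- if (mode == "all") rowSums(calls$flags) == ncol(calls$flags)
          else rowSums(calls$flags) > 0L
  rownames(calls$flags)[keep]
}

#' Assign flagged genes to specificity groups
#'
#' Partition used for reporting: group 1 holds genes with placenta- or
#' germline-restricted normal expression, group 2 germline-predominant
#' genes, group 3 embryonic-stem-predominant genes; everything else is
#' `other`.
#'
#' @param genes character vector of genes (each must appear in `spec`).
#' @param spec a `specificity_table`.
#' @return data frame: gene, group, with group one of `group1_restricted`,
#'   `group2_germline_predominant`, `group3_es_predominant`, `other`.
#' @export
assign_groups <- function(genes, spec) {
  genes <- as.character(genes)
  miss <- setdiff(genes, spec$gene)
  if (length(miss))
    stop("gene(s) absent from the specificity table: ",
         paste(utils::head(miss, 10), collapse = ", "), call. = FALSE)
  s <- spec[match(genes, spec$gene), , drop = FALSE]
  group <- rep("other", length(genes))
  group[s$status == "restricted" &
          s$target_class %in% c("placenta", "germline")] <- "group1_restricted"
  group[s$status == "predominant" &
          s$target_class == "germline"] <- "group2_germline_predominant"
  group[s$status == "predominant" &
          s$target_class == "embryonic_stem"] <- "group3_es_predominant"
  data.frame(gene = genes, group = group, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Permutation-based empirical null for ectopic calls
#'
#' Optional add-on to the threshold rule (off by default in the pipeline):
#' for each gene, case/control labels are shuffled `n_perm` times, the
#' threshold and calls recomputed, and an empirical p-value reported for
#' observing at least as many flagged case cells as in the real labelling.
#' The `+1` correction keeps p-values strictly positive.
#'
#' @param cases,controls `expr_matrix` objects on the same scale.
#' @param params a `call_params`.
#' @param n_perm number of label permutations (default 1000).
#' @param seed integer seed for the permutation stream.
#' @param adjust multiple-testing adjustment passed to [stats::p.adjust()]
#'   (default `"none"`, matching the headline analysis).
#' @return data frame: gene, n_flagged (observed), p_value, p_adjusted.
#' @export
permutation_null <- function(cases, controls, params = call_params(),
                             n_perm = 1000, seed = 1L, adjust = "none") {
  stopifnot_same_scale(cases, controls, "case and control matrices")
  if (!identical(rownames(cases), rownames(controls)))
    stop("case and control matrices must share the same gene set",
         call. = FALSE)
  n_case <- ncol(cases)
  n_ctrl <- ncol(controls)
  pool <- cbind(unclass(cases), unclass(controls))
  obs <- rowSums(call_ectopic(cases, control_thresholds(controls, params))$flags)
  set.seed(as.integer(seed))
  exceed <- integer(nrow(pool))
  scale <- expr_scale(cases)
  for (b in seq_len(n_perm)) {
    idx <- sample(n_case + n_ctrl)
    perm_cases <- expression_matrix(pool[, idx[seq_len(n_case)],
                                         drop = FALSE], scale)
    perm_ctrls <- expression_matrix(pool[, idx[n_case + seq_len(n_ctrl)],
                                         drop = FALSE], scale)
    stat <- rowSums(call_ectopic(perm_cases,
                                 control_thresholds(perm_ctrls,
                                                    params))$flags)
    exceed <- exceed + (stat >= obs)
  }
  p <- (exceed + 1) / (n_perm + 1)
  data.frame(gene = rownames(cases), n_flagged = obs, p_value = p,
             p_adjusted = stats::p.adjust(p, method = adjust),
             row.names = NULL, stringsAsFactors = FALSE)
}
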