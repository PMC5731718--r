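#' Specificity-classification parameters
#'
#' Parameters of the atlas stage. The atlas threshold for each gene is its
#' mean expression across somatic tissues plus `k_atlas` standard deviations
#' (SD across somatic tissue-level means, n-1 denominator). `detection_floor`
#' is the expression level at or below which a gene counts as silent in a
#' tissue; when `NULL` it is resolved at run time as the 25th percentile of
#' all atlas values on the working scale.
#'
#' @param k_atlas positive SD multiplier (default 3).
#' @param detection_floor non-negative silence cutoff on the working scale,
#'   or `NULL` to resolve from the data.
#' @param target_classes ordered character vector of target classes; the
#'   order breaks ties when a gene is equally expressed in two classes.
#' @return a `specificity_params` list.
#' @export
specificity_params <- function(k_atlas = 3, detection_floor = NULL,
                               target_classes = c("germline", "placenta",
                                                  "embryonic_stem")) {
  if (!is.numeric(k_atlas) || length(k_atlas) != 1 || k_atlas <= 0)
    stop("k_atlas must be a single positive number", call. = FALSE)
  if (!is.null(detection_floor) &&
      (!is.numeric(detection_floor) || length(detection_floor) != 1 ||
       detection_floor < 0))
    stop("detection_floor must be NULL or a single non-negative number",
         call. = FALSE)
  valid <- c("germline", "placenta", "embryonic_stem")
  if (!length(target_classes) || !all(target_classes %in% valid))
    stop("target_classes must be drawn from: ",
         paste(valid, collapse = ", "), call. = FALSE)
  structure(list(k_atlas = k_atlas, detection_floor = detection_floor,
                 target_classes = target_classes),
            class = "specificity_params")
}

#' Per-tissue mean expression
#'
#' Collapses samples to tissues by arithmetic mean on the working scale.
#'
#' @param expr an `expr_matrix`.
#' @param ann a `tissue_annotation` covering every sample in `expr`.
#' @return numeric matrix, genes x tissues; the tissue set equals the
#'   annotation's tissue set (restricted to annotated samples present).
#' @export
tissue_means <- function(expr, ann) {
  check_samples_annotated(expr, ann)
  ann <- ann[ann$sample_id %in% colnames(expr), , drop = FALSE]
  tissues <- unique(ann$tissue_label)
  if (length(tissues) == 0L)
    stop("annotation covers no sample of the matrix", call. = FALSE)
  v <- unclass(expr)
  attr(v, "scale_tag") <- NULL
  out <- matrix(NA_real_, nrow(v), length(tissues),
                dimnames = list(rownames(expr), tissues))
  for (t in tissues) {
    s <- ann$sample_id[ann$tissue_label == t]
    if (!length(s)) stop("tissue group is empty: ", t, call. = FALSE)
    out[, t] <- rowMeans(v[, s, drop = FALSE])
  }
  out
}

somatic_tissues <- function(tmeans, ann) {
  som <- intersect(colnames(tmeans), tissues_of_class(ann, "somatic"))
  if (length(som) < 2)
    stop("need >= 2 somatic tissues to define the atlas threshold (found ",
         length(som), ")", call. = FALSE)
  som
}

#' Per-gene atlas threshold
#'
#' For each gene: mean of its somatic tissue means plus `k_atlas` times their
#' sample SD (n-1 denominator, computed over tissue means, not raw samples).
#' Target-class expression above this value counts as predominant.
#'
#' @param tmeans genes x tissues mean matrix from [tissue_means()].
#' @param ann a `tissue_annotation`.
#' @param params a `specificity_params`.
#' @return named numeric vector of per-gene thresholds.
#' @export
atlas_threshold <- function(tmeans, ann, params = specificity_params()) {
  som <- somatic_tissues(tmeans, ann)
  x <- tmeans[, som, drop = FALSE]
  m <- rowMeans(x)
  sdv <- sqrt(rowSums((x - m)^2) / (ncol(x) - 1))
  m + params$k_atlas * sdv
}

class_means <- function(tmeans, ann, target_classes) {
  out <- vapply(target_classes, function(cl) {
    ts <- intersect(colnames(tmeans), tissues_of_class(ann, cl))
    if (!length(ts))
      stop("target class has no tissue in the annotation: ", cl,
           call. = FALSE)
    rowMeans(tmeans[, ts, drop = FALSE])
  }, numeric(nrow(tmeans)))
  dimnames(out) <- list(rownames(tmeans), target_classes)
  out
}

# argmax over target classes, ties broken by column (= target_classes) order
argmax_class <- function(cmeans) {
  colnames(cmeans)[max.col(cmeans, ties.method = "first")]
}

#' Classify tissue-restricted genes
#'
#' A gene is restricted when every somatic tissue mean is at or below the
#' detection floor (silent in all somatic tissues) and at least one
#' target-class tissue mean exceeds the floor. The assigned class is the
#' target class with the largest class mean.
#'
#' @inheritParams atlas_threshold
#' @param params a `specificity_params` with a resolved (numeric)
#'   `detection_floor`.
#' @return data frame: gene, restricted (logical), target_class.
#' @export
classify_restricted <- function(tmeans, ann, params) {
  floor <- params$detection_floor
  if (is.null(floor))
    stop("detection_floor must be resolved to a number before classification",
         call. = FALSE)
  som <- somatic_tissues(tmeans, ann)
  target_ts <- unlist(lapply(params$target_classes, tissues_of_class,
                             ann = ann))
  target_ts <- intersect(colnames(tmeans), target_ts)
  silent_somatic <- rowSums(tmeans[, som, drop = FALSE] > floor) == 0L
  expressed_target <- rowSums(tmeans[, target_ts, drop = FALSE] > floor) > 0L
  restricted <- silent_somatic & expressed_target
  cm <- class_means(tmeans, ann, params$target_classes)
  data.frame(gene = rownames(tmeans),
             restricted = restricted,
             target_class = ifelse(restricted, argmax_class(cm), "none"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify tissue-predominant genes
#'
#' A gene is predominant when its largest target-class mean exceeds its atlas
#' threshold; the class is the argmax, ties broken by the `target_classes`
#' order in `params`.
#'
#' @inheritParams classify_restricted
#' @param thresholds per-gene thresholds from [atlas_threshold()] on the same
#'   atlas.
#' @return data frame: gene, predominant (logical), target_class.
#' @export
classify_predominant <- function(tmeans, thresholds, ann, params) {
  if (!all(rownames(tmeans) %in% names(thresholds)))
    stop("thresholds do not cover all genes", call. = FALSE)
  thresholds <- thresholds[rownames(tmeans)]
  cm <- class_means(tmeans, ann, params$target_classes)
  best <- apply(cm, 1L, max)
  predominant <- best > thresholds
  data.frame(gene = rownames(tmeans),
             predominant = predominant,
             target_class = ifelse(predominant, argmax_class(cm), "none"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Build the per-gene specificity table
#'
#' Runs the full atlas stage: per-tissue means, per-gene somatic
#' mean + k * SD thresholds, restricted and predominant classification. Every
#' gene receives exactly one status; a gene qualifying as both restricted and
#' predominant is reported restricted (restriction is the stronger claim).
#'
#' @param expr atlas `expr_matrix`.
#' @param ann a `tissue_annotation` covering every sample; each of the
#'   parameter's target classes must own at least one tissue.
#' @param params a `specificity_params`; a `NULL` `detection_floor` is
#'   resolved to the 25th percentile of all atlas values.
#' @return a `specificity_table` data frame: gene, status
#'   (`restricted`/`predominant`/`unrestricted`), target_class,
#'   atlas_threshold, and one `mean_<class>` column per target class, with
#'   the resolved parameters attached as attributes.
#' @export
build_specificity_table <- function(expr, ann, params = specificity_params()) {
  check_samples_annotated(expr, ann)
  for (cl in params$target_classes)
    if (!length(tissues_of_class(ann, cl)))
      stop("target class has no tissue in the annotation: ", cl,
           call. = FALSE)
  if (is.null(params$detection_floor))
    params$detection_floor <-
      as.numeric(stats::quantile(unclass(expr), 0.25, names = FALSE))
  tm <- tissue_means(expr, ann)
  thr <- atlas_threshold(tm, ann, params)
  res <- classify_restricted(tm, ann, params)
  pre <- classify_predominant(tm, thr, ann, params)
  status <- ifelse(res$restricted, "restricted",
                   ifelse(pre$predominant, "predominant", "unrestricted"))
  target_class <- ifelse(res$restricted, res$target_class,
                         ifelse(pre$predominant, pre$target_class, "none"))
  cm <- class_means(tm, ann, params$target_classes)
  out <- data.frame(gene = rownames(tm), status = status,
                    target_class = target_class, atlas_threshold = thr,
                    row.names = NULL, stringsAsFactors = FALSE)
  for (cl in params$target_classes)
    out[[paste0("mean_", cl)]] <- cm[, cl]
  attr(out, "params") <- params
  attr(out, "scale_tag") <- expr_scale(expr)
  class(out) <- c("specificity_table", "data.frame")
  out
}
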