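#' Construct an expression matrix
#'
#' The common currency of every pipeline stage: a numeric gene x sample
#' intensity matrix tagged with its working scale. On the `linear` scale all
#' values must be non-negative; on the `log2` scale negative values are
#' permitted (log2 of an intensity below 1). All values must be finite and
#' gene/sample identifiers must be unique.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param scale working scale, `"log2"` or `"linear"`.
#' @return an object of class `expr_matrix` (a numeric matrix with a
#'   `scale_tag` attribute).
#' @export
expression_matrix <- function(values, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "), call. = FALSE)
  if (any(!is.finite(values)))
    stop("expression values must be finite (no NA/NaN/Inf)", call. = FALSE)
  if (scale == "linear" && any(values < 0))
    stop("linear-scale intensities must be non-negative", call. = FALSE)
  structure(values, scale_tag = scale, class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, scale = %s\n",
              nrow(x), ncol(x), expr_scale(x)))
  invisible(x)
}

#' Working scale of an expression matrix
#' @param x an `expr_matrix`.
#' @return `"log2"` or `"linear"`.
#' @export
expr_scale <- function(x) {
  s <- attr(x, "scale_tag")
  if (is.null(s)) stop("not an expr_matrix: missing scale_tag", call. = FALSE)
  s
}

#' Convert a linear-scale matrix to log2(x + 1)
#'
#' Identity on matrices already tagged `log2`.
#' @param x an `expr_matrix`.
#' @return an `expr_matrix` on the log2 scale.
#' @export
to_log2 <- function(x) {
  if (expr_scale(x) == "log2") return(x)
  expression_matrix(log2(unclass(x) + 1), scale = "log2")
}

stopifnot_same_scale <- function(a, b, what = "matrices") {
  if (expr_scale(a) != expr_scale(b))
    stop(sprintf("%s are on different working scales (%s vs %s)",
                 what, expr_scale(a), expr_scale(b)), call. = FALSE)
  invisible(TRUE)
}

#' Construct a tissue annotation
#'
#' Maps every atlas sample to a tissue label and every tissue label to one of
#' the four tissue classes. The class partition drives the specificity logic:
#' `somatic` tissues define the atlas threshold; `germline`, `placenta` and
#' `embryonic_stem` are the target classes screened for restriction and
#' predominance.
#'
#' @param sample_id character vector of sample ids.
#' @param tissue_label character vector, same length, tissue of each sample.
#' @param class character vector, same length: class of each sample's tissue,
#'   one of `"somatic"`, `"germline"`, `"placenta"`, `"embryonic_stem"`.
#'   Must be constant within a tissue label.
#' @return a `tissue_annotation` data frame.
#' @export
tissue_annotation <- function(sample_id, tissue_label, class) {
  valid <- c("somatic", "germline", "placenta", "embryonic_stem")
  if (length(sample_id) != length(tissue_label) ||
      length(sample_id) != length(class))
    stop("sample_id, tissue_label and class must have equal length",
         call. = FALSE)
  if (anyDuplicated(sample_id))
    stop("duplicate sample ids in annotation: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(class), valid)
  if (length(bad))
    stop("unknown tissue class: ", paste(bad, collapse = ", "), call. = FALSE)
  per_tissue <- tapply(class, tissue_label, function(z) length(unique(z)))
  if (any(per_tissue > 1))
    stop("tissue labels mapped to more than one class: ",
         paste(names(per_tissue)[per_tissue > 1], collapse = ", "),
         call. = FALSE)
  ann <- data.frame(sample_id = as.character(sample_id),
                    tissue_label = as.character(tissue_label),
                    class = as.character(class),
                    stringsAsFactors = FALSE)
  class(ann) <- c("tissue_annotation", "data.frame")
  ann
}

#' Tissue labels belonging to a class
#' @param ann a `tissue_annotation`.
#' @param cls a tissue class.
#' @return character vector of tissue labels.
#' @export
tissues_of_class <- function(ann, cls) {
  unique(ann$tissue_label[ann$class == cls])
}

check_samples_annotated <- function(expr, ann) {
  missing <- setdiff(colnames(expr), ann$sample_id)
  if (length(missing))
    stop("samples without tissue annotation: ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}
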