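#' Per-dataset ectopic call set
#'
#' Holds the gene set called ectopic in one independently processed dataset,
#' with the aggregation mode used. Gene ids are normalized (uppercased,
#' whitespace stripped) so that symbol-cased lists from different platforms
#' compare; symbol aliases are deliberately not resolved.
#'
#' @param dataset_id label for the dataset.
#' @param genes character vector of ectopic genes.
#' @param mode_used aggregation mode the set was built with, `"all"` or
#'   `"any"`.
#' @return a `dataset_calls` list.
#' @export
dataset_calls <- function(dataset_id, genes, mode_used = c("all", "any")) {
  mode_used <- match.arg(mode_used)
  structure(list(dataset_id = as.character(dataset_id),
                 genes = unique(normalize_gene_ids(genes)),
                 mode_used = mode_used),
            class = "dataset_calls")
}

#' Normalize gene identifiers for cross-dataset comparison
#' @param genes character vector.
#' @return uppercased, whitespace-stripped ids.
#' @export
normalize_gene_ids <- function(genes) {
  toupper(trimws(as.character(genes)))
}

#' Cross-dataset concordance report
#'
#' Counts, for every gene called in at least one dataset, the datasets
#' supporting it.
#'
#' @param calls list of `dataset_calls`.
#' @return a `concordance_report` data frame: gene, n_datasets, datasets
#'   (comma-separated ids), sorted by decreasing support.
#' @export
concordance_report <- function(calls) {
  if (!length(calls)) stop("need at least one dataset", call. = FALSE)
  if (!all(vapply(calls, inherits, logical(1), "dataset_calls")))
    stop("`calls` must be a list of dataset_calls objects", call. = FALSE)
  ids <- vapply(calls, `[[`, character(1), "dataset_id")
  if (anyDuplicated(ids))
    stop("duplicate dataset ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  long <- data.frame(
    gene = unlist(lapply(calls, `[[`, "genes"), use.names = FALSE),
    dataset = rep(ids, vapply(calls, function(x) length(x$genes), integer(1))),
    stringsAsFactors = FALSE)
  support <- split(long$dataset, long$gene)
  out <- data.frame(gene = names(support),
                    n_datasets = vapply(support, length, integer(1)),
                    datasets = vapply(support, paste, character(1),
                                      collapse = ","),
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(-out$n_datasets, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_total_datasets") <- length(calls)
  class(out) <- c("concordance_report", "data.frame")
  out
}

#' Genes replicated in at least k datasets
#'
#' @param calls list of `dataset_calls`.
#' @param min_datasets minimum number of supporting datasets (>= 1). A value
#'   exceeding the number of datasets yields an empty set with a warning.
#' @return character vector of normalized gene ids.
#' @export
replicated_genes <- function(calls, min_datasets = 2) {
  if (!is.numeric(min_datasets) || length(min_datasets) != 1 ||
      min_datasets < 1 || min_datasets != round(min_datasets))
    stop("min_datasets must be a positive integer", call. = FALSE)
  report <- concordance_report(calls)
  if (min_datasets > attr(report, "n_total_datasets"))
    warning("min_datasets (", min_datasets, ") exceeds the number of ",
            "datasets (", attr(report, "n_total_datasets"),
            "); returning the empty set", call. = FALSE)
  sort(report$gene[report$n_datasets >= min_datasets])
}

#' Mark report genes against a reference set
#'
#' Annotates a concordance report with membership in a reference gene set
#' (e.g. the restricted-only genes from the primary cohort).
#'
#' @param report a `concordance_report`.
#' @param reference_set character vector of reference genes (normalized
#'   internally).
#' @return the report with an added logical `in_reference` column and a
#'   `n_in_reference` attribute.
#' @export
cross_reference <- function(report, reference_set) {
  ref <- unique(normalize_gene_ids(reference_set))
  report$in_reference <- report$gene %in% ref
  attr(report, "n_in_reference") <- sum(report$in_reference)
  report
}
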