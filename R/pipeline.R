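#' Run the full off-context detection pipeline
#'
#' Atlas classification, control thresholds, ectopic calls, group
#' assignment and gene-set aggregation, with all artifacts written to
#' `out_dir`. Inputs may be in-memory objects or file paths (expression as
#' TSV/CSV/GCT, annotations as TSV). All inputs are loaded and validated
#' before any output is written, so a failing run leaves no partial
#' artifacts.
#'
#' Written artifacts: `specificity_table.tsv`, `ectopic_calls.tsv` (per-gene
#' thresholds, per-case flags, group), `genes_all.tsv` / `genes_any.tsv`
#' (candidate genes flagged in every / at least one case),
#' `genes_any_restricted.tsv` (the any-patient set limited to the
#' restricted-only candidate universe), `heatmap_matrix.tsv` (values of the
#' any-flagged genes across control and case samples, for external
#' plotting) and `summary.json` (parameters, counts, seed, versions).
#'
#' @param atlas atlas `expr_matrix` or path.
#' @param annotation `tissue_annotation` or path.
#' @param cases,controls case/control `expr_matrix` or paths. Alternatively
#'   give `cases` as the full cohort matrix and `condition` to split it.
#' @param condition optional condition annotation (data frame or TSV path
#'   with sample_id, condition) splitting a single cohort matrix.
#' @param out_dir output directory (created if absent).
#' @param scale working scale used when reading matrices from files.
#' @param spec_params a `specificity_params`.
#' @param cparams a `call_params`.
#' @param all_genes when `TRUE`, call ectopic expression for every gene
#'   shared by atlas and cohort rather than only the atlas-flagged
#'   candidates (exploratory escape hatch).
#' @param seed optional integer recorded in the run summary (the pipeline
#'   itself is deterministic; the seed documents upstream simulation).
#' @return invisibly, a list with the specificity table, calls, groups,
#'   aggregated gene sets and the summary.
#' @export
run_pipeline <- function(atlas, annotation, cases, controls = NULL,
                         condition = NULL, out_dir,
                         scale = c("log2", "linear"),
                         spec_params = specificity_params(),
                         cparams = call_params(),
                         all_genes = FALSE, seed = NULL) {
  scale <- match.arg(scale)
  if (is.character(atlas)) atlas <- read_expression(atlas, scale = scale)
  if (is.character(annotation)) annotation <- read_tissue_annotation(annotation)
  if (is.character(cases)) cases <- read_expression(cases, scale = scale)
  if (is.character(controls)) controls <- read_expression(controls,
                                                          scale = scale)
  if (!is.null(condition)) {
    if (is.character(condition)) condition <- read_condition_annotation(condition)
    ids_case <- condition$sample_id[condition$condition == "case"]
    ids_ctrl <- condition$sample_id[condition$condition == "control"]
    miss <- setdiff(c(ids_case, ids_ctrl), colnames(cases))
    if (length(miss))
      stop("condition annotation names samples absent from the cohort ",
           "matrix: ", paste(miss, collapse = ", "), call. = FALSE)
    controls <- expression_matrix(unclass(cases)[, ids_ctrl, drop = FALSE],
                                  scale = expr_scale(cases))
    cases <- expression_matrix(unclass(cases)[, ids_case, drop = FALSE],
                               scale = expr_scale(cases))
  }
  if (is.null(controls))
    stop("controls are required (directly or via a condition annotation)",
         call. = FALSE)
  stopifnot_same_scale(atlas, cases, "atlas and case matrices")
  stopifnot_same_scale(atlas, controls, "atlas and control matrices")

  spec <- build_specificity_table(atlas, annotation, spec_params)
  thresholds <- control_thresholds(controls, cparams)
  candidates <- if (all_genes) {
    intersect(spec$gene, rownames(cases))
  } else {
    spec$gene[spec$status != "unrestricted"]
  }
  calls <- call_ectopic(cases, thresholds, candidates)
  genes_all <- aggregate_calls(calls, "all")
  genes_any <- aggregate_calls(calls, "any")
  groups <- assign_groups(rownames(calls$flags), spec)
  restricted_universe <- spec$gene[spec$status == "restricted"]
  genes_any_restricted <- intersect(genes_any, restricted_universe)

  group_counts <- table(factor(
    groups$group[groups$gene %in% genes_all],
    levels = c("group1_restricted", "group2_germline_predominant",
               "group3_es_predominant", "other")))
  summary <- list(
    parameters = list(
      scale = scale,
      k_atlas = spec_params$k_atlas,
      detection_floor = attr(spec, "params")$detection_floor,
      target_classes = spec_params$target_classes,
      k_control = cparams$k_control,
      epsilon = attr(thresholds, "epsilon"),
      all_genes = all_genes),
    counts = list(
      n_genes_atlas = nrow(spec),
      n_restricted = sum(spec$status == "restricted"),
      n_predominant = sum(spec$status == "predominant"),
      n_candidates = length(candidates),
      n_flagged_all_cases = length(genes_all),
      n_flagged_any_case = length(genes_any),
      n_flagged_any_case_restricted_only = length(genes_any_restricted),
      groups_all_cases = as.list(group_counts)),
    n_cases = ncol(cases), n_controls = ncol(controls),
    seed = seed,
    versions = list(r = as.character(getRversion()),
                    offcontext = as.character(
                      utils::packageVersion("offcontext"))),
    rng = "Mersenne-Twister (R default)")

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_specificity_table(spec, file.path(out_dir, "specificity_table.tsv"))
  write_call_matrix(calls, file.path(out_dir, "ectopic_calls.tsv"), groups)
  write_gene_set(genes_all, file.path(out_dir, "genes_all.tsv"))
  write_gene_set(genes_any, file.path(out_dir, "genes_any.tsv"))
  write_gene_set(genes_any_restricted,
                 file.path(out_dir, "genes_any_restricted.tsv"))
  if (length(genes_any)) {
    hm <- cbind(unclass(controls)[genes_any, , drop = FALSE],
                unclass(cases)[genes_any, , drop = FALSE])
    hm_df <- data.frame(gene = genes_any, signif(hm, 6),
                        check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    hm_df <- data.frame(gene = character(0))
  }
  utils::write.table(hm_df, file.path(out_dir, "heatmap_matrix.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(list(spec_table = spec, thresholds = thresholds, calls = calls,
                 groups = groups, genes_all = genes_all,
                 genes_any = genes_any,
                 genes_any_restricted = genes_any_restricted,
                 summary = summary))
}
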