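#' Read an expression matrix
#'
#' Supported formats: TSV/CSV with the first column holding gene ids and one
#' column per sample, and GCT 1.2 (`#1.2` header, dimensions line, `Name` /
#' `Description` columns). Duplicate gene ids are collapsed to the per-gene,
#' per-sample maximum (conservative for presence-calling); genes with any
#' missing cell are dropped. Both filters are logged via `message()` and
#' recorded in attributes `n_collapsed` and `n_dropped`.
#'
#' @param path file path.
#' @param format `"tsv"`, `"csv"` or `"gct"`; default guesses from the file
#'   extension (anything not `.csv`/`.gct` reads as TSV).
#' @param scale working-scale tag to attach, `"log2"` or `"linear"`.
#' @return an `expr_matrix`.
#' @export
read_expression <- function(path, format = NULL,
                            scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("csv", "gct")) ext else "tsv"
  }
  format <- match.arg(format, c("tsv", "csv", "gct"))
  if (format == "gct") {
    df <- read_gct_body(path)
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE,
                            quote = "\"", comment.char = "")
    if (ncol(df) < 2) stop("expression table needs >= 1 sample column",
                           call. = FALSE)
  }
  genes <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col) & col != "NA")
      if (length(bad))
        stop(sprintf("non-numeric cell at row %d, column '%s': '%s'",
                     bad[1], colnames(vals)[j], col[bad[1]]), call. = FALSE)
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- genes

  n_collapsed <- 0L
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    n_collapsed <- length(dup)
    message("collapsing ", n_collapsed,
            " duplicated gene id(s) by per-sample maximum")
    first <- !duplicated(genes)
    base <- m[first, , drop = FALSE]
    rownames(base) <- genes[first]
    for (g in dup) {
      rows <- m[genes == g, , drop = FALSE]
      base[g, ] <- apply(rows, 2L, max)
    }
    m <- base
  }

  incomplete <- rowSums(is.na(m)) > 0
  n_dropped <- sum(incomplete)
  if (n_dropped) {
    message("dropping ", n_dropped, " gene(s) with missing cells")
    m <- m[!incomplete, , drop = FALSE]
  }
  out <- expression_matrix(m, scale = scale)
  attr(out, "n_collapsed") <- n_collapsed
  attr(out, "n_dropped") <- n_dropped
  out
}

read_gct_body <- function(path) {
  lines <- readLines(path, n = 2L)
  if (length(lines) < 2 || trimws(lines[1]) != "#1.2")
    stop("malformed GCT: first line must be '#1.2'", call. = FALSE)
  dims <- suppressWarnings(as.integer(strsplit(trimws(lines[2]),
                                               "[ \t]+")[[1]]))
  if (length(dims) < 2 || anyNA(dims))
    stop("malformed GCT: second line must give row and column counts",
         call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = 2,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "\"", comment.char = "")
  if (ncol(df) < 3)
    stop("malformed GCT: expected Name, Description and sample columns",
         call. = FALSE)
  if (nrow(df) != dims[1] || ncol(df) - 2L != dims[2])
    stop(sprintf(paste0("GCT dimensions line says %d x %d but body has ",
                        "%d x %d"),
                 dims[1], dims[2], nrow(df), ncol(df) - 2L), call. = FALSE)
  df[, -2, drop = FALSE] # drop Description
}

#' Write an expression matrix as TSV
#'
#' Floats are formatted with 6 significant digits, so a write/read
#' round-trip is value-identical at 1e-6 relative tolerance.
#'
#' @param expr an `expr_matrix`.
#' @param path output path.
#' @param gene_col name of the gene id column (default `"gene"`).
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, gene_col = "gene") {
  df <- data.frame(rownames(expr),
                   signif(unclass(expr), 6),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(gene_col, colnames(expr))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tissue annotation TSV
#'
#' Expects columns `sample_id`, `tissue_label`, `class`.
#' @param path file path.
#' @return a `tissue_annotation`.
#' @export
read_tissue_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "tissue_label", "class")
  if (!all(need %in% colnames(df)))
    stop("tissue annotation needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  tissue_annotation(df$sample_id, df$tissue_label, df$class)
}

#' Write a tissue annotation TSV
#' @param ann a `tissue_annotation`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tissue_annotation <- function(ann, path) {
  utils::write.table(as.data.frame(ann), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a case/control condition annotation TSV
#'
#' Expects columns `sample_id`, `condition` with condition in
#' {`case`, `control`}.
#' @param path file path.
#' @return data frame with sample_id and condition.
#' @export
read_condition_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "condition")
  if (!all(need %in% colnames(df)))
    stop("condition annotation needs columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(df$condition), c("case", "control"))
  if (length(bad))
    stop("condition must be 'case' or 'control'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in condition annotation", call. = FALSE)
  df[, need]
}

numeric_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = 6)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a specificity table as TSV
#' @param spec a `specificity_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_specificity_table <- function(spec, path) {
  numeric_tsv(as.data.frame(spec), path)
}

#' Write an ectopic call matrix as TSV
#'
#' One row per candidate gene: control statistics, threshold, one logical
#' flag column per case sample, and (when `groups` is given) the specificity
#' group.
#'
#' @param calls an `ectopic_calls`.
#' @param path output path.
#' @param groups optional data frame from [assign_groups()].
#' @return `path`, invisibly.
#' @export
write_call_matrix <- function(calls, path, groups = NULL) {
  df <- calls$stats
  fl <- as.data.frame(calls$flags)
  colnames(fl) <- paste0("flag_", colnames(calls$flags))
  df <- cbind(df, fl)
  if (!is.null(groups))
    df$group <- groups$group[match(df$gene, groups$gene)]
  numeric_tsv(df, path)
}

#' Read a gene-set TSV (one gene id per line, header `gene`)
#' @param path file path.
#' @return character vector of gene ids.
#' @export
read_gene_set <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  as.character(df[[1]])
}

#' Write a gene set as a one-column TSV
#' @param genes character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_set <- function(genes, path) {
  utils::write.table(data.frame(gene = genes), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a run configuration from a YAML file
#'
#' Mirrors the arguments of [run_pipeline()]; unknown keys are rejected.
#' @param path YAML file path.
#' @return named list of pipeline arguments.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  known <- c("atlas_path", "atlas_annotation_path", "cohort_path",
             "condition_path", "out_dir", "scale", "k_atlas", "k_control",
             "detection_floor", "epsilon", "mode", "seed", "simulate",
             "all_genes")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  cfg
}
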