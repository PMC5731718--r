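# Shared fixtures: small deterministic atlases and random instances used
# across the unit and acceptance tests.

# Atlas with one sample per tissue and hand-chosen values, used for the
# worked examples whose expected numbers were computed by hand.
toy_annotation <- function(n_somatic = 3) {
  tissue <- c(paste0("som", seq_len(n_somatic)), "testis", "placenta",
              "es_cells")
  cls <- c(rep("somatic", n_somatic), "germline", "placenta",
           "embryonic_stem")
  tissue_annotation(sample_id = paste0(tissue, "_s1"),
                    tissue_label = tissue, class = cls)
}

toy_matrix <- function(values, genes, samples, scale = "log2") {
  expression_matrix(matrix(values, nrow = length(genes), byrow = TRUE,
                           dimnames = list(genes, samples)),
                    scale = scale)
}

# Random atlas instance: n_somatic somatic tissues + germline (testis,
# ovary) + placenta + es_cells, spt samples per tissue.
random_atlas <- function(n_genes = 200, n_somatic = 6, spt = 3, seed = 1,
                         mean = 5, sd = 2) {
  set.seed(seed)
  tissue <- c(paste0("som", seq_len(n_somatic)), "testis", "ovary",
              "placenta", "es_cells")
  cls <- c(rep("somatic", n_somatic), "germline", "germline", "placenta",
           "embryonic_stem")
  samples <- paste0(rep(tissue, each = spt), "_s", seq_len(spt))
  ann <- tissue_annotation(samples, rep(tissue, each = spt),
                           rep(cls, each = spt))
  genes <- sprintf("g%03d", seq_len(n_genes))
  expr <- expression_matrix(
    matrix(stats::rnorm(n_genes * length(samples), mean, sd),
           nrow = n_genes, dimnames = list(genes, samples)),
    scale = "log2")
  list(expr = expr, ann = ann)
}

random_cohort <- function(n_genes = 100, n_controls = 5, n_cases = 4,
                          seed = 1, mean = 5, sd = 1) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  ctrl <- expression_matrix(
    matrix(stats::rnorm(n_genes * n_controls, mean, sd), nrow = n_genes,
           dimnames = list(genes, paste0("ctrl", seq_len(n_controls)))),
    scale = "log2")
  cs <- expression_matrix(
    matrix(stats::rnorm(n_genes * n_cases, mean, sd), nrow = n_genes,
           dimnames = list(genes, paste0("case", seq_len(n_cases)))),
    scale = "log2")
  list(controls = ctrl, cases = cs)
}
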