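test_that("tissue means reduce to relabeled columns with one sample per tissue", {
  ann <- toy_annotation()
  expr <- toy_matrix(c(2, 4, 6, 50, 1, 1,
                       3, 3, 3, 3, 3, 3),
                     genes = c("gA", "gB"),
                     samples = ann$sample_id)
  tm <- tissue_means(expr, ann)
  expect_identical(dim(tm), c(2L, 6L))
  expect_equal(unname(tm), matrix(as.numeric(expr), nrow = 2))
  expect_identical(colnames(tm), unique(ann$tissue_label))
})

test_that("tissue means average within tissues and match the scalar oracle", {
  # two samples in one tissue: {4, 6} -> 5
  ann <- tissue_annotation(c("s1", "s2", "s3", "s4"),
                           c("liver", "liver", "kidney", "testis"),
                           c("somatic", "somatic", "somatic", "germline"))
  expr <- toy_matrix(c(4, 6, 2, 9), "gA", c("s1", "s2", "s3", "s4"))
  tm <- tissue_means(expr, ann)
  expect_equal(tm["gA", "liver"], 5)

  inst <- random_atlas(n_genes = 50, n_somatic = 1, spt = 4, seed = 42)
  expect_equal(tissue_means(inst$expr, inst$ann),
               oracle_tissue_means(inst$expr, inst$ann), tolerance = 1e-12)
})

test_that("tissue means reject unannotated samples and empty tissues", {
  ann <- toy_annotation()
  expr <- toy_matrix(rep(1, 7), "gA", c(ann$sample_id, "mystery"))
  expect_error(tissue_means(expr, ann), "mystery")
})

test_that("atlas threshold is somatic mean + k * SD over tissue means", {
  ann <- toy_annotation(n_somatic = 3)
  # somatic tissue means {2,4,6}: mean 4, sample SD 2 -> 4 + 3*2 = 10
  expr <- toy_matrix(c(2, 4, 6, 0, 0, 0,
                       5, 5, 5, 0, 0, 0),
                     genes = c("gA", "gB"), samples = ann$sample_id)
  thr <- atlas_threshold(tissue_means(expr, ann), ann)
  expect_equal(unname(thr["gA"]), 10)
  expect_equal(unname(thr["gB"]), 5) # zero variance

  inst <- random_atlas(n_genes = 200, seed = 7)
  tm <- tissue_means(inst$expr, inst$ann)
  expect_equal(atlas_threshold(tm, inst$ann, specificity_params(k_atlas = 3)),
               oracle_atlas_threshold(tm, inst$ann, 3), tolerance = 1e-12)
})

test_that("atlas threshold requires at least two somatic tissues", {
  ann <- tissue_annotation(c("s1", "s2"), c("liver", "testis"),
                           c("somatic", "germline"))
  expr <- toy_matrix(c(1, 2), "gA", c("s1", "s2"))
  expect_error(atlas_threshold(tissue_means(expr, ann), ann),
               ">= 2 somatic tissues")
})

test_that("restriction requires somatic silence plus target presence", {
  ann <- toy_annotation()
  p <- specificity_params(detection_floor = 1)
  # gA: silent somatic, high germline -> restricted(germline)
  # gB: one somatic tissue at 2x floor -> not restricted
  # gC: silent everywhere -> not restricted (no target presence)
  expr <- toy_matrix(c(0, 0, 0, 50, 0.5, 0.5,
                       0, 2, 0, 50, 0.5, 0.5,
                       0, 0, 0, 0.5, 0.5, 0.5),
                     genes = c("gA", "gB", "gC"), samples = ann$sample_id)
  res <- classify_restricted(tissue_means(expr, ann), ann, p)
  expect_identical(res$restricted, c(TRUE, FALSE, FALSE))
  expect_identical(res$target_class[1], "germline")
})

test_that("predominance compares the best class mean to the atlas threshold", {
  ann <- toy_annotation()
  p <- specificity_params(detection_floor = 0)
  # somatic means {2,4,6} -> threshold 10
  expr <- toy_matrix(c(2, 4, 6, 12, 3, 3,    # germline 12 > 10
                       2, 4, 6, 9, 8, 7,     # all class means <= 10
                       2, 4, 6, 12, 3, 12),  # germline/ES tie at 12
                     genes = c("gA", "gB", "gC"), samples = ann$sample_id)
  tm <- tissue_means(expr, ann)
  thr <- atlas_threshold(tm, ann, p)
  pre <- classify_predominant(tm, thr, ann, p)
  expect_identical(pre$predominant, c(TRUE, FALSE, TRUE))
  expect_identical(pre$target_class, c("germline", "none", "germline"))
})

test_that("specificity table gives restriction precedence and recovers planted truth", {
  ann <- toy_annotation()
  # silent somatic (all below resolved floor), germline far above both the
  # floor and the somatic mean+3SD threshold: restricted wins over predominant
  expr <- toy_matrix(c(0, 0, 0, 50, 0, 0,
                       5, 5, 5, 5, 5, 5),
                     genes = c("gA", "gB"), samples = ann$sample_id)
  spec <- build_specificity_table(expr, ann,
                                  specificity_params(detection_floor = 1))
  expect_identical(spec$status[spec$gene == "gA"], "restricted")

  cfg <- synthetic_config(n_genes = 500, seed = 11)
  atlas <- generate_atlas(cfg)
  spec <- build_specificity_table(atlas$expr, atlas$annotation)
  expect_identical(spec$status, atlas$truth$genes$status)
  expect_identical(spec$target_class[spec$status != "unrestricted"],
                   atlas$truth$genes$class[spec$status != "unrestricted"])
})

test_that("specificity table errors when a target class has no tissue", {
  ann <- tissue_annotation(c("s1", "s2", "s3"),
                           c("liver", "kidney", "testis"),
                           c("somatic", "somatic", "germline"))
  expr <- toy_matrix(c(1, 2, 3), "gA", c("s1", "s2", "s3"))
  expect_error(build_specificity_table(expr, ann), "placenta")
})

test_that("statuses partition the gene set", {
  inst <- random_atlas(n_genes = 300, seed = 3)
  spec <- build_specificity_table(inst$expr, inst$ann)
  expect_identical(nrow(spec), 300L)
  expect_true(all(spec$status %in%
                    c("restricted", "predominant", "unrestricted")))
  expect_identical(spec$status == "unrestricted",
                   spec$target_class == "none")
})

test_that("linear-scale verdicts are equivariant under intensity rescaling", {
  for (seed in 1:5) {
    inst <- random_atlas(n_genes = 80, seed = seed)
    vals <- abs(unclass(inst$expr))
    expr1 <- expression_matrix(vals, scale = "linear")
    floor1 <- as.numeric(quantile(vals, 0.25))
    c_scale <- 3.7
    expr2 <- expression_matrix(vals * c_scale, scale = "linear")
    s1 <- build_specificity_table(expr1, inst$ann,
                                  specificity_params(detection_floor = floor1))
    s2 <- build_specificity_table(expr2, inst$ann,
                                  specificity_params(detection_floor =
                                                       floor1 * c_scale))
    expect_identical(s1$status, s2$status)
    expect_identical(s1$target_class, s2$target_class)
    expect_equal(s2$atlas_threshold, s1$atlas_threshold * c_scale,
                 tolerance = 1e-12)
  }
})

test_that("raising a gene's target-class expression never revokes predominance", {
  inst <- random_atlas(n_genes = 40, seed = 9)
  ann <- inst$ann
  spec <- build_specificity_table(inst$expr, ann)
  pred_before <- spec$gene[spec$status == "predominant"]
  v <- unclass(inst$expr)
  germ <- ann$sample_id[ann$class == "germline"]
  v[, germ] <- v[, germ] + 2 # raise every gene's germline expression
  spec2 <- build_specificity_table(
    expression_matrix(v, "log2"), ann,
    specificity_params(detection_floor =
                         attr(spec, "params")$detection_floor))
  # genes predominant before stay flagged (possibly reclassified restricted)
  expect_true(all(spec2$status[spec2$gene %in% pred_before] != "unrestricted"))
})
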