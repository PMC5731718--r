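ctrl_matrix <- function(values, genes = "gA") {
  toy_matrix(values, genes, paste0("c", seq_len(length(values) / length(genes))))
}

test_that("control threshold is mean + k * max(SD, epsilon)", {
  p0 <- call_params(epsilon = 0)
  # controls {2,4,6}: mean 4, sample SD 2 -> 4 + 3*2 = 10
  expect_equal(control_thresholds(ctrl_matrix(c(2, 4, 6)), p0)$threshold, 10)
  # zero variance, eps 0 -> threshold collapses onto the mean
  expect_equal(control_thresholds(ctrl_matrix(c(5, 5, 5)), p0)$threshold, 5)
  # zero variance, eps 0.1 -> 5 + 3*0.1
  expect_equal(control_thresholds(ctrl_matrix(c(5, 5, 5)),
                                  call_params(epsilon = 0.1))$threshold, 5.3)
})

test_that("control thresholds match the per-gene scalar oracle", {
  co <- random_cohort(n_genes = 150, seed = 5)
  thr <- control_thresholds(co$controls, call_params(epsilon = 0))
  expect_equal(stats::setNames(thr$threshold, thr$gene),
               oracle_control_thresholds(co$controls), tolerance = 1e-12)
})

test_that("fewer than two controls is an error", {
  expect_error(control_thresholds(ctrl_matrix(5)), ">= 2 control samples")
})

test_that("calls use a strict inequality at the threshold", {
  thr <- control_thresholds(ctrl_matrix(c(2, 4, 6)), call_params(epsilon = 0))
  cases <- toy_matrix(c(10.5, 10, 9), "gA", c("p1", "p2", "p3"))
  calls <- call_ectopic(cases, thr)
  expect_identical(unname(calls$flags["gA", ]), c(TRUE, FALSE, FALSE))
})

test_that("calls are restricted to the candidate set", {
  co <- random_cohort(n_genes = 10, seed = 2)
  thr <- control_thresholds(co$controls)
  calls <- call_ectopic(co$cases, thr, candidates = c("g001", "g002"))
  expect_identical(rownames(calls$flags), c("g001", "g002"))
  expect_error(call_ectopic(co$cases, thr, candidates = "nope"),
               "missing from the case matrix")
})

test_that("aggregation implements conjunction and disjunction over cases", {
  flags <- matrix(c(TRUE, TRUE, TRUE,
                    TRUE, FALSE, TRUE),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(c("g1", "g2"), c("p1", "p2", "p3")))
  calls <- structure(list(stats = NULL, flags = flags),
                     class = "ectopic_calls")
  expect_identical(aggregate_calls(calls, "all"), "g1")
  expect_identical(aggregate_calls(calls, "any"), c("g1", "g2"))
})

test_that("aggregation matches a loop oracle and nests all within any", {
  for (seed in 1:5) {
    set.seed(seed)
    flags <- matrix(runif(500) < 0.4, nrow = 100,
                    dimnames = list(sprintf("g%03d", 1:100),
                                    paste0("p", 1:5)))
    calls <- structure(list(stats = NULL, flags = flags),
                       class = "ectopic_calls")
    g_all <- aggregate_calls(calls, "all")
    g_any <- aggregate_calls(calls, "any")
    expect_identical(g_all, oracle_aggregate(flags, "all"))
    expect_identical(g_any, oracle_aggregate(flags, "any"))
    expect_true(all(g_all %in% g_any))
  }
})

test_that("group assignment follows the restricted/predominant partition", {
  spec <- data.frame(
    gene = c("r_pla", "r_ger", "r_es", "p_ger", "p_es", "p_pla", "un"),
    status = c("restricted", "restricted", "restricted", "predominant",
               "predominant", "predominant", "unrestricted"),
    target_class = c("placenta", "germline", "embryonic_stem", "germline",
                     "embryonic_stem", "placenta", "none"),
    stringsAsFactors = FALSE)
  g <- assign_groups(spec$gene, spec)
  expect_identical(g$group,
                   c("group1_restricted", "group1_restricted", "other",
                     "group2_germline_predominant", "group3_es_predominant",
                     "other", "other"))
  expect_error(assign_groups("missing", spec), "absent")
})

test_that("group partition is disjoint and exhaustive on random gene sets", {
  for (seed in 1:5) {
    inst <- random_atlas(n_genes = 120, seed = seed, sd = 3)
    spec <- build_specificity_table(inst$expr, inst$ann)
    genes <- sample(spec$gene, 60)
    g <- assign_groups(genes, spec)
    expect_identical(nrow(g), 60L)
    expect_identical(g$gene, genes)
    expect_true(all(g$group %in% c("group1_restricted",
                                   "group2_germline_predominant",
                                   "group3_es_predominant", "other")))
  }
})

test_that("raising a case value never unflags it, lowering never flags it", {
  co <- random_cohort(n_genes = 60, seed = 8)
  thr <- control_thresholds(co$controls)
  calls <- call_ectopic(co$cases, thr)
  v <- unclass(co$cases)
  up <- call_ectopic(expression_matrix(v + abs(rnorm(length(v))), "log2"),
                     thr)
  down <- call_ectopic(expression_matrix(v - abs(rnorm(length(v))), "log2"),
                       thr)
  expect_true(all(up$flags[calls$flags]))
  expect_false(any(down$flags[!calls$flags]))
})

test_that("flags are invariant under linear rescaling when epsilon is zero", {
  co <- random_cohort(n_genes = 80, seed = 13)
  p0 <- call_params(epsilon = 0)
  lin <- function(x, c_scale = 1)
    expression_matrix(abs(unclass(x)) * c_scale, "linear")
  f1 <- call_ectopic(lin(co$cases),
                     control_thresholds(lin(co$controls), p0))$flags
  f2 <- call_ectopic(lin(co$cases, 11.3),
                     control_thresholds(lin(co$controls, 11.3), p0))$flags
  expect_identical(f1, f2)
})

test_that("permutation null separates activated genes from null genes", {
  set.seed(31)
  genes <- sprintf("g%02d", 1:20)
  ctrl <- expression_matrix(
    matrix(rnorm(20 * 3, 5, 0.5), nrow = 20,
           dimnames = list(genes, paste0("c", 1:3))), "log2")
  cs <- matrix(rnorm(20 * 3, 5, 0.5), nrow = 20,
               dimnames = list(genes, paste0("p", 1:3)))
  cs["g01", ] <- cs["g01", ] + 5 # strong activation in every case
  cases <- expression_matrix(cs, "log2")
  res <- permutation_null(cases, ctrl, n_perm = 200, seed = 1)
  # activated gene at the permutation floor; typical null gene far above
  expect_lt(res$p_value[res$gene == "g01"], 0.1)
  expect_gt(median(res$p_value[res$gene != "g01"]), 0.3)
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
})
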