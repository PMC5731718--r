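# Naive scalar re-derivations of every statistic, used as independent
# oracles against the vectorized implementation. These deliberately use
# base mean()/sd() in per-gene loops and share no code with the package
# internals.

oracle_tissue_means <- function(expr, ann) {
  tissues <- unique(ann$tissue_label[ann$sample_id %in% colnames(expr)])
  out <- matrix(NA_real_, nrow(expr), length(tissues),
                dimnames = list(rownames(expr), tissues))
  for (g in rownames(expr)) {
    for (t in tissues) {
      s <- ann$sample_id[ann$tissue_label == t]
      out[g, t] <- mean(unclass(expr)[g, s])
    }
  }
  out
}

oracle_atlas_threshold <- function(tmeans, ann, k = 3) {
  som <- unique(ann$tissue_label[ann$class == "somatic"])
  som <- intersect(colnames(tmeans), som)
  out <- numeric(nrow(tmeans))
  names(out) <- rownames(tmeans)
  for (g in rownames(tmeans)) {
    x <- tmeans[g, som]
    out[g] <- mean(x) + k * stats::sd(x)
  }
  out
}

oracle_class_mean <- function(tmeans, ann, cl) {
  ts <- intersect(colnames(tmeans),
                  unique(ann$tissue_label[ann$class == cl]))
  vapply(rownames(tmeans), function(g) mean(tmeans[g, ts]), numeric(1))
}

oracle_status <- function(tmeans, ann, k, floor,
                          target_classes = c("germline", "placenta",
                                             "embryonic_stem")) {
  thr <- oracle_atlas_threshold(tmeans, ann, k)
  som <- intersect(colnames(tmeans),
                   unique(ann$tissue_label[ann$class == "somatic"]))
  target_ts <- intersect(colnames(tmeans),
                         unique(ann$tissue_label[ann$class %in%
                                                   target_classes]))
  cm <- sapply(target_classes, function(cl) oracle_class_mean(tmeans, ann, cl))
  status <- character(nrow(tmeans))
  tclass <- character(nrow(tmeans))
  for (i in seq_len(nrow(tmeans))) {
    g <- rownames(tmeans)[i]
    silent <- all(tmeans[g, som] <= floor)
    present <- any(tmeans[g, target_ts] > floor)
    best <- target_classes[which.max(cm[i, ])]
    if (silent && present) {
      status[i] <- "restricted"; tclass[i] <- best
    } else if (max(cm[i, ]) > thr[g]) {
      status[i] <- "predominant"; tclass[i] <- best
    } else {
      status[i] <- "unrestricted"; tclass[i] <- "none"
    }
  }
  data.frame(gene = rownames(tmeans), status = status,
             target_class = tclass, stringsAsFactors = FALSE)
}

oracle_control_thresholds <- function(controls, k = 3, eps = 0) {
  out <- numeric(nrow(controls))
  names(out) <- rownames(controls)
  for (g in rownames(controls)) {
    x <- unclass(controls)[g, ]
    out[g] <- mean(x) + k * max(stats::sd(x), eps)
  }
  out
}

oracle_flags <- function(cases, tau) {
  out <- matrix(NA, nrow(cases), ncol(cases),
                dimnames = dimnames(unclass(cases)))
  for (g in rownames(cases))
    for (s in colnames(cases))
      out[g, s] <- unclass(cases)[g, s] > tau[g]
  out
}

oracle_aggregate <- function(flags, mode) {
  keep <- logical(nrow(flags))
  for (i in seq_len(nrow(flags)))
    keep[i] <- if (mode == "all") all(flags[i, ]) else any(flags[i, ])
  rownames(flags)[keep]
}

oracle_support_counts <- function(sets) {
  genes <- unique(toupper(trimws(unlist(sets))))
  counts <- integer(length(genes))
  names(counts) <- genes
  for (g in genes)
    for (s in sets)
      if (g %in% toupper(trimws(s))) counts[g] <- counts[g] + 1L
  counts
}
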