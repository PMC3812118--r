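# Regulator -> target analyses across development: family-mean r^2 for
# known edges, interactor-vs-random permutation tests with a
# topology-preserving rewiring null, sensitive/insensitive classification
# by ordinary least squares, trend and paternal-variance-by-class tests,
# and the tissue-composition control.

# family-mean matrix at one time point: rows = families (dam x sire),
# columns = genes
fam_matrix <- function(expr, timepoint, genes = NULL) {
  fm <- family_means(dplyr::filter(expr, .data$timepoint == !!timepoint))
  if (!is.null(genes)) fm <- dplyr::filter(fm, .data$gene %in% genes)
  wide <- tidyr::pivot_wider(fm, id_cols = c("dam_id", "sire_id"),
                             names_from = "gene", values_from = "value")
  m <- as.matrix(wide[, -(1:2), drop = FALSE])
  rownames(m) <- paste(wide$dam_id, wide$sire_id, sep = "x")
  m
}

#' Squared correlation between two genes' family means
#'
#' Pearson r^2 over family (dam x sire) mean expression at one time point;
#' replicates are averaged first. `NA` when either gene has zero variance
#' or fewer than `min_families` paired means are available.
#'
#' @param expr long expression tibble.
#' @param a,b gene identifiers.
#' @param timepoint time point.
#' @param min_families minimum paired family means (default 5).
#' @return r^2 in `[0, 1]`, or `NA`.
#' @export
pairwise_r2 <- function(expr, a, b, timepoint, min_families = 5) {
  m <- fam_matrix(expr, timepoint, genes = c(a, b))
  if (!all(c(a, b) %in% colnames(m))) {
    stop("gene(s) absent at that time point", call. = FALSE)
  }
  ok <- stats::complete.cases(m[, c(a, b)])
  if (sum(ok) < min_families) return(NA_real_)
  x <- m[ok, a]; y <- m[ok, b]
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)^2
}

# r^2 lookup matrix over a family-mean matrix
r2_matrix <- function(m) {
  suppressWarnings(cor(m, use = "pairwise.complete.obs"))^2
}

# one rewiring of the active edges onto non-interacting pairs.
# mode "degree": shuffle the target stubs among edges (preserving the
# out-degree sequence and the in-degree multiset), rejecting self-pairs and
# known-interacting pairs, with a per-edge uniform fallback when the
# shuffle cannot place an edge; mode "uniform": sample |E| non-interacting
# pairs outright.
rewire_edges <- function(src, tgt, genes, linked_keys, nonint, mode) {
  n_e <- length(src)
  if (mode == "uniform") {
    idx <- sample.int(nrow(nonint), n_e, replace = nrow(nonint) < n_e)
    return(cbind(nonint$a[idx], nonint$b[idx]))
  }
  for (attempt in 1:20) {
    new_tgt <- sample(tgt)
    bad <- new_tgt == src | pair_key(src, new_tgt) %in% linked_keys
    if (!any(bad)) return(cbind(src, new_tgt))
    if (attempt == 20) {
      for (i in which(bad)) {
        cand <- which(nonint$a == src[i] | nonint$b == src[i])
        if (length(cand) == 0) cand <- seq_len(nrow(nonint))
        j <- cand[sample.int(length(cand), 1)]
        new_tgt[i] <- ifelse(nonint$a[j] == src[i], nonint$b[j], nonint$a[j])
      }
      return(cbind(src, new_tgt))
    }
  }
}

#' Do known interactors covary more than random gene pairs?
#'
#' Compares the mean family-mean r^2 over edges active at a time point with
#' a permutation null that rewires the same number of edges onto pairs of
#' active genes with no known interaction, keeping the network's degree
#' structure intact (see `mode`). Also reports a bootstrap confidence
#' interval for the random-pair mean r^2.
#'
#' @param expr long expression tibble.
#' @param net a [network()].
#' @param timepoint time point in 1..6.
#' @param n_perm permutations (default 10000).
#' @param mode `"degree"` (default) shuffles target stubs preserving the
#'   degree sequence; `"uniform"` samples non-interacting pairs outright.
#' @param include_repressing include repressing edges (default TRUE).
#' @param min_samples expression filter floor for active genes.
#' @param n_boot bootstrap replicates for the random-pair mean CI.
#' @return list of class `perm_test`: `observed` (mean r^2 over edges),
#'   `null_stats`, `p_value`, `n_edges`, `random_mean`, `random_ci`,
#'   `timepoint`.
#' @export
interactor_vs_random_test <- function(expr, net, timepoint, n_perm = 10000,
                                      mode = c("degree", "uniform"),
                                      include_repressing = TRUE,
                                      min_samples = 20, n_boot = 200) {
  mode <- match.arg(mode)
  act <- active_genes(net, timepoint, expr, min_samples, include_repressing)
  ae <- active_edges(net, timepoint, include_repressing)
  ae <- ae[ae$source %in% act & ae$target %in% act, , drop = FALSE]
  if (nrow(ae) < 3) stop("fewer than 3 active edges with expressed endpoints",
                         call. = FALSE)
  nonint <- noninteracting_pairs(net, timepoint, expr, min_samples,
                                 include_repressing)
  if (nrow(nonint) < nrow(ae)) {
    stop("not enough non-interacting pairs to rewire onto", call. = FALSE)
  }
  m <- fam_matrix(expr, timepoint, genes = act)
  R2 <- r2_matrix(m)
  edge_r2 <- R2[cbind(ae$source, ae$target)]
  observed <- mean(edge_r2, na.rm = TRUE)
  linked_keys <- unique(pair_key(net$edges$source, net$edges$target))
  null_stats <- vapply(seq_len(n_perm), function(i) {
    pr <- rewire_edges(ae$source, ae$target, act, linked_keys, nonint, mode)
    mean(R2[pr], na.rm = TRUE)
  }, numeric(1))
  rand_r2 <- R2[cbind(nonint$a, nonint$b)]
  boot_means <- vapply(seq_len(n_boot), function(i) {
    mean(rand_r2[sample.int(length(rand_r2), replace = TRUE)], na.rm = TRUE)
  }, numeric(1))
  structure(list(observed = observed, null_stats = null_stats,
                 p_value = perm_pvalue(null_stats, observed),
                 n_edges = nrow(ae),
                 random_mean = mean(rand_r2, na.rm = TRUE),
                 random_ci = unname(quantile(boot_means, c(0.025, 0.975))),
                 timepoint = timepoint, mode = mode),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat("<perm_test> t =", x$timepoint, ": observed mean r2 =",
      signif(x$observed, 3), "over", x$n_edges, "edges; null mean =",
      signif(mean(x$null_stats), 3), "; p =", signif(x$p_value, 3), "\n")
  invisible(x)
}

#' Classify one regulatory edge as sensitive or insensitive
#'
#' Ordinary least-squares regression of the target's family means on the
#' source's at one time point. The edge is `sensitive` (quantitative) when
#' the slope is significant at `alpha` (two-sided), else `insensitive`
#' (switch-like). Fewer than `min_families` usable family means, or zero
#' variance, leaves the edge unclassified (`NA` label).
#'
#' @param expr long expression tibble.
#' @param source,target gene identifiers (regulator, target).
#' @param timepoint time point.
#' @param alpha significance level (default 0.01).
#' @param min_families minimum family means (default 5).
#' @return one-row tibble: source, target, timepoint, n_families, r2,
#'   slope, p_value, label.
#' @export
classify_edge <- function(expr, source, target, timepoint, alpha = 0.01,
                          min_families = 5) {
  m <- fam_matrix(expr, timepoint, genes = c(source, target))
  if (!all(c(source, target) %in% colnames(m))) {
    return(classify_pair(numeric(0), numeric(0), source, target, timepoint,
                         alpha, min_families))
  }
  classify_pair(m[, source], m[, target], source, target, timepoint,
                alpha, min_families)
}

# OLS of target family means on source family means; the slope t-test
# is the classification criterion
classify_pair <- function(x, y, source, target, timepoint, alpha,
                          min_families) {
  out <- tibble::tibble(source = source, target = target,
                        timepoint = timepoint, n_families = 0L,
                        r2 = NA_real_, slope = NA_real_,
                        p_value = NA_real_, label = NA_character_)
  ok <- !is.na(x) & !is.na(y)
  out$n_families <- sum(ok)
  if (sum(ok) < min_families) return(out)
  x <- x[ok]; y <- y[ok]
  if (sd(x) == 0 || sd(y) == 0) return(out)
  n <- length(x)
  r <- cor(x, y)
  out$r2 <- r^2
  out$slope <- r * sd(y) / sd(x)
  tt <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  out$p_value <- 2 * pt(-abs(tt), df = n - 2)
  out$label <- ifelse(out$p_value < alpha, "sensitive", "insensitive")
  out
}

#' Classify every active edge at every (or one) time point
#'
#' @param expr long expression tibble.
#' @param net a [network()].
#' @param timepoints time points to classify (default 1:6).
#' @param alpha significance level (default 0.01).
#' @param include_repressing include repressing edges (default TRUE).
#' @param min_samples expression filter floor.
#' @param min_families minimum family means per classification.
#' @return tibble of [classify_edge()] rows for each active edge x time
#'   whose endpoints pass the expression filter.
#' @export
classify_edges <- function(expr, net, timepoints = 1:6, alpha = 0.01,
                           include_repressing = TRUE, min_samples = 20,
                           min_families = 5) {
  purrr::map_dfr(timepoints, function(t) {
    act <- active_genes(net, t, expr, min_samples, include_repressing)
    ae <- active_edges(net, t, include_repressing)
    ae <- ae[ae$source %in% act & ae$target %in% act, , drop = FALSE]
    if (nrow(ae) == 0) return(tibble::tibble())
    m <- fam_matrix(expr, t, genes = unique(c(ae$source, ae$target)))
    purrr::map_dfr(seq_len(nrow(ae)), function(i) {
      classify_pair(m[, ae$source[i]], m[, ae$target[i]],
                    ae$source[i], ae$target[i], t, alpha, min_families)
    })
  })
}

#' Does the sensitive/insensitive composition change over time?
#'
#' Chi-square contingency test (no continuity correction) of classified
#' edge counts (label x time point). Time points with no classified edges
#' are dropped with a warning.
#'
#' @param classifications tibble from [classify_edges()].
#' @return tibble: statistic, df, p_value, plus the counts table as an
#'   attribute `"counts"`.
#' @export
sensitivity_trend_test <- function(classifications) {
  cls <- classifications[!is.na(classifications$label), , drop = FALSE]
  counts <- table(cls$timepoint, factor(cls$label,
                                        c("sensitive", "insensitive")))
  empty <- rowSums(counts) == 0
  if (any(empty)) {
    warning("dropping time point(s) with no classified edges: ",
            paste(rownames(counts)[empty], collapse = ", "))
    counts <- counts[!empty, , drop = FALSE]
  }
  if (nrow(counts) < 2) stop("need classified edges at >= 2 time points",
                             call. = FALSE)
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  out <- tibble::tibble(statistic = unname(ct$statistic),
                        df = unname(ct$parameter), p_value = ct$p.value)
  attr(out, "counts") <- counts
  out
}

#' Paternal variance upstream of insensitive versus sensitive edges
#'
#' Maps each classified edge to the scaled sire (paternal) variance
#' component of its source gene at that time point, and compares the two
#' class distributions by a two-sample Kolmogorov-Smirnov test. A second,
#' time-adjusted p-value comes from a linear model of the paternal variance
#' on class plus a time-point factor, which accounts for developmental
#' changes in both the components and the class mix.
#'
#' @param fit an [fit_ncii()] object covering the source genes and times.
#' @param classifications tibble from [classify_edges()].
#' @param scaled use scaled components (default TRUE).
#' @return list: `by_class` (tibble of class means and n), `ks` (tibble:
#'   statistic, p_value), `time_adjusted_p`.
#' @export
paternal_by_class_test <- function(fit, classifications, scaled = TRUE) {
  col <- if (scaled) "scaled_mean" else "mean"
  sire <- dplyr::filter(fit$components, .data$term == "sire")
  sire <- dplyr::select(sire, "gene", "timepoint",
                        paternal = dplyr::all_of(col))
  cls <- dplyr::filter(classifications, !is.na(.data$label))
  dat <- dplyr::inner_join(cls, sire,
                           by = c(source = "gene", "timepoint"))
  if (dplyr::n_distinct(dat$label) < 2) {
    stop("both edge classes must be non-empty", call. = FALSE)
  }
  ins <- dat$paternal[dat$label == "insensitive"]
  sen <- dat$paternal[dat$label == "sensitive"]
  ks <- suppressWarnings(ks.test(ins, sen))
  form <- if (dplyr::n_distinct(dat$timepoint) > 1) {
    paternal ~ label + factor(timepoint)
  } else {
    paternal ~ label
  }
  lmfit <- lm(form, data = dat)
  p_adj <- summary(lmfit)$coefficients["labelsensitive", "Pr(>|t|)"]
  list(by_class = dplyr::summarise(dplyr::group_by(dat, .data$label),
                                   n = dplyr::n(),
                                   mean_paternal = mean(.data$paternal),
                                   .groups = "drop"),
       ks = tibble::tibble(statistic = unname(ks$statistic),
                           p_value = ks$p.value),
       time_adjusted_p = p_adj)
}

# gene -> tissue annotation at a time point, from the tissues of the edges
# the gene participates in at that time
gene_tissues <- function(net, timepoint) {
  ae <- active_edges(net, timepoint)
  dplyr::distinct(dplyr::bind_rows(
    tibble::tibble(gene = ae$source, tissue = ae$tissue),
    tibble::tibble(gene = ae$target, tissue = ae$tissue)))
}

#' Tissue-composition control
#'
#' If differences in tissue composition among broods drove the observed
#' correlations, genes expressed in the same tissue should covary more
#' than random gene sets. For each tissue with at least 2 annotated genes
#' at the time point, the observed mean pairwise correlation of family
#' means (or of a supplied per-unit value matrix, e.g. breeding values) is
#' compared to `n_perm` equal-sized random sets of active genes.
#'
#' @param expr long expression tibble.
#' @param net a [network()] (tissue annotations come from its edges).
#' @param timepoint time point in 1..6.
#' @param n_perm permutations (default 1000).
#' @param unique_only restrict to genes annotated to exactly one tissue at
#'   the time point (default FALSE).
#' @param value_matrix optional units x genes matrix to correlate instead
#'   of family means (e.g. breeding values).
#' @param min_samples expression filter floor.
#' @return tibble per tissue: tissue, n_genes, observed_mean_cor, p_value;
#'   tissues with < 2 genes are skipped with a message.
#' @export
tissue_composition_test <- function(expr, net, timepoint, n_perm = 1000,
                                    unique_only = FALSE, value_matrix = NULL,
                                    min_samples = 20) {
  gt <- gene_tissues(net, timepoint)
  if (unique_only) {
    n_tis <- table(gt$gene)
    gt <- gt[gt$gene %in% names(n_tis)[n_tis == 1], , drop = FALSE]
  }
  act <- active_genes(net, timepoint, expr, min_samples)
  gt <- gt[gt$gene %in% act, , drop = FALSE]
  m <- value_matrix %||% fam_matrix(expr, timepoint, genes = act)
  genes <- intersect(act, colnames(m))
  C <- suppressWarnings(cor(m[, genes, drop = FALSE],
                            use = "pairwise.complete.obs"))
  mean_cor <- function(gs) {
    cc <- C[gs, gs]
    mean(cc[upper.tri(cc)], na.rm = TRUE)
  }
  purrr::map_dfr(unique(gt$tissue), function(tis) {
    gs <- intersect(gt$gene[gt$tissue == tis], genes)
    if (length(gs) < 2) {
      message("tissue '", tis, "' has < 2 annotated genes at t", timepoint,
              ": skipped")
      return(tibble::tibble(tissue = tis, n_genes = length(gs),
                            observed_mean_cor = NA_real_,
                            p_value = NA_real_))
    }
    obs <- mean_cor(gs)
    null_stats <- vapply(seq_len(n_perm), function(i) {
      mean_cor(sample(genes, length(gs)))
    }, numeric(1))
    tibble::tibble(tissue = tis, n_genes = length(gs),
                   observed_mean_cor = obs,
                   p_value = perm_pvalue(null_stats, obs))
  })
}
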