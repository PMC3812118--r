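# Two-block partial least squares between the gene x time expression block
# and the skeletal-measure block: singular value decomposition of the
# between-block cross-covariance, RV coefficient with permutation
# significance, and eigenvalue-weighted contribution ranking.

#' Build the culture x (gene x time) expression block
#'
#' One column per gene x time combination (named `gene@tN`), one row per
#' culture. When a network is supplied only gene x times at which the gene
#' is active (incident to an active edge) are kept; time points outside the
#' network's annotated range (7) can be added explicitly via `timepoints`.
#'
#' @param expr long expression tibble.
#' @param net optional [network()] restricting columns to active
#'   gene x times.
#' @param timepoints time points to include (default: all in `expr`).
#' @param min_samples expression filter floor when `net` is supplied.
#' @return numeric matrix, rownames = culture ids.
#' @export
expression_block <- function(expr, net = NULL, timepoints = NULL,
                             min_samples = 20) {
  assert_expr_tbl(expr)
  timepoints <- timepoints %||% sort(unique(expr$timepoint))
  blocks <- purrr::map(timepoints, function(t) {
    sub <- dplyr::filter(expr, .data$timepoint == !!t)
    if (!is.null(net) && t >= 1 && t <= 6) {
      keep <- active_genes(net, t, expr, min_samples)
      sub <- dplyr::filter(sub, .data$gene %in% keep)
    }
    if (nrow(sub) == 0) return(NULL)
    wide <- tidyr::pivot_wider(sub, id_cols = "culture_id",
                               names_from = "gene", values_from = "value")
    m <- as.matrix(wide[, -1, drop = FALSE])
    rownames(m) <- wide$culture_id
    colnames(m) <- paste0(colnames(m), "@t", t)
    m
  })
  blocks <- blocks[!vapply(blocks, is.null, logical(1))]
  cultures <- Reduce(intersect, lapply(blocks, rownames))
  do.call(cbind, lapply(blocks, function(b) b[cultures, , drop = FALSE]))
}

#' Build the culture x rod-measure block
#' @param morph rods-form morphology tibble (per individual).
#' @return numeric matrix of per-culture mean rod lengths.
#' @export
rod_block <- function(morph) {
  cm <- culture_rod_means(morph)
  m <- as.matrix(cm[, -1, drop = FALSE])
  rownames(m) <- cm$culture_id
  m
}

center_block <- function(M, scale = FALSE) {
  M <- scale(M, center = TRUE, scale = scale)
  attr(M, "scaled:center") <- NULL
  attr(M, "scaled:scale") <- NULL
  M
}

#' Two-block partial least squares
#'
#' Columns of both blocks are centred (expression columns are additionally
#' standardized to unit variance by default, since expression and rod
#' lengths have incommensurate units), and the between-block
#' cross-covariance matrix is decomposed by SVD. Each pair of singular
#' vectors is a pair of factors, one per block, that together maximize
#' cross-block covariance subject to orthogonality with earlier pairs.
#' Factors are oriented so that the largest-magnitude skeletal loading is
#' positive.
#'
#' @param X culture x expression-measure matrix (see [expression_block()]).
#' @param Y culture x skeletal-measure matrix, rows aligned with `X`.
#' @param scale_x standardize expression columns (default TRUE).
#' @param scale_y standardize skeletal columns (default FALSE: kept in µm).
#' @return object of class `pls2b`: `x_loadings`, `y_loadings` (unit-norm
#'   columns, one per factor pair), `singular_values` (non-increasing),
#'   `weights` (normalized squared singular values, sum 1), `rv`
#'   (RV coefficient of the processed blocks), `n`.
#' @export
fit_2bpls <- function(X, Y, scale_x = TRUE, scale_y = FALSE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("blocks must share rows", call. = FALSE)
  if (nrow(X) < 3) stop("need at least 3 cultures", call. = FALSE)
  if (any(apply(X, 2, sd) == 0) || any(apply(Y, 2, sd) == 0)) {
    stop("all-zero-variance column in a block", call. = FALSE)
  }
  Xc <- center_block(X, scale_x)
  Yc <- center_block(Y, scale_y)
  C <- crossprod(Xc, Yc) / (nrow(Xc) - 1)
  sv <- svd(C)
  k <- sum(sv$d > max(sv$d) * 1e-12)
  k <- max(k, 1)
  u <- sv$u[, seq_len(k), drop = FALSE]
  v <- sv$v[, seq_len(k), drop = FALSE]
  d <- sv$d[seq_len(k)]
  for (j in seq_len(k)) {
    top <- which.max(abs(v[, j]))
    if (v[top, j] < 0) {
      v[, j] <- -v[, j]
      u[, j] <- -u[, j]
    }
  }
  rownames(u) <- colnames(X)
  rownames(v) <- colnames(Y)
  structure(list(x_loadings = u, y_loadings = v, singular_values = d,
                 weights = d^2 / sum(d^2),
                 rv = rv_coefficient(Xc, Yc),
                 n = nrow(X)),
            class = "pls2b")
}

#' @export
print.pls2b <- function(x, ...) {
  cat("<pls2b> ", nrow(x$x_loadings), " expression measures x ",
      nrow(x$y_loadings), " skeletal measures, ",
      length(x$singular_values), " factor pairs; RV = ",
      signif(x$rv, 3), "\n", sep = "")
  invisible(x)
}

#' RV coefficient between two blocks
#'
#' Matrix correlation
#' `RV = tr(X'Y Y'X) / sqrt(tr((X'X)^2) tr((Y'Y)^2))`, bounded in
#' `[0, 1]`, equal to 1 when the blocks agree up to rotation/scaling —
#' the multivariate analogue of squared Pearson correlation. Columns are
#' centred internally.
#'
#' @param X,Y matrices with the same number of rows.
#' @return scalar in `[0, 1]`.
#' @export
rv_coefficient <- function(X, Y) {
  X <- center_block(as.matrix(X)); Y <- center_block(as.matrix(Y))
  sxx <- crossprod(X); syy <- crossprod(Y); sxy <- crossprod(X, Y)
  den <- sqrt(sum(sxx^2) * sum(syy^2))
  if (den == 0) stop("a block has zero total variance", call. = FALSE)
  sum(sxy * sxy) / den
}

#' Permutation test of the RV coefficient
#'
#' Rows of `Y` are permuted `n_perm` times;
#' `p = (#\{RV_null >= RV_obs\} + 1) / (n_perm + 1)`.
#'
#' @param X,Y aligned blocks.
#' @param n_perm permutations (default 1000; below 100 warns).
#' @return list: `rv`, `null_stats`, `p_value`.
#' @export
rv_permutation_test <- function(X, Y, n_perm = 1000) {
  if (n_perm < 100) warning("n_perm < 100 gives a coarse p-value")
  X <- as.matrix(X); Y <- as.matrix(Y)
  observed <- rv_coefficient(X, Y)
  null_stats <- vapply(seq_len(n_perm), function(i) {
    rv_coefficient(X, Y[sample.int(nrow(Y)), , drop = FALSE])
  }, numeric(1))
  list(rv = observed, null_stats = null_stats,
       p_value = perm_pvalue(null_stats, observed))
}

#' Eigenvalue-weighted contribution of each expression measure
#'
#' `score(measure) = sum_k weight_k * |loading_k(measure)|` with the
#' normalized squared singular values as weights — the total contribution
#' of the measure to the cross-block association over all factor pairs.
#' Absolute loadings are the default because factor signs are
#' direction-arbitrary.
#'
#' @param res a [fit_2bpls()] result.
#' @param signed use signed loadings instead of absolute (default FALSE).
#' @return tibble: `measure`, `score`, `rank`, sorted by decreasing score.
#' @export
weighted_contributions <- function(res, signed = FALSE) {
  L <- if (signed) res$x_loadings else abs(res$x_loadings)
  score <- as.numeric(L %*% res$weights)
  out <- tibble::tibble(measure = rownames(res$x_loadings), score = score)
  out <- out[order(-out$score), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out
}

#' Select the top fraction of scored measures
#'
#' The highest `ceiling(fraction * N)` scores; ties are broken by the
#' stable original measure order.
#'
#' @param scores tibble with `measure` and `score` (e.g.
#'   [weighted_contributions()]) or a named numeric vector.
#' @param fraction in (0, 1).
#' @return character vector of selected measure names.
#' @export
top_fraction <- function(scores, fraction) {
  stopifnot(fraction > 0, fraction < 1)
  if (is.numeric(scores)) {
    scores <- tibble::tibble(measure = names(scores), score = scores)
  }
  if (nrow(scores) == 0) stop("empty scores", call. = FALSE)
  n_sel <- ceiling(fraction * nrow(scores))
  ord <- order(-scores$score)        # stable for ties
  scores$measure[ord[seq_len(n_sel)]]
}

measure_timepoint <- function(measures) {
  as.integer(sub("^.*@t", "", measures))
}

#' Time-point enrichment of selected measures
#'
#' 2 x 2 chi-square test (1 df, no continuity correction) of selected
#' versus unselected measures against membership of one time point, to ask
#' whether the strongest expression-morphology contributions concentrate at
#' that time.
#'
#' @param selected character vector of selected measure names
#'   (`gene@tN` format).
#' @param universe all measure names.
#' @param timepoint time point tested for over-representation (default 1).
#' @return tibble: timepoint, n_selected, n_selected_at_t, statistic, df,
#'   p_value.
#' @export
timepoint_enrichment_test <- function(selected, universe, timepoint = 1) {
  if (length(selected) == 0) stop("empty selection", call. = FALSE)
  stopifnot(all(selected %in% universe))
  sel <- universe %in% selected
  at_t <- measure_timepoint(universe) == timepoint
  tab <- table(factor(sel, c(TRUE, FALSE)), factor(at_t, c(TRUE, FALSE)))
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  tibble::tibble(timepoint = timepoint, n_selected = length(selected),
                 n_selected_at_t = sum(sel & at_t),
                 statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p_value = ct$p.value)
}

#' Expression-morphology PLS on a dataset
#'
#' Convenience wrapper: builds the expression and rod blocks on the shared
#' cultures, fits [fit_2bpls()] and runs the RV permutation test.
#'
#' @param expr long expression tibble.
#' @param morph rods-form morphology tibble.
#' @param net optional [network()] restricting expression columns to
#'   active gene x times.
#' @param timepoints time points for the expression block.
#' @param n_perm RV permutations.
#' @param scale_x,scale_y passed to [fit_2bpls()]; the permutation test
#'   uses the same preprocessing.
#' @return a `pls2b` object with extra elements `rv_p` and
#'   `contributions`.
#' @export
pls_expression_morphology <- function(expr, morph, net = NULL,
                                      timepoints = NULL, n_perm = 1000,
                                      scale_x = TRUE, scale_y = FALSE) {
  X <- expression_block(expr, net, timepoints)
  Y <- rod_block(morph)
  cultures <- intersect(rownames(X), rownames(Y))
  X <- X[cultures, , drop = FALSE]
  Y <- Y[cultures, , drop = FALSE]
  res <- fit_2bpls(X, Y, scale_x = scale_x, scale_y = scale_y)
  res$rv_p <- rv_permutation_test(center_block(X, scale_x),
                                  center_block(Y, scale_y),
                                  n_perm = n_perm)$p_value
  res$contributions <- weighted_contributions(res)
  res
}
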