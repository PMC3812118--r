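# Skeletal morphology: landmark-to-rod distances, PCA of per-culture rod
# lengths, parental effects on PC scores, gene-PC correlation screens and
# the maternal-conditioned association test.

#' Default skeletal rod definitions
#'
#' Inter-landmark distances defining six skeletal rods from the eight
#' landmarks (indices into the landmark set). The exact landmark scheme is
#' lab-specific, so the table is configurable; this default pairs the
#' apex/tip landmarks into the six standard rod measures.
#'
#' @return tibble: `rod`, `i`, `j` (landmark indices).
#' @export
default_rod_definitions <- function() {
  tibble::tibble(
    rod = c("body", "postoral_l", "postoral_r",
            "anterolateral_l", "anterolateral_r", "transverse"),
    i = c(1L, 2L, 3L, 2L, 3L, 2L),
    j = c(4L, 5L, 6L, 7L, 8L, 3L))
}

#' Rod lengths from 3-D landmarks
#'
#' Euclidean distances (µm) between the landmark pairs in
#' `rod_definitions` for a single individual's 8 x 3 coordinate matrix.
#' Invariant under rigid rotation and translation of the landmark set.
#'
#' @param landmarks numeric 8 x 3 matrix (rows = landmarks; columns x, y,
#'   z; µm).
#' @param rod_definitions tibble with `rod`, `i`, `j`
#'   (default [default_rod_definitions()]).
#' @return named numeric vector of rod lengths (µm). A coincident landmark
#'   pair yields length 0 with a warning.
#' @export
landmarks_to_rods <- function(landmarks, rod_definitions = default_rod_definitions()) {
  landmarks <- as.matrix(landmarks)
  if (!all(is.finite(landmarks))) stop("landmark coordinates must be finite",
                                       call. = FALSE)
  idx <- c(rod_definitions$i, rod_definitions$j)
  if (any(idx < 1 | idx > nrow(landmarks))) {
    stop("rod definition references a landmark index outside 1..",
         nrow(landmarks), call. = FALSE)
  }
  d <- sqrt(rowSums((landmarks[rod_definitions$i, , drop = FALSE] -
                     landmarks[rod_definitions$j, , drop = FALSE])^2))
  if (any(d == 0)) {
    warning("coincident landmark pair(s): rod length 0 for ",
            paste(rod_definitions$rod[d == 0], collapse = ", "))
  }
  setNames(d, rod_definitions$rod)
}

#' Convert a landmarks morphology table to rod lengths
#'
#' @param morph landmarks-form tibble (see [read_morphology()]), columns
#'   `x1..z8`.
#' @param rod_definitions see [landmarks_to_rods()].
#' @return rods-form tibble (culture_id, individual_id, one column per rod).
#' @export
morphology_to_rods <- function(morph,
                               rod_definitions = default_rod_definitions()) {
  stopifnot(all(landmark_cols %in% names(morph)))
  rods <- t(apply(as.matrix(morph[landmark_cols]), 1, function(row) {
    landmarks_to_rods(matrix(row, nrow = 8, byrow = TRUE),
                      rod_definitions)
  }))
  out <- dplyr::bind_cols(morph[c("culture_id", "individual_id")],
                          tibble::as_tibble(rods))
  attr(out, "morph_type") <- "rods"
  out
}

# per-culture mean of each rod measure
culture_rod_means <- function(morph) {
  rods <- setdiff(names(morph), c("culture_id", "individual_id"))
  dplyr::summarise(dplyr::group_by(morph, .data$culture_id),
                   dplyr::across(dplyr::all_of(rods),
                                 ~ mean(.x, na.rm = TRUE)),
                   .groups = "drop")
}

#' PCA of per-culture skeletal rod lengths
#'
#' Individuals are averaged within culture, then the culture-mean rod
#' lengths are decomposed by PCA. The covariance matrix is used by default
#' since all measures share units (µm); set `mode = "correlation"` to
#' standardize. All components are retained; the first three are the
#' conventional summary of skeletal size and shape.
#'
#' @param morph rods-form morphology tibble (per individual).
#' @param mode `"covariance"` (default) or `"correlation"`.
#' @return object of class `skeletal_pca`: `scores` (tibble: culture_id +
#'   PC columns), `loadings` (measures x components), `variance_fraction`,
#'   `culture_means`, `mode`.
#' @export
skeletal_pca <- function(morph, mode = c("covariance", "correlation")) {
  mode <- match.arg(mode)
  cm <- culture_rod_means(morph)
  if (nrow(cm) < 3) stop("need at least 3 cultures", call. = FALSE)
  X <- as.matrix(cm[, -1, drop = FALSE])
  pc <- stats::prcomp(X, center = TRUE, scale. = mode == "correlation")
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- dplyr::bind_cols(cm["culture_id"], tibble::as_tibble(pc$x))
  structure(list(scores = scores, loadings = pc$rotation,
                 variance_fraction = vf, culture_means = cm, mode = mode),
            class = "skeletal_pca")
}

#' @export
print.skeletal_pca <- function(x, ...) {
  cat("<skeletal_pca> ", nrow(x$scores), " cultures, ",
      ncol(x$loadings), " measures; first three components explain ",
      round(100 * sum(x$variance_fraction[1:min(3, length(x$variance_fraction))]), 1),
      "% of variance\n", sep = "")
  invisible(x)
}

#' Parental variance components of skeletal PC scores
#'
#' Mixed model `score ~ (1|dam) + (1|sire) + (1|dam:sire)` per principal
#' component, with likelihood-ratio tests of each dropped random term.
#' Because the null value (variance 0) lies on the boundary of the
#' parameter space, LRT p-values use the 50:50 chi-square(0)/chi-square(1)
#' mixture (the naive chi-square(1) p halved).
#'
#' @param pca a [skeletal_pca()].
#' @param design tibble mapping `culture_id` to `dam_id` and `sire_id`
#'   (replicate cultures of a family share dam and sire).
#' @param components how many leading PCs to test (default 3).
#' @return tibble: component, term, variance, lrt_stat, p_value.
#' @export
pc_parental_effects <- function(pca, design, components = 3) {
  scores <- dplyr::inner_join(pca$scores, design, by = "culture_id")
  purrr::map_dfr(seq_len(components), function(k) {
    dat <- data.frame(score = scores[[paste0("PC", k)]],
                      dam = factor(scores$dam_id),
                      sire = factor(scores$sire_id))
    full <- lme4::lmer(score ~ (1 | dam) + (1 | sire) + (1 | dam:sire),
                       data = dat, REML = FALSE,
                       control = lme4::lmerControl(check.conv.singular = "ignore"))
    vc <- as.data.frame(lme4::VarCorr(full))
    get_var <- function(grp) {
      v <- vc$vcov[vc$grp == grp]
      if (length(v) == 0) 0 else v
    }
    drop_forms <- list(
      dam = score ~ (1 | sire) + (1 | dam:sire),
      sire = score ~ (1 | dam) + (1 | dam:sire),
      interaction = score ~ (1 | dam) + (1 | sire))
    purrr::map_dfr(names(drop_forms), function(tm) {
      red <- lme4::lmer(drop_forms[[tm]], data = dat, REML = FALSE,
                        control = lme4::lmerControl(check.conv.singular = "ignore"))
      stat <- max(0, 2 * (as.numeric(logLik(full)) - as.numeric(logLik(red))))
      tibble::tibble(
        component = k, term = tm,
        variance = get_var(switch(tm, dam = "dam", sire = "sire",
                                  interaction = "dam:sire")),
        lrt_stat = stat,
        p_value = 0.5 * pchisq(stat, df = 1, lower.tail = FALSE))
    })
  })
}

#' Gene-expression correlations with skeletal principal components
#'
#' Pearson correlation of each gene's per-culture expression at each time
#' point with each of the first `components` PC scores, with a family-wise
#' multiple-testing adjustment over all gene x time x component tests.
#'
#' @param expr long expression tibble.
#' @param pca a [skeletal_pca()].
#' @param timepoints time points to screen (default: all in `expr`).
#' @param components leading PCs to test (default 3).
#' @param correction [p.adjust()] method over all tests (default `"BH"`;
#'   `"holm"`/`"bonferroni"` available).
#' @param min_cultures minimum shared cultures (default 5).
#' @return tibble: gene, timepoint, component, n, r, p_value, adj_p.
#' @export
gene_pc_correlations <- function(expr, pca, timepoints = NULL,
                                 components = 3, correction = "BH",
                                 min_cultures = 5) {
  assert_expr_tbl(expr)
  timepoints <- timepoints %||% sort(unique(expr$timepoint))
  scores <- pca$scores
  res <- purrr::map_dfr(timepoints, function(t) {
    sub <- dplyr::filter(expr, .data$timepoint == !!t)
    wide <- tidyr::pivot_wider(sub, id_cols = "culture_id",
                               names_from = "gene", values_from = "value")
    joined <- dplyr::inner_join(wide, scores, by = "culture_id")
    if (nrow(joined) < min_cultures) {
      stop("fewer than ", min_cultures, " cultures shared with morphology",
           call. = FALSE)
    }
    genes <- setdiff(names(wide), "culture_id")
    purrr::map_dfr(genes, function(g) {
      purrr::map_dfr(seq_len(components), function(k) {
        x <- joined[[g]]; y <- joined[[paste0("PC", k)]]
        ok <- !is.na(x) & !is.na(y)
        if (sum(ok) < min_cultures || sd(x[ok]) == 0) {
          return(tibble::tibble(gene = g, timepoint = t, component = k,
                                n = sum(ok), r = NA_real_,
                                p_value = NA_real_))
        }
        ct <- cor.test(x[ok], y[ok])
        tibble::tibble(gene = g, timepoint = t, component = k, n = sum(ok),
                       r = unname(ct$estimate), p_value = ct$p.value)
      })
    })
  })
  res$adj_p <- p.adjust(res$p_value, method = correction)
  res
}

#' Genes associated with morphology at multiple time points
#'
#' Associations supported at two or more developmental time points are the
#' strongest single-gene candidates; this collects them from a
#' [gene_pc_correlations()] table.
#'
#' @param assoc tibble from [gene_pc_correlations()].
#' @param alpha adjusted-p threshold (default 0.05).
#' @return tibble: gene, n_timepoints (number of time points with at least
#'   one significant component), restricted to genes with >= 2.
#' @export
multi_timepoint_genes <- function(assoc, alpha = 0.05) {
  sig <- dplyr::filter(assoc, !is.na(.data$adj_p), .data$adj_p < alpha)
  counts <- dplyr::summarise(
    dplyr::group_by(sig, .data$gene),
    n_timepoints = dplyr::n_distinct(.data$timepoint), .groups = "drop")
  dplyr::filter(counts, .data$n_timepoints >= 2)
}

#' Maternal-conditioned expression-morphology association
#'
#' Tests whether a gene's expression still predicts a skeletal PC score
#' after a maternal (dam) factor is included:
#' `score ~ dam + expression`. A significant expression coefficient
#' (`p < alpha`) rejects the hypothesis that a shared maternal input is the
#' sole source of the association, i.e. supports a non-maternal (genetic)
#' covariance. Expression constant within every dam group is perfectly
#' confounded and reported as `NA`.
#'
#' Replicate cultures of one family share their family-level expression
#' and morphology, so testing at culture level would overstate the degrees
#' of freedom; observations are therefore collapsed to family (dam x sire)
#' means before the model is fit.
#'
#' @param expr long expression tibble.
#' @param pca a [skeletal_pca()].
#' @param design tibble mapping `culture_id` to `dam_id` (and `sire_id`,
#'   used to identify replicate cultures of the same family).
#' @param gene,timepoint,component which association to test.
#' @param alpha rejection level for the maternal-only hypothesis
#'   (default 0.01).
#' @return one-row tibble: gene, timepoint, component, expression
#'   coefficient, `p_value`, `non_maternal` (logical).
#' @export
maternal_conditioned_test <- function(expr, pca, design, gene, timepoint,
                                      component = 1, alpha = 0.01) {
  sub <- dplyr::filter(expr, .data$gene == !!gene,
                       .data$timepoint == !!timepoint)
  dat <- dplyr::inner_join(
    dplyr::inner_join(sub[c("culture_id", "value")], pca$scores,
                      by = "culture_id"),
    design, by = "culture_id")
  dat$score <- dat[[paste0("PC", component)]]
  if ("sire_id" %in% names(dat)) {
    dat <- dplyr::summarise(
      dplyr::group_by(dat, .data$dam_id, .data$sire_id),
      value = mean(.data$value, na.rm = TRUE),
      score = mean(.data$score, na.rm = TRUE), .groups = "drop")
  }
  dat$dam <- factor(dat$dam_id)
  dat <- dat[!is.na(dat$value) & !is.na(dat$score), , drop = FALSE]
  if (nlevels(droplevels(dat$dam)) < 2) {
    stop("dam factor needs at least 2 levels", call. = FALSE)
  }
  within_var <- tapply(dat$value, dat$dam, function(v) var(v) %||% 0)
  out <- tibble::tibble(gene = gene, timepoint = timepoint,
                        component = component, estimate = NA_real_,
                        p_value = NA_real_, non_maternal = NA)
  if (all(is.na(within_var) | within_var == 0)) return(out)
  fit <- lm(score ~ dam + value, data = dat)
  sm <- summary(fit)$coefficients
  if (!"value" %in% rownames(sm)) return(out)
  out$estimate <- sm["value", "Estimate"]
  out$p_value <- sm["value", "Pr(>|t|)"]
  out$non_maternal <- out$p_value < alpha
  out
}
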