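# End-to-end orchestration: simulate (or load) -> variance components ->
# edge analysis -> morphology -> PLS, writing TSV/JSON artifacts plus a
# manifest with per-stage timing and file checksums. Every stage draws its
# randomness from a named substream of the run seed, so identical
# configurations reproduce byte-identical artifacts.

#' Assemble and validate a pipeline run configuration
#'
#' Either a simulation configuration or a full set of input paths must be
#' provided. Unknown settings are an error, not a warning.
#'
#' @param simulation a [sim_config()] (e.g. [sim_config_urchin()]), or NULL
#'   to read inputs from files.
#' @param expression_path,metadata_path,network_path,morphology_path input
#'   files used when `simulation` is NULL.
#' @param alpha edge-classification significance level.
#' @param n_perm permutation count for all permutation tests.
#' @param correction multiple-testing method for the morphology screen.
#' @param chain a [chain_control()].
#' @param dic also fit the three reduced models per gene x time and flag
#'   term significance by DIC (default FALSE: it quadruples the variance
#'   stage, and the posterior summaries themselves do not need it).
#' @param exclude_repressing drop repressing edges from edge analyses.
#' @param seed global run seed.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(simulation = NULL, expression_path = NULL,
                       metadata_path = NULL, network_path = NULL,
                       morphology_path = NULL, alpha = 0.01, n_perm = 1000,
                       correction = "BH", chain = chain_control(),
                       dic = FALSE, exclude_repressing = FALSE, seed = 1) {
  if (is.null(simulation) &&
      (is.null(expression_path) || is.null(metadata_path))) {
    stop("provide either a simulation config or expression + metadata paths",
         call. = FALSE)
  }
  structure(list(simulation = simulation, expression_path = expression_path,
                 metadata_path = metadata_path, network_path = network_path,
                 morphology_path = morphology_path, alpha = alpha,
                 n_perm = n_perm, correction = correction, chain = chain,
                 dic = dic, exclude_repressing = exclude_repressing,
                 seed = as.integer(seed)),
            class = "run_config")
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

# Table-S1-shaped wide variance-component export
variance_components_table <- function(fit, expr) {
  comp <- dplyr::select(fit$components, "gene", "timepoint", "term",
                        "mean", "mode", "median", "lower90", "upper90",
                        "scaled_mean")
  wide <- tidyr::pivot_wider(
    comp, names_from = "term",
    values_from = c("mean", "mode", "median", "lower90", "upper90",
                    "scaled_mean"),
    names_glue = "{term}.{.value}")
  raw <- dplyr::summarise(
    dplyr::group_by(expr, .data$gene, .data$timepoint),
    mean = mean(.data$value, na.rm = TRUE),
    var = var(.data$value, na.rm = TRUE), .groups = "drop")
  out <- dplyr::left_join(wide, raw, by = c("gene", "timepoint"))
  dplyr::left_join(out, fit$gene_stats, by = c("gene", "timepoint"))
}

#' Run the analysis pipeline
#'
#' Executes the requested stages and writes each stage's artifacts (TSV
#' tables, JSON test summaries) plus a `manifest.json` recording the seed,
#' package version, per-stage timing and a checksum of every written file.
#' Later stages require the artifacts of earlier ones: a missing upstream
#' artifact raises an error naming the stage that produces it.
#'
#' @param cfg a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param stages subset of `c("simulate", "varcomp", "edges", "morpho",
#'   "pls")`, or `"all"`.
#' @return (invisibly) a list with the in-memory results of the stages run.
#' @export
run_pipeline <- function(cfg, out_dir,
                         stages = c("simulate", "varcomp", "edges",
                                    "morpho", "pls")) {
  stopifnot(inherits(cfg, "run_config"))
  if (identical(stages, "all")) {
    stages <- c("simulate", "varcomp", "edges", "morpho", "pls")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  timing <- list(); results <- list()
  t_stage <- function(name, code) {
    t0 <- Sys.time()
    r <- code
    timing[[name]] <<- round(as.numeric(difftime(Sys.time(), t0,
                                                 units = "secs")), 2)
    r
  }
  p <- function(f) file.path(out_dir, f)
  need <- function(f, producer) {
    if (!file.exists(p(f))) {
      stop("missing artifact '", f, "': run the '", producer,
           "' stage first", call. = FALSE)
    }
  }

  # the run configuration is serialized into the output directory so a
  # result can always be traced back to its settings
  sim <- cfg$simulation
  write_json_artifact(list(
    seed = cfg$seed, alpha = cfg$alpha, n_perm = cfg$n_perm,
    correction = cfg$correction, dic = cfg$dic,
    exclude_repressing = cfg$exclude_repressing, chain = cfg$chain,
    inputs = if (is.null(sim)) {
      list(expression = cfg$expression_path, metadata = cfg$metadata_path,
           network = cfg$network_path, morphology = cfg$morphology_path)
    } else {
      list(simulation = list(seed = sim$seed, n_genes = nrow(sim$genes),
                             n_dams = sim$n_dams, n_sires = sim$n_sires,
                             n_replicates = sim$n_replicates,
                             timepoints = sim$timepoints,
                             n_edges = nrow(sim$network$edges)))
    }), p("config.json"))

  if ("simulate" %in% stages) {
    if (is.null(cfg$simulation)) {
      stop("'simulate' requested but the config has no simulation; ",
           "pass input paths and skip this stage", call. = FALSE)
    }
    results$sim <- t_stage("simulate", {
      ds <- simulate_cross(cfg$simulation)
      write_expression(ds$expression, p("expression.tsv"), p("samples.tsv"))
      write_edge_table(ds$network, p("network.tsv"))
      if (!is.null(ds$morphology)) {
        write_morphology(ds$morphology, p("morphology.tsv"))
      }
      truth <- realized_truth_summary(ds)
      write_json_artifact(
        list(components = dplyr::select(truth$components, -dplyr::any_of(
          c("dam_effects", "sire_effects", "inter_effects"))),
          edge_labels = truth$edge_labels,
          morphology_drivers = truth$morphology_drivers),
        p("truth.json"))
      ds
    })
  }

  load_expr <- function() {
    if (file.exists(p("expression.tsv"))) {
      read_expression(p("expression.tsv"), p("samples.tsv"))
    } else if (!is.null(cfg$expression_path)) {
      read_expression(cfg$expression_path, cfg$metadata_path)
    } else {
      stop("no expression input: run the 'simulate' stage or provide paths",
           call. = FALSE)
    }
  }
  load_net <- function() {
    if (file.exists(p("network.tsv"))) {
      read_edge_table(p("network.tsv"))
    } else if (!is.null(cfg$network_path)) {
      read_edge_table(cfg$network_path)
    } else {
      stop("no network input: run the 'simulate' stage or provide ",
           "network_path", call. = FALSE)
    }
  }

  if ("varcomp" %in% stages) {
    results$varcomp <- t_stage("varcomp", {
      expr <- load_expr()
      fit <- fit_ncii(expr, chain = cfg$chain, dic = cfg$dic,
                      seed = substream_seed(cfg$seed, "varcomp"))
      readr::write_tsv(variance_components_table(fit, expr),
                       p("variance_components.tsv"))
      readr::write_tsv(fit$breeding_values, p("breeding_values.tsv"))
      tps <- sort(unique(fit$components$timepoint))
      mvp <- purrr::map_dfr(tps, function(t) maternal_vs_paternal_test(fit, t))
      trend <- parental_effect_trend_test(fit)
      corr <- purrr::map_dfr(tps, function(t)
        parental_effect_correlation(fit, t))
      set.seed(substream_seed(cfg$seed, "gmatrix"))
      gm <- purrr::map_dfr(tps, function(t) {
        g <- gmatrix_structure_test(fit, t, n_perm = cfg$n_perm)
        tibble::tibble(timepoint = t, statistic = g$statistic,
                       p_value = g$p_value, n_genes = g$n_genes)
      })
      write_json_artifact(
        list(maternal_vs_paternal = mvp, trend_kruskal = trend$kruskal,
             trend_early_vs_late = trend$early_vs_late,
             dam_sire_correlation = corr, gmatrix = gm),
        p("varcomp_tests.json"))
      list(fit = fit, maternal_vs_paternal = mvp, trend = trend,
           correlation = corr, gmatrix = gm)
    })
  }

  if ("edges" %in% stages) {
    results$edges <- t_stage("edges", {
      expr <- load_expr()
      net <- load_net()
      incl <- !cfg$exclude_repressing
      set.seed(substream_seed(cfg$seed, "edges"))
      ivr <- purrr::map(1:6, function(t) {
        tryCatch(interactor_vs_random_test(expr, net, t,
                                           n_perm = cfg$n_perm,
                                           include_repressing = incl),
                 error = function(e) NULL)
      })
      ivr_tbl <- purrr::map_dfr(1:6, function(t) {
        x <- ivr[[t]]
        if (is.null(x)) return(tibble::tibble())
        tibble::tibble(timepoint = t, observed_mean_r2 = x$observed,
                       null_mean_r2 = mean(x$null_stats),
                       null_q95 = unname(quantile(x$null_stats, 0.95)),
                       random_mean_r2 = x$random_mean,
                       n_edges = x$n_edges, p_value = x$p_value)
      })
      cls <- classify_edges(expr, net, alpha = cfg$alpha,
                            include_repressing = incl)
      readr::write_tsv(cls, p("edge_classifications.tsv"))
      trend <- tryCatch(sensitivity_trend_test(cls), error = function(e) NULL)
      pbc <- if ("varcomp" %in% names(results)) {
        tryCatch(paternal_by_class_test(results$varcomp$fit, cls),
                 error = function(e) NULL)
      }
      tissue <- purrr::map_dfr(1:6, function(t) {
        tryCatch(dplyr::mutate(
          tissue_composition_test(expr, net, t, n_perm = cfg$n_perm),
          timepoint = t, .before = 1), error = function(e) tibble::tibble())
      })
      write_json_artifact(
        list(interactor_vs_random = ivr_tbl, sensitivity_trend = trend,
             paternal_by_class = if (!is.null(pbc))
               list(by_class = pbc$by_class, ks = pbc$ks,
                    time_adjusted_p = pbc$time_adjusted_p),
             tissue_composition = tissue),
        p("edge_tests.json"))
      list(interactor_vs_random = ivr, interactor_table = ivr_tbl,
           classifications = cls, trend = trend, paternal_by_class = pbc,
           tissue = tissue)
    })
  }

  if ("morpho" %in% stages || "pls" %in% stages) {
    morph <- if (file.exists(p("morphology.tsv"))) {
      read_morphology(p("morphology.tsv"))
    } else if (!is.null(cfg$morphology_path)) {
      read_morphology(cfg$morphology_path)
    } else {
      stop("no morphology input: run the 'simulate' stage or provide ",
           "morphology_path", call. = FALSE)
    }
    if (identical(attr(morph, "morph_type"), "landmarks")) {
      morph <- morphology_to_rods(morph)
    }
  }

  if ("morpho" %in% stages) {
    results$morpho <- t_stage("morpho", {
      expr <- load_expr()
      design <- dplyr::distinct(expr, .data$culture_id, .data$dam_id,
                                .data$sire_id)
      pca <- skeletal_pca(morph)
      pe <- pc_parental_effects(pca, design)
      assoc <- gene_pc_correlations(expr, pca, correction = cfg$correction)
      readr::write_tsv(assoc, p("morphology_associations.tsv"))
      sig <- dplyr::filter(assoc, !is.na(.data$adj_p), .data$adj_p < 0.05)
      cond <- purrr::map_dfr(seq_len(nrow(sig)), function(i) {
        maternal_conditioned_test(expr, pca, design, sig$gene[i],
                                  sig$timepoint[i], sig$component[i],
                                  alpha = cfg$alpha)
      })
      write_json_artifact(
        list(variance_fraction = pca$variance_fraction,
             parental_effects = pe,
             n_significant = nrow(sig),
             multi_timepoint = multi_timepoint_genes(assoc),
             maternal_conditioned = cond),
        p("morpho_tests.json"))
      list(pca = pca, parental = pe, associations = assoc,
           conditioned = cond)
    })
  }

  if ("pls" %in% stages) {
    results$pls <- t_stage("pls", {
      expr <- load_expr()
      net <- tryCatch(load_net(), error = function(e) NULL)
      set.seed(substream_seed(cfg$seed, "pls"))
      res <- pls_expression_morphology(expr, morph, net = net,
                                       n_perm = cfg$n_perm)
      readr::write_tsv(res$contributions, p("pls_contributions.tsv"))
      top5 <- top_fraction(res$contributions, 0.05)
      enr <- timepoint_enrichment_test(
        top_fraction(setNames(abs(res$x_loadings[, 1]),
                              rownames(res$x_loadings)), 0.10),
        rownames(res$x_loadings), timepoint = 1)
      write_json_artifact(
        list(rv = res$rv, rv_p = res$rv_p,
             singular_values = res$singular_values,
             weights = res$weights, top5 = top5,
             t1_enrichment_first_factor = enr),
        p("pls_tests.json"))
      list(pls = res, top5 = top5, enrichment = enr)
    })
  }

  # timing goes to the run log; the manifest stays byte-identical across
  # re-runs with the same seed and configuration
  writeLines(c(sprintf("run seed: %d", cfg$seed),
               sprintf("stage %-10s %8.2f s", names(timing),
                       unlist(timing))),
             p("run.log"))
  files <- sort(setdiff(list.files(out_dir), c("manifest.json", "run.log")))
  manifest <- list(
    package = "grnvar",
    version = as.character(utils::packageVersion("grnvar")),
    seed = cfg$seed,
    stages = names(timing),
    checksums = setNames(lapply(files, function(f) file_checksum(p(f))),
                         files))
  write_json_artifact(manifest, p("manifest.json"))
  invisible(results)
}

#' Summarize a completed pipeline run
#'
#' Reads the artifacts in an output directory and assembles report tables:
#' parental components by time, edge correlation/sensitivity by time, the
#' morphology association grid and the PLS summary. Stages that were not
#' run yield `NULL` sections (flagged in `missing`); an empty directory is
#' an error.
#'
#' @param out_dir a [run_pipeline()] output directory.
#' @return list of class `pipeline_report` with sections
#'   `parental_components`, `edges`, `morphology`, `pls`, and `missing`.
#' @export
pipeline_report <- function(out_dir) {
  if (!dir.exists(out_dir) || length(list.files(out_dir)) == 0) {
    stop("no pipeline artifacts in ", out_dir, call. = FALSE)
  }
  sections <- list()
  vc_path <- file.path(out_dir, "variance_components.tsv")
  sections$parental_components <- if (file.exists(vc_path)) {
    vc <- readr::read_tsv(vc_path, show_col_types = FALSE)
    dplyr::summarise(
      dplyr::group_by(vc, .data$timepoint),
      median_dam_scaled = median(.data$dam.scaled_mean, na.rm = TRUE),
      median_sire_scaled = median(.data$sire.scaled_mean, na.rm = TRUE),
      n_genes = dplyr::n(), .groups = "drop")
  }
  et_path <- file.path(out_dir, "edge_tests.json")
  cls_path <- file.path(out_dir, "edge_classifications.tsv")
  sections$edges <- if (file.exists(et_path) && file.exists(cls_path)) {
    et <- jsonlite::read_json(et_path, simplifyVector = TRUE)
    cls <- readr::read_tsv(cls_path, show_col_types = FALSE)
    frac <- dplyr::summarise(
      dplyr::group_by(cls[!is.na(cls$label), ], .data$timepoint),
      n_classified = dplyr::n(),
      sensitive_fraction = mean(.data$label == "sensitive"),
      .groups = "drop")
    list(interactor_vs_random = tibble::as_tibble(et$interactor_vs_random),
         sensitive_fraction = frac,
         trend = et$sensitivity_trend)
  }
  ma_path <- file.path(out_dir, "morphology_associations.tsv")
  sections$morphology <- if (file.exists(ma_path)) {
    assoc <- readr::read_tsv(ma_path, show_col_types = FALSE)
    dplyr::filter(assoc, !is.na(.data$adj_p), .data$adj_p < 0.05)
  }
  pls_path <- file.path(out_dir, "pls_tests.json")
  sections$pls <- if (file.exists(pls_path)) {
    jsonlite::read_json(pls_path, simplifyVector = TRUE)
  }
  sections$missing <- setdiff(c("parental_components", "edges",
                                "morphology", "pls"), names(sections))
  if (length(sections$missing) == 4) {
    stop("no stage artifacts in ", out_dir,
         ": run at least one analysis stage", call. = FALSE)
  }
  structure(sections, class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> sections:",
      paste(setdiff(names(x), "missing"), collapse = ", "), "\n")
  if (length(x$missing) > 0) {
    cat("  missing:", paste(x$missing, collapse = ", "), "\n")
  }
  invisible(x)
}
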