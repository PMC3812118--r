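# Seeded synthetic-data generator emulating the study design: a 6 dam x
# 6 sire factorial cross raised in replicate cultures and sampled at seven
# developmental time points, with genes wired into a time-resolved
# regulatory network, a maternal latent factor acting on the first time
# point, and larval rod-length morphology driven by terminal genes plus the
# maternal factor. Every random draw comes from a named substream of the
# master seed (see [substream_seed()]), so adding genes or rods never
# reshuffles the parental draws.

#' Build a simulation configuration
#'
#' @param genes tibble with columns `gene` and `layer`
#'   (`early`/`intermediate`/`terminal`).
#' @param n_dams,n_sires,n_replicates cross dimensions (default 6 x 6 x 2).
#' @param timepoints integer vector of sampled time points (default 1:7).
#' @param network a [network()] object wiring the genes (may have 0 edges).
#' @param edge_spec tibble keyed by (`source`, `target`) with `kind`
#'   (`"linear"` or `"saturating"`) and response parameters: `a`, `b`
#'   (linear) or `a`, `v_max`, `K`, `h` (saturating Hill), plus optional
#'   `noise_sd` added to the propagated family-level contribution.
#' @param variance_spec tibble keyed by (`gene`, `timepoint`) with `mean`,
#'   `sigma2_dam`, `sigma2_sire`, `sigma2_inter`, `sigma2_res` (all >= 0).
#' @param maternal_loading tibble (`gene`, `loading`): effect of the
#'   per-dam latent factor (standardized to zero mean and unit variance
#'   across the dams) on that gene at time point 1
#'   (egg-quality/provisioning proxy). Empty tibble disables it.
#' @param edge_strength_by_time numeric vector (one entry per time point in
#'   1..6) scaling the propagated edge contribution; 0 severs all edges at
#'   that time.
#' @param morphology `NULL`, or a list with `rods` (named numeric baseline
#'   lengths, µm), `drivers` (tibble `gene`, `timepoint`, `rod`, `loading`),
#'   `maternal` (named numeric per-rod loading of the dam latent factor),
#'   `noise_sd` (per-individual sd, µm) and `n_individuals` per culture.
#' @param propagate_replicates propagate upstream per-culture values instead
#'   of family means (default FALSE: downstream analyses operate on culture
#'   means).
#' @param seed master integer seed; fully determines the dataset.
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(genes,
                       n_dams = 6, n_sires = 6, n_replicates = 2,
                       timepoints = 1:7,
                       network = NULL,
                       edge_spec = NULL,
                       variance_spec,
                       maternal_loading = NULL,
                       edge_strength_by_time = rep(1, 6),
                       morphology = NULL,
                       propagate_replicates = FALSE,
                       seed = 1) {
  genes <- tibble::as_tibble(genes)
  stopifnot(all(c("gene", "layer") %in% names(genes)),
            !anyDuplicated(genes$gene))
  variance_spec <- tibble::as_tibble(variance_spec)
  vc_cols <- c("gene", "timepoint", "mean", "sigma2_dam", "sigma2_sire",
               "sigma2_inter", "sigma2_res")
  stopifnot(all(vc_cols %in% names(variance_spec)))
  sig <- as.matrix(variance_spec[c("sigma2_dam", "sigma2_sire",
                                   "sigma2_inter", "sigma2_res")])
  if (any(sig < 0)) stop("variances must be >= 0", call. = FALSE)
  if (is.null(network)) network <- read_edge_table_empty()
  if (is.null(edge_spec)) {
    edge_spec <- tibble::tibble(source = character(), target = character(),
                                kind = character(), a = numeric(),
                                b = numeric(), v_max = numeric(),
                                K = numeric(), h = numeric(),
                                noise_sd = numeric())
  }
  edge_spec <- tibble::as_tibble(edge_spec)
  if (nrow(edge_spec) > 0) {
    stopifnot(all(edge_spec$kind %in% c("linear", "saturating")))
    if ("K" %in% names(edge_spec) &&
        any(edge_spec$K[edge_spec$kind == "saturating"] <= 0, na.rm = TRUE)) {
      stop("Hill half-saturation K must be > 0", call. = FALSE)
    }
  }
  if (is.null(maternal_loading)) {
    maternal_loading <- tibble::tibble(gene = character(), loading = numeric())
  }
  structure(list(genes = genes, n_dams = n_dams, n_sires = n_sires,
                 n_replicates = n_replicates, timepoints = timepoints,
                 network = network, edge_spec = edge_spec,
                 variance_spec = variance_spec,
                 maternal_loading = tibble::as_tibble(maternal_loading),
                 edge_strength_by_time = edge_strength_by_time,
                 morphology = morphology,
                 propagate_replicates = propagate_replicates,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Regulatory edge response function
#'
#' Expected downstream contribution of an upstream expression level `x`:
#' linear `a + b * x` for quantitative ("sensitive") interactions, or a
#' saturating Hill response `a + v_max * x^h / (K^h + x^h)` for switch-like
#' ("insensitive") interactions that plateau once the regulator exceeds its
#' half-saturation level `K`.
#'
#' @param kind `"linear"` or `"saturating"`.
#' @param params list/row with `a`, `b` (linear) or `a`, `v_max`, `K`, `h`.
#' @param x upstream expression level(s), `x >= 0`.
#' @return numeric vector of expected downstream values.
#' @export
edge_response <- function(kind, params, x) {
  a <- params$a %||% 0
  if (kind == "linear") {
    a + params$b * x
  } else if (kind == "saturating") {
    h <- params$h %||% 1
    a + params$v_max * x^h / (params$K^h + x^h)
  } else {
    stop("unknown edge kind: ", kind, call. = FALSE)
  }
}

# Kahn topological sort over the union of edges; NULL if cyclic
topo_order <- function(genes, edges) {
  indeg <- setNames(integer(length(genes)), genes)
  adj <- split(edges$target, edges$source)
  for (tg in edges$target) indeg[tg] <- indeg[tg] + 1L
  queue <- names(indeg)[indeg == 0]
  out <- character(0)
  while (length(queue) > 0) {
    g <- queue[1]; queue <- queue[-1]
    out <- c(out, g)
    for (tg in adj[[g]] %||% character(0)) {
      indeg[tg] <- indeg[tg] - 1L
      if (indeg[tg] == 0L) queue <- c(queue, tg)
    }
  }
  if (length(out) < length(genes)) NULL else out
}

#' Simulate an NCII-cross expression + morphology dataset
#'
#' Root genes (no active in-edge at a time point) take the hierarchical
#' form `mu_gt + dam_i + sire_j + inter_ij + maternal (t = 1) + residual`,
#' with parental effects drawn once per parent (or family) per gene x time
#' from zero-mean normals at the configured variances. Genes downstream of
#' active edges additionally receive the summed edge-responses of their
#' regulators' family means, each centred at the regulator's mean so that
#' propagation moves variance, not the mean level. Morphology is generated per individual
#' from the configured rod baselines, terminal-gene family-mean drivers,
#' the per-dam maternal factor and individual noise.
#'
#' @param cfg a [sim_config()].
#' @return object of class `grn_sim`: list with `expression` (long tibble),
#'   `morphology` (tibble or NULL), `network`, `config` and `truth`
#'   (realized parental/maternal draws and edge kinds).
#' @export
simulate_cross <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  genes <- cfg$genes$gene
  ord <- topo_order(unique(c(genes, cfg$network$genes)), cfg$network$edges)
  if (is.null(ord)) stop("cyclic edge graph: generation is topological-order",
                         call. = FALSE)
  ord <- ord[ord %in% genes]
  dams <- sprintf("D%02d", seq_len(cfg$n_dams))
  sires <- sprintf("S%02d", seq_len(cfg$n_sires))
  fam <- expand.grid(dam_id = dams, sire_id = sires,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n_fam <- nrow(fam)
  reps <- seq_len(cfg$n_replicates)

  # parental + residual draws, one substream per gene
  truth_par <- list(); draws <- list()
  for (g in genes) {
    set.seed(substream_seed(cfg$seed, paste0("parental:", g)))
    for (t in cfg$timepoints) {
      vs <- cfg$variance_spec[cfg$variance_spec$gene == g &
                              cfg$variance_spec$timepoint == t, ]
      if (nrow(vs) != 1) {
        stop("variance_spec must have one row for gene ", g, " time ", t,
             call. = FALSE)
      }
      draws[[paste(g, t)]] <- list(
        vs = vs,
        dam = rnorm(cfg$n_dams, 0, sqrt(vs$sigma2_dam)),
        sire = rnorm(cfg$n_sires, 0, sqrt(vs$sigma2_sire)),
        inter = rnorm(n_fam, 0, sqrt(vs$sigma2_inter)))
    }
    set.seed(substream_seed(cfg$seed, paste0("residual:", g)))
    for (t in cfg$timepoints) {
      d <- draws[[paste(g, t)]]
      d$resid <- rnorm(n_fam * cfg$n_replicates, 0, sqrt(d$vs$sigma2_res))
      draws[[paste(g, t)]] <- d
    }
  }
  set.seed(substream_seed(cfg$seed, "maternal"))
  maternal <- rnorm(cfg$n_dams)
  if (cfg$n_dams > 1 && sd(maternal) > 0) {
    # the latent is centred and scaled to unit variance across the dams by
    # construction, so the strength of the maternal condition is set by
    # the loadings alone rather than by the luck of a handful of draws
    maternal <- (maternal - mean(maternal)) / sd(maternal)
  }
  maternal <- setNames(maternal, dams)
  loading <- setNames(rep(0, length(genes)), genes)
  if (nrow(cfg$maternal_loading) > 0) {
    loading[cfg$maternal_loading$gene] <- cfg$maternal_loading$loading
  }
  set.seed(substream_seed(cfg$seed, "edge_noise"))

  edge_of <- function(src, tgt) {
    cfg$edge_spec[cfg$edge_spec$source == src & cfg$edge_spec$target == tgt, ]
  }

  rows <- vector("list", length(genes) * length(cfg$timepoints))
  k <- 0
  for (t in cfg$timepoints) {
    strength <- if (t <= length(cfg$edge_strength_by_time))
      cfg$edge_strength_by_time[t] else 0
    ae <- if (t <= 6) active_edges(cfg$network, t) else
      cfg$network$edges[0, , drop = FALSE]
    # family-level values built in topological order
    famval <- matrix(NA_real_, nrow = n_fam, ncol = length(genes),
                     dimnames = list(NULL, genes))
    cultval <- matrix(NA_real_, nrow = n_fam * cfg$n_replicates,
                      ncol = length(genes), dimnames = list(NULL, genes))
    dam_idx <- match(fam$dam_id, dams)
    sire_idx <- match(fam$sire_id, sires)
    for (g in ord) {
      d <- draws[[paste(g, t)]]
      base <- d$vs$mean + d$dam[dam_idx] + d$sire[sire_idx] + d$inter
      if (t == 1) base <- base + loading[g] * maternal[dam_idx]
      in_e <- ae[ae$target == g & ae$source %in% genes, , drop = FALSE]
      prop_fam <- 0; prop_cult <- 0
      if (nrow(in_e) > 0 && strength != 0) {
        contrib_f <- matrix(0, n_fam, nrow(in_e))
        contrib_c <- matrix(0, n_fam * cfg$n_replicates, nrow(in_e))
        for (i in seq_len(nrow(in_e))) {
          es <- edge_of(in_e$source[i], g)
          if (nrow(es) != 1) {
            stop("edge_spec missing for ", in_e$source[i], " -> ", g,
                 call. = FALSE)
          }
          mu_up <- cfg$variance_spec$mean[
            cfg$variance_spec$gene == in_e$source[i] &
            cfg$variance_spec$timepoint == t]
          f0 <- edge_response(es$kind, es, mu_up)
          contrib_f[, i] <- edge_response(es$kind, es, famval[, in_e$source[i]]) - f0
          contrib_c[, i] <- edge_response(es$kind, es,
                                          cultval[, in_e$source[i]]) - f0
          nsd <- es$noise_sd %||% 0
          if (length(nsd) == 1 && !is.na(nsd) && nsd > 0) {
            en <- rnorm(n_fam, 0, nsd)
            contrib_f[, i] <- contrib_f[, i] + en
            contrib_c[, i] <- contrib_c[, i] + rep(en, cfg$n_replicates)
          }
        }
        prop_fam <- strength * rowSums(contrib_f)
        prop_cult <- strength * rowSums(contrib_c)
      }
      fv <- base + prop_fam
      famval[, g] <- fv
      res <- d$resid
      cv <- rep(base, cfg$n_replicates) +
        (if (cfg$propagate_replicates) prop_cult else rep(prop_fam, cfg$n_replicates)) +
        res
      cultval[, g] <- cv
      k <- k + 1
      rows[[k]] <- tibble::tibble(
        gene = g,
        dam_id = rep(fam$dam_id, cfg$n_replicates),
        sire_id = rep(fam$sire_id, cfg$n_replicates),
        replicate = rep(reps, each = n_fam),
        timepoint = t,
        value = cv)
    }
  }
  expr <- dplyr::bind_rows(rows)
  expr$culture_id <- paste0(expr$dam_id, "x", expr$sire_id, "_r",
                            expr$replicate)
  expr$sample_id <- paste0(expr$culture_id, "_t", expr$timepoint)
  expr$background <- 0
  expr <- dplyr::select(expr, "gene", dplyr::all_of(expr_meta_cols),
                        "value", "background")

  morph <- NULL
  if (!is.null(cfg$morphology)) {
    morph <- simulate_morphology(cfg, expr, maternal)
  }

  truth_components <- dplyr::bind_rows(lapply(names(draws), function(nm) {
    d <- draws[[nm]]
    parts <- strsplit(nm, " ")[[1]]
    tibble::tibble(gene = parts[1], timepoint = as.integer(parts[2]),
                   mean = d$vs$mean,
                   sigma2_dam = d$vs$sigma2_dam, sigma2_sire = d$vs$sigma2_sire,
                   sigma2_inter = d$vs$sigma2_inter,
                   sigma2_res = d$vs$sigma2_res,
                   dam_effects = list(setNames(d$dam, dams)),
                   sire_effects = list(setNames(d$sire, sires)),
                   inter_effects = list(d$inter))
  }))

  structure(list(
    expression = expr,
    morphology = morph,
    network = cfg$network,
    config = cfg,
    truth = list(components = truth_components,
                 maternal = tibble::tibble(dam_id = dams, value = maternal),
                 maternal_loading = tibble::tibble(gene = genes,
                                                   loading = unname(loading)),
                 edge_kinds = if (nrow(cfg$edge_spec) > 0)
                   cfg$edge_spec[c("source", "target", "kind")] else
                   cfg$edge_spec)),
    class = "grn_sim")
}

# rod lengths per individual: baseline + driver-gene family means +
# maternal factor + individual noise
simulate_morphology <- function(cfg, expr, maternal) {
  mo <- cfg$morphology
  stopifnot(!is.null(mo$rods), !is.null(mo$n_individuals))
  fm <- family_means(expr)
  cultures <- dplyr::distinct(expr, .data$culture_id, .data$dam_id,
                              .data$sire_id, .data$replicate)
  set.seed(substream_seed(cfg$seed, "morphology"))
  rods <- names(mo$rods)
  n_ind <- mo$n_individuals
  out <- vector("list", nrow(cultures))
  for (ci in seq_len(nrow(cultures))) {
    cu <- cultures[ci, ]
    base <- mo$rods
    if (!is.null(mo$drivers) && nrow(mo$drivers) > 0) {
      for (i in seq_len(nrow(mo$drivers))) {
        dr <- mo$drivers[i, ]
        v <- fm$value[fm$gene == dr$gene & fm$timepoint == dr$timepoint &
                      fm$dam_id == cu$dam_id & fm$sire_id == cu$sire_id]
        mu_g <- cfg$variance_spec$mean[cfg$variance_spec$gene == dr$gene &
                                       cfg$variance_spec$timepoint == dr$timepoint]
        base[dr$rod] <- base[dr$rod] + dr$loading * (v - mu_g)
      }
    }
    if (!is.null(mo$maternal)) {
      base[names(mo$maternal)] <- base[names(mo$maternal)] +
        mo$maternal * maternal[cu$dam_id]
    }
    m <- matrix(rep(base, each = n_ind), nrow = n_ind,
                dimnames = list(NULL, rods)) +
      matrix(rnorm(n_ind * length(rods), 0, mo$noise_sd), nrow = n_ind)
    m[m < 0] <- 0
    out[[ci]] <- dplyr::bind_cols(
      tibble::tibble(culture_id = cu$culture_id,
                     individual_id = sprintf("%s_i%02d", cu$culture_id,
                                             seq_len(n_ind))),
      tibble::as_tibble(m))
  }
  res <- dplyr::bind_rows(out)
  attr(res, "morph_type") <- "rods"
  res
}

#' @export
print.grn_sim <- function(x, ...) {
  cat("<grn_sim> ", dplyr::n_distinct(x$expression$gene), " genes x ",
      dplyr::n_distinct(x$expression$sample_id), " samples",
      if (!is.null(x$morphology)) paste0("; morphology for ",
        dplyr::n_distinct(x$morphology$culture_id), " cultures"),
      "\n", sep = "")
  invisible(x)
}

#' Realized ground truth of a simulated dataset
#'
#' Empirical (realized) variances of the drawn dam/sire/interaction effects
#' per gene x time, the configured edge kinds, and the morphology driver
#' list — the oracle against which recovery of variance components, edge
#' classes and morphology drivers is tested.
#'
#' @param ds a `grn_sim` object.
#' @return list with `components` (tibble: gene, timepoint, nominal and
#'   realized variances), `edge_labels` (tibble with `label` =
#'   sensitive/insensitive implied by the edge kind) and
#'   `morphology_drivers`.
#' @export
realized_truth_summary <- function(ds) {
  stopifnot(inherits(ds, "grn_sim"))
  tc <- ds$truth$components
  comp <- dplyr::mutate(
    dplyr::select(tc, "gene", "timepoint", "mean", dplyr::starts_with("sigma2")),
    realized_dam = vapply(tc$dam_effects, var, numeric(1)),
    realized_sire = vapply(tc$sire_effects, var, numeric(1)),
    realized_inter = vapply(tc$inter_effects, var, numeric(1)))
  labels <- ds$truth$edge_kinds
  if (nrow(labels) > 0) {
    labels$label <- ifelse(labels$kind == "linear", "sensitive", "insensitive")
  }
  drivers <- if (!is.null(ds$config$morphology$drivers))
    tibble::as_tibble(ds$config$morphology$drivers) else NULL
  list(components = comp, edge_labels = labels, morphology_drivers = drivers)
}
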