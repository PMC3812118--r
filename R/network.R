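# Curated developmental gene regulatory network: directed signed edges with
# per-time-point activity windows and tissue annotations. Edge activity is
# only annotated for time points 1..6; the final sampling time has no
# activity information and is never part of an activity window.

sign_tokens <- c(activating = "activating", activate = "activating",
                 activator  = "activating", positive = "activating",
                 repressing = "repressing", repress  = "repressing",
                 repressor  = "repressing", negative = "repressing")

#' Construct a regulatory-network object
#'
#' @param edges tibble with columns `source`, `target`, `sign`,
#'   `timepoints` (list-column of integers in 1..6, or a comma-separated
#'   character column), `tissue`. Self-loops are dropped with a message
#'   (self-regulation is excluded because within-time-point correlations
#'   cannot speak to it). Edges must be unique by (source, target, tissue).
#' @param genes optional character vector of known genes; defaults to the
#'   union of edge endpoints.
#' @return an object of class `grn_network` with elements `edges` (tibble)
#'   and `genes` (character).
#' @export
network <- function(edges, genes = NULL) {
  edges <- tibble::as_tibble(edges)
  need <- c("source", "target", "sign", "timepoints", "tissue")
  missing <- setdiff(need, names(edges))
  if (length(missing) > 0) {
    stop("edge table missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (is.character(edges$timepoints)) {
    edges$timepoints <- lapply(strsplit(edges$timepoints, ","),
                               function(x) as.integer(trimws(x)))
  }
  bad_t <- vapply(edges$timepoints,
                  function(tp) length(tp) == 0 || anyNA(tp) ||
                    any(tp < 1 | tp > 6), logical(1))
  if (any(bad_t)) {
    stop("edge activity time points must be a non-empty subset of 1..6 (rows ",
         paste(which(bad_t), collapse = ", "), ")", call. = FALSE)
  }
  tok <- sign_tokens[tolower(edges$sign)]
  if (anyNA(tok)) {
    stop("unknown sign token(s): ",
         paste(unique(edges$sign[is.na(tok)]), collapse = ", "), call. = FALSE)
  }
  edges$sign <- unname(tok)
  self <- edges$source == edges$target
  if (any(self)) {
    message("dropping ", sum(self), " self-regulatory edge(s): ",
            paste(unique(edges$source[self]), collapse = ", "))
    edges <- edges[!self, , drop = FALSE]
  }
  key <- paste(edges$source, edges$target, edges$tissue)
  if (anyDuplicated(key)) {
    stop("duplicate edges by (source, target, tissue)", call. = FALSE)
  }
  genes <- sort(unique(c(genes, edges$source, edges$target)))
  structure(list(edges = edges, genes = genes), class = "grn_network")
}

#' @export
print.grn_network <- function(x, ...) {
  cat("<grn_network> ", length(x$genes), " genes, ",
      nrow(x$edges), " edges\n", sep = "")
  if (nrow(x$edges) > 0) print(utils::head(x$edges, 5))
  invisible(x)
}

#' Read a network edge table from TSV
#'
#' Expected columns: `source`, `target`, `sign`, `timepoints` (comma list of
#' integers in 1..6) and `tissue`. Self-loops are dropped (and reported).
#'
#' @param path TSV path.
#' @return a [network()] object.
#' @export
read_edge_table <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  if (nrow(tab) == 0) {
    return(network(tibble::tibble(source = character(), target = character(),
                                  sign = character(),
                                  timepoints = list(), tissue = character())))
  }
  network(tab)
}

#' Write a network edge table to TSV
#' @param net a `grn_network`.
#' @param path output TSV path.
#' @return `net`, invisibly.
#' @export
write_edge_table <- function(net, path) {
  edges <- net$edges
  edges$timepoints <- vapply(edges$timepoints, paste, character(1),
                             collapse = ",")
  readr::write_tsv(edges, path)
  invisible(net)
}

#' Export a parsed network as JSON
#' @param net a `grn_network`.
#' @param path output path.
#' @return `net`, invisibly.
#' @export
write_network_json <- function(net, path) {
  jsonlite::write_json(
    list(genes = net$genes,
         edges = lapply(seq_len(nrow(net$edges)), function(i) {
           e <- net$edges[i, ]
           list(source = e$source, target = e$target, sign = e$sign,
                timepoints = e$timepoints[[1]], tissue = e$tissue)
         })),
    path, auto_unbox = TRUE)
  invisible(net)
}

#' Import a Biotapestry-flavoured XML network
#'
#' Parses a small subset of the Biotapestry export format: `<gene>` nodes and
#' `<link>` records with `src`, `targ`, `sign`, `region` and an activity
#' window `minTime`/`maxTime` in hours of the source developmental schedule.
#' Because the network database and the expression assay can follow
#' different rearing-temperature schedules, a conversion table mapping each
#' sampled time point (1..6) to its hour on the database schedule is
#' required. A window that contains a sampled hour is assigned to that time
#' point; a window falling strictly between two sampled hours is assigned to
#' the later one.
#'
#' @param path XML path.
#' @param time_conversion data frame with columns `timepoint` (1..6) and
#'   `hour` (the database-schedule hour of that sampling time).
#' @return a [network()] object.
#' @export
import_biotapestry_xml <- function(path, time_conversion) {
  stopifnot(all(c("timepoint", "hour") %in% names(time_conversion)))
  tc <- time_conversion[order(time_conversion$hour), ]
  doc <- xml2::read_xml(path)
  links <- xml2::xml_find_all(doc, ".//link")
  if (length(links) == 0) {
    return(read_edge_table_empty())
  }
  rows <- purrr::map_dfr(links, function(lk) {
    tibble::tibble(
      source = xml2::xml_attr(lk, "src"),
      target = xml2::xml_attr(lk, "targ"),
      sign = xml2::xml_attr(lk, "sign"),
      tissue = xml2::xml_attr(lk, "region"),
      min_time = as.numeric(xml2::xml_attr(lk, "minTime")),
      max_time = as.numeric(xml2::xml_attr(lk, "maxTime")))
  })
  if (anyNA(rows$min_time) || anyNA(rows$max_time)) {
    stop("link without a numeric minTime/maxTime activity window",
         call. = FALSE)
  }
  rows$timepoints <- purrr::map2(rows$min_time, rows$max_time, function(lo, hi) {
    inside <- tc$timepoint[tc$hour >= lo & tc$hour <= hi]
    if (length(inside) > 0) return(as.integer(inside))
    later <- tc$timepoint[tc$hour > hi]
    if (length(later) == 0) {
      stop("activity window [", lo, ", ", hi,
           "] lies outside the time-conversion table", call. = FALSE)
    }
    as.integer(later[1])
  })
  genes <- xml2::xml_attr(xml2::xml_find_all(doc, ".//gene"), "name")
  network(dplyr::select(rows, -"min_time", -"max_time"), genes = genes)
}

read_edge_table_empty <- function() {
  network(tibble::tibble(source = character(), target = character(),
                         sign = character(), timepoints = list(),
                         tissue = character()))
}

# edges (rows of net$edges) active at time t, optionally dropping repressors
active_edges <- function(net, t, include_repressing = TRUE) {
  keep <- vapply(net$edges$timepoints, function(tp) t %in% tp, logical(1))
  if (!include_repressing) keep <- keep & net$edges$sign == "activating"
  net$edges[keep, , drop = FALSE]
}

#' Genes active at a time point
#'
#' A gene is active at time `t` when it is incident to at least one edge
#' whose activity window covers `t`; when an expression table is supplied
#' the gene must additionally pass [expressed_filter()] at `t`.
#'
#' @param net a `grn_network`.
#' @param t time point in 1..6.
#' @param expr optional long expression tibble.
#' @param min_samples threshold passed to [expressed_filter()].
#' @param include_repressing include repressing edges when determining
#'   incidence (default TRUE).
#' @return character vector of gene ids.
#' @export
active_genes <- function(net, t, expr = NULL, min_samples = 20,
                         include_repressing = TRUE) {
  stopifnot(t >= 1, t <= 6)
  ae <- active_edges(net, t, include_repressing)
  g <- sort(unique(c(ae$source, ae$target)))
  if (!is.null(expr)) {
    g <- g[vapply(g, function(gg) {
      gg %in% expr$gene && expressed_filter(expr, gg, t, min_samples)
    }, logical(1))]
  }
  g
}

# unordered pair key
pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "||")

#' Pairs of active genes with no known interaction
#'
#' Returns every unordered pair of genes active at `t` that has no edge in
#' either direction at *any* time point. "No known interaction" is global
#' across time, which keeps the background conservative: a pair linked at
#' another time is never treated as independent.
#'
#' @inheritParams active_genes
#' @return tibble with columns `a`, `b` (a < b lexically).
#' @export
noninteracting_pairs <- function(net, t, expr = NULL, min_samples = 20,
                                 include_repressing = TRUE) {
  g <- active_genes(net, t, expr, min_samples, include_repressing)
  if (length(g) < 2) return(tibble::tibble(a = character(), b = character()))
  cmb <- utils::combn(g, 2)
  linked <- unique(pair_key(net$edges$source, net$edges$target))
  keep <- !(pair_key(cmb[1, ], cmb[2, ]) %in% linked)
  tibble::tibble(a = cmb[1, keep], b = cmb[2, keep])
}
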