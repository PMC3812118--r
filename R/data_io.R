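# Reading, writing and normalising expression and morphology tables.
#
# Expression data live in a long tibble with one row per (gene, sample):
#   gene, sample_id, culture_id, dam_id, sire_id, replicate, timepoint,
#   value, background
# On disk the matrix is a wide TSV (gene rows x sample columns) plus a
# metadata TSV with one row per sample. Missing values are "NA" or empty
# fields and stay NA in the tibble; downstream statistics drop them pairwise.

expr_meta_cols <- c("sample_id", "culture_id", "dam_id", "sire_id",
                    "replicate", "timepoint")

assert_expr_tbl <- function(expr) {
  need <- c("gene", expr_meta_cols, "value")
  missing <- setdiff(need, names(expr))
  if (length(missing) > 0) {
    stop("expression table is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(expr)
}

#' Read an expression matrix and its sample metadata
#'
#' Reads a wide TSV (one row per gene, one column per sample, first column
#' `gene`) together with a metadata TSV (one row per sample: `sample_id`,
#' `culture_id`, `dam_id`, `sire_id`, `replicate`, `timepoint`, and an
#' optional per-sample `background` scalar) and returns a long tibble with
#' one row per (gene, sample). Samples present in the metadata but absent
#' from the matrix are reported with a message; a matrix column with no
#' metadata row is an error.
#'
#' @param path path to the wide expression TSV.
#' @param meta_path path to the sample metadata TSV.
#' @return a long tibble: `gene`, sample metadata columns, `value`,
#'   `background` (0 where the metadata carries none).
#' @seealso [write_expression()], [normalize_to_reference()]
#' @export
read_expression <- function(path, meta_path) {
  # values come in as text and through base R's correctly-rounded strtod,
  # so a write -> read round trip is bit-exact
  wide <- readr::read_tsv(path, show_col_types = FALSE, na = c("", "NA"),
                          col_types = readr::cols(.default = "c"))
  wide[-1] <- lapply(wide[-1], as.numeric)
  if (names(wide)[1] != "gene") names(wide)[1] <- "gene"
  if (anyDuplicated(wide$gene)) {
    stop("duplicated gene names in ", path, ": ",
         paste(unique(wide$gene[duplicated(wide$gene)]), collapse = ", "),
         call. = FALSE)
  }
  meta <- readr::read_tsv(meta_path, show_col_types = FALSE, na = c("", "NA"))
  missing_meta <- setdiff(setdiff(names(wide), "gene"), meta$sample_id)
  if (length(missing_meta) > 0) {
    stop("samples in matrix but not in metadata: ",
         paste(missing_meta, collapse = ", "), call. = FALSE)
  }
  unmatched <- setdiff(meta$sample_id, names(wide))
  if (length(unmatched) > 0) {
    message("metadata rows without matrix columns (ignored): ",
            paste(unmatched, collapse = ", "))
    meta <- dplyr::filter(meta, .data$sample_id %in% names(wide))
  }
  if (!"background" %in% names(meta)) meta$background <- 0
  long <- tidyr::pivot_longer(wide, -"gene",
                              names_to = "sample_id", values_to = "value")
  out <- dplyr::inner_join(long, meta, by = "sample_id")
  out <- dplyr::select(out, "gene", dplyr::all_of(expr_meta_cols),
                       "value", "background")
  assert_expr_tbl(out)
  tibble::as_tibble(out)
}

#' Write an expression tibble back to wide TSV + metadata TSV
#'
#' Inverse of [read_expression()]; the round trip reproduces values to full
#' precision.
#'
#' @param expr long expression tibble.
#' @param path,meta_path output paths for the matrix and metadata TSVs.
#' @return `expr`, invisibly.
#' @export
write_expression <- function(expr, path, meta_path) {
  assert_expr_tbl(expr)
  wide <- tidyr::pivot_wider(
    dplyr::select(expr, "gene", "sample_id", "value"),
    names_from = "sample_id", values_from = "value")
  # 17 significant digits so the round trip is bit-exact for doubles
  num <- setdiff(names(wide), "gene")
  wide[num] <- lapply(wide[num], function(x) {
    out <- sprintf("%.17g", x)
    out[is.na(x)] <- NA_character_
    out
  })
  readr::write_tsv(wide, path)
  meta <- dplyr::distinct(
    dplyr::select(expr, dplyr::all_of(expr_meta_cols),
                  dplyr::any_of("background")))
  readr::write_tsv(meta, meta_path)
  invisible(expr)
}

#' Normalise expression to a reference gene
#'
#' Background-corrects each measurement with its sample's background scalar
#' and divides by the background-corrected value of the reference gene in
#' the same sample, so the reference row becomes identically 1. This is the
#' standard single-reference normalisation used for multiplexed expression
#' assays.
#'
#' @param expr long expression tibble (see [read_expression()]).
#' @param reference_gene gene identifier present in every sample.
#' @return normalised tibble; `background` is reset to 0 (already removed).
#' @export
normalize_to_reference <- function(expr, reference_gene) {
  assert_expr_tbl(expr)
  if (!reference_gene %in% expr$gene) {
    stop("reference gene '", reference_gene, "' not present", call. = FALSE)
  }
  bg <- if ("background" %in% names(expr)) expr$background else 0
  ref <- dplyr::filter(expr, .data$gene == reference_gene)
  ref_bg <- if ("background" %in% names(ref)) ref$background else 0
  ref_val <- setNames(ref$value - ref_bg, ref$sample_id)
  bad <- names(ref_val)[!is.na(ref_val) & ref_val <= 0]
  if (any(is.na(ref_val))) {
    bad <- union(bad, names(ref_val)[is.na(ref_val)])
  }
  if (length(bad) > 0) {
    stop("reference gene '", reference_gene,
         "' has non-positive or missing background-corrected values in: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- dplyr::mutate(expr,
    value = (.data$value - bg) / ref_val[.data$sample_id],
    background = 0)
  out
}

#' Is a gene sufficiently expressed at a time point?
#'
#' A (gene, time point) combination is analysable only when enough samples
#' measured it above background; with fewer than `min_samples` such samples
#' no variance measures are calculated for it.
#'
#' @param expr long expression tibble.
#' @param gene gene identifier.
#' @param timepoint time point (integer).
#' @param min_samples minimum number of above-background samples (default 20).
#' @return `TRUE` iff at least `min_samples` samples at `timepoint` have
#'   `value > background` (strictly).
#' @export
expressed_filter <- function(expr, gene, timepoint, min_samples = 20) {
  assert_expr_tbl(expr)
  if (!gene %in% expr$gene) {
    stop("gene '", gene, "' not present", call. = FALSE)
  }
  rows <- dplyr::filter(expr, .data$gene == !!gene,
                        .data$timepoint == !!timepoint)
  bg <- if ("background" %in% names(rows)) rows$background else 0
  sum(!is.na(rows$value) & rows$value > bg) >= min_samples
}

#' Per-family mean expression
#'
#' Collapses replicate cultures to family (dam x sire) means at each gene and
#' time point; replicates are the unit of the variance models, but pairwise
#' correlation and morphology analyses operate on these means.
#'
#' @param expr long expression tibble.
#' @return tibble: `gene`, `dam_id`, `sire_id`, `timepoint`, `value`.
#' @export
family_means <- function(expr) {
  assert_expr_tbl(expr)
  dplyr::summarise(
    dplyr::group_by(expr, .data$gene, .data$dam_id, .data$sire_id,
                    .data$timepoint),
    value = mean(.data$value, na.rm = TRUE), .groups = "drop")
}

landmark_cols <- as.vector(t(outer(1:8, c("x", "y", "z"),
                                   function(i, a) paste0(a, i))))

#' Read a morphology table
#'
#' Accepts either eight 3-D landmark coordinate columns (`x1..z8`, in µm)
#' or named skeletal rod-length columns (µm), one row per individual, with
#' `culture_id` and `individual_id` identifying columns.
#'
#' @param path TSV path.
#' @return tibble with an attribute `morph_type` of `"landmarks"` or
#'   `"rods"`.
#' @export
read_morphology <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, na = c("", "NA"))
  if (!all(c("culture_id", "individual_id") %in% names(tab))) {
    stop("morphology table needs culture_id and individual_id columns",
         call. = FALSE)
  }
  present <- intersect(landmark_cols, names(tab))
  if (length(present) > 0 && length(present) < length(landmark_cols)) {
    stop("partial landmark columns: expected all of x1..z8, found only ",
         paste(present, collapse = ", "), call. = FALSE)
  }
  if (length(present) == length(landmark_cols)) {
    attr(tab, "morph_type") <- "landmarks"
    return(tab)
  }
  rods <- setdiff(names(tab), c("culture_id", "individual_id"))
  if (length(rods) == 0) stop("no landmark or rod-length columns", call. = FALSE)
  vals <- as.matrix(tab[rods])
  if (any(vals < 0, na.rm = TRUE)) {
    stop("negative rod lengths in columns: ",
         paste(rods[apply(vals < 0, 2, any, na.rm = TRUE)], collapse = ", "),
         call. = FALSE)
  }
  attr(tab, "morph_type") <- "rods"
  tab
}

#' Write a morphology table
#' @param morph tibble as returned by [read_morphology()].
#' @param path output TSV path.
#' @return `morph`, invisibly.
#' @export
write_morphology <- function(morph, path) {
  readr::write_tsv(morph, path)
  invisible(morph)
}
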