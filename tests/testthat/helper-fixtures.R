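# Fixtures built in code: tiny expression tables, networks and morphology
# sets used across the test files.

# long expression tibble from a genes x samples value matrix and a 6x6(xR)
# cross layout; values_matrix rows = genes, cols = samples in the order of
# the generated metadata
make_expr <- function(values, n_dams = 2, n_sires = 2, n_replicates = 1,
                      timepoints = 1, genes = NULL, background = 0) {
  genes <- genes %||% sprintf("g%d", seq_len(nrow(values)))
  meta <- expand.grid(dam_id = sprintf("D%02d", seq_len(n_dams)),
                      sire_id = sprintf("S%02d", seq_len(n_sires)),
                      replicate = seq_len(n_replicates),
                      timepoint = timepoints,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta$culture_id <- paste0(meta$dam_id, "x", meta$sire_id, "_r",
                            meta$replicate)
  meta$sample_id <- paste0(meta$culture_id, "_t", meta$timepoint)
  stopifnot(ncol(values) == nrow(meta))
  out <- purrr::map_dfr(seq_along(genes), function(i) {
    dplyr::mutate(tibble::as_tibble(meta), gene = genes[i],
                  value = values[i, ], background = background)
  })
  dplyr::select(out, "gene", "sample_id", "culture_id", "dam_id", "sire_id",
                "replicate", "timepoint", "value", "background")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# NCII-structured family means for one gene: mu + dam + sire + noise over a
# 6x6 cross (single replicate)
ncii_family_values <- function(sigma2_dam = 0.05, sigma2_sire = 0.05,
                               sigma2_res = 0.1, mu = 1,
                               n_dams = 6, n_sires = 6) {
  dam <- rnorm(n_dams, 0, sqrt(sigma2_dam))
  sire <- rnorm(n_sires, 0, sqrt(sigma2_sire))
  grid <- expand.grid(d = seq_len(n_dams), s = seq_len(n_sires))
  mu + dam[grid$d] + sire[grid$s] + rnorm(nrow(grid), 0, sqrt(sigma2_res))
}

# 4-gene toy network with one edge, used by pair-enumeration tests
toy_network <- function() {
  network(tibble::tibble(
    source = "gA", target = "gB", sign = "activating",
    timepoints = list(1:3), tissue = "EM"),
    genes = c("gA", "gB", "gC", "gD"))
}

# a tiny Biotapestry-flavoured XML file; returns its path
write_toy_xml <- function(links, dir = tempdir()) {
  path <- file.path(dir, paste0("net-", as.integer(runif(1, 1, 1e8)), ".xml"))
  writeLines(c(
    "<?xml version='1.0' encoding='UTF-8'?>",
    "<BioTapestry>",
    "  <genes>",
    "    <gene name='Alpha'/>",
    "    <gene name='Beta'/>",
    "  </genes>",
    "  <links>",
    links,
    "  </links>",
    "</BioTapestry>"), path)
  path
}

# hour of each sampled time point on the database schedule
toy_time_conversion <- function() {
  data.frame(timepoint = 1:6, hour = c(6, 12, 18, 21, 27, 33))
}

# fabricated ncii_fit-shaped object carrying only breeding values (for
# G-matrix structure tests) or only components (for rank tests)
fake_fit <- function(components = NULL, breeding_values = NULL) {
  structure(list(components = components, breeding_values = breeding_values,
                 gene_stats = tibble::tibble(), skipped = tibble::tibble(),
                 chain = chain_control()), class = "ncii_fit")
}

# components tibble from per-gene dam/sire scaled values at one time point
fake_components <- function(dam, sire, timepoint = 1) {
  genes <- sprintf("g%02d", seq_along(dam))
  dplyr::bind_rows(
    tibble::tibble(gene = genes, timepoint = timepoint, term = "dam",
                   mean = dam, scaled_mean = dam),
    tibble::tibble(gene = genes, timepoint = timepoint, term = "sire",
                   mean = sire, scaled_mean = sire))
}
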