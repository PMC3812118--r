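# Network parsing, Biotapestry XML import and pair enumeration.

test_that("edge table parsing: activity lists, self-loops, signs, bounds", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("source\ttarget\tsign\ttimepoints\ttissue",
               "Tgif\tHex\tactivate\t3,4,5,6\tEM",
               "Hex\tHex\tactivate\t2\tEM"), f)
  expect_message(net <- read_edge_table(f), "self-regulatory")
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$timepoints[[1]], 3:6)
  expect_equal(net$edges$sign, "activating")

  writeLines("source\ttarget\tsign\ttimepoints\ttissue", f)
  expect_equal(nrow(read_edge_table(f)$edges), 0)

  bad_sign <- tibble::tibble(source = "a", target = "b", sign = "maybe",
                             timepoints = list(1L), tissue = "EM")
  expect_error(network(bad_sign), "sign token")
  bad_time <- tibble::tibble(source = "a", target = "b", sign = "activate",
                             timepoints = list(7L), tissue = "EM")
  expect_error(network(bad_time), "1..6")
})

test_that("edge table write -> read round trips", {
  net <- network(tibble::tibble(
    source = c("a", "b"), target = c("b", "c"),
    sign = c("activating", "repressing"),
    timepoints = list(1:2, c(3L, 5L)), tissue = c("EM", "P")),
    genes = c("a", "b", "c", "d"))
  f <- tempfile(fileext = ".tsv")
  write_edge_table(net, f)
  back <- read_edge_table(f)
  expect_equal(back$edges$source, net$edges$source)
  expect_equal(back$edges$timepoints, net$edges$timepoints)
  expect_equal(back$edges$sign, net$edges$sign)
})

test_that("Biotapestry XML import maps activity windows to sampled times", {
  # window covering sampled hours 12 and 18 -> time points 2 and 3
  p <- write_toy_xml(
    "    <link src='Alpha' targ='Beta' sign='positive' region='EM' minTime='12' maxTime='18'/>")
  net <- import_biotapestry_xml(p, toy_time_conversion())
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$timepoints[[1]], 2:3)
  expect_true(all(c("Alpha", "Beta") %in% net$genes))

  # window strictly between sampled hours 21 and 27 -> later sample (t5)
  p <- write_toy_xml(
    "    <link src='Alpha' targ='Beta' sign='negative' region='P' minTime='23' maxTime='25'/>")
  net <- import_biotapestry_xml(p, toy_time_conversion())
  expect_equal(net$edges$timepoints[[1]], 5L)
  expect_equal(net$edges$sign, "repressing")

  # self-regulatory edge dropped
  p <- write_toy_xml(c(
    "    <link src='Alpha' targ='Alpha' sign='positive' region='EM' minTime='12' maxTime='18'/>",
    "    <link src='Alpha' targ='Beta' sign='positive' region='EM' minTime='12' maxTime='18'/>"))
  expect_message(net <- import_biotapestry_xml(p, toy_time_conversion()),
                 "self-regulatory")
  expect_equal(nrow(net$edges), 1)

  # window after the last sampled hour cannot be mapped
  p <- write_toy_xml(
    "    <link src='Alpha' targ='Beta' sign='positive' region='EM' minTime='40' maxTime='45'/>")
  expect_error(import_biotapestry_xml(p, toy_time_conversion()),
               "outside the time-conversion table")
})

test_that("active_genes respects activity windows and the expression filter", {
  net <- toy_network()                       # gA -> gB active at t 1..3
  expect_setequal(active_genes(net, 3), c("gA", "gB"))
  expect_length(active_genes(net, 5), 0)
  # with an expression table, genes must also pass the filter
  expr <- make_expr(matrix(c(rep(1, 36), rep(0, 36)), nrow = 2, byrow = TRUE),
                    n_dams = 6, n_sires = 6, genes = c("gA", "gB"))
  expect_equal(active_genes(net, 1, expr, min_samples = 20), "gA")
})

test_that("non-interacting pairs exclude edges at any time point", {
  net <- network(tibble::tibble(
    source = c("gA", "gC"), target = c("gB", "gD"),
    sign = "activating",
    timepoints = list(1:3, 4L), tissue = "EM"))
  # at t=1 all four genes are active only if incident to a t1 edge; gC,gD
  # are not -> only pair set among {gA,gB} minus their edge
  expect_equal(nrow(noninteracting_pairs(net, 1)), 0)
  # 4 active genes, 1 active edge at t1, but gC-gD linked at t4:
  # C(4,2) = 6 pairs - 2 linked (any time) = 4
  net2 <- network(tibble::tibble(
    source = c("gA", "gC"), target = c("gB", "gD"),
    sign = "activating",
    timepoints = list(1:3, c(1L, 4L)), tissue = "EM"))
  pairs <- noninteracting_pairs(net2, 1)
  expect_equal(nrow(pairs), 4)
  expect_false(any(pairs$a == "gA" & pairs$b == "gB"))
  # fully connected triangle -> no non-interacting pairs
  tri <- network(tibble::tibble(
    source = c("x", "y", "z"), target = c("y", "z", "x"),
    sign = "activating", timepoints = list(1L, 1L, 1L),
    tissue = c("EM", "P", "VE")))
  expect_equal(nrow(noninteracting_pairs(tri, 1)), 0)
})

test_that("pair counts partition all pairs of active genes", {
  set.seed(4)
  cfg <- sim_config_urchin(seed = 4)
  net <- cfg$network
  for (t in c(1, 4)) {
    act <- active_genes(net, t)
    ae <- net$edges[vapply(net$edges$timepoints, function(tp) t %in% tp,
                           logical(1)), ]
    ae <- ae[ae$source %in% act & ae$target %in% act, ]
    linked_now <- unique(paste(pmin(ae$source, ae$target),
                               pmax(ae$source, ae$target)))
    all_edges <- net$edges[net$edges$source %in% act &
                           net$edges$target %in% act, ]
    linked_ever <- unique(paste(pmin(all_edges$source, all_edges$target),
                                pmax(all_edges$source, all_edges$target)))
    n_cross_time <- length(setdiff(linked_ever, linked_now))
    n_non <- nrow(noninteracting_pairs(net, t))
    expect_equal(length(linked_now) + n_cross_time + n_non,
                 choose(length(act), 2))
  }
})

test_that("JSON export of a topology is readable and complete", {
  net <- toy_network()
  f <- tempfile(fileext = ".json")
  write_network_json(net, f)
  parsed <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_setequal(parsed$genes, net$genes)
  expect_equal(parsed$edges$source, "gA")
  expect_equal(unlist(parsed$edges$timepoints), 1:3)
})
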