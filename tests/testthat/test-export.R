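fixture_nets <- function() list(
  source_reporter = network_source_reporter(),
  source_not = network_source_not(),
  receiver = network_receiver(),
  hill1_cascade = network_hill1_cascade(),
  hill2_composed = network_hill2_composed(),
  oscillator = network_oscillator())

test_that("the oscillator graph has the expected topology", {
  g <- to_graph(network_oscillator())
  expect_equal(sum(igraph::V(g)$type == "operator"), 3)
  reg <- igraph::E(g)[igraph::E(g)$type == "regulation"]
  expect_length(reg, 4)
  # 2 edges into the two-input node, 1 into each one-input node
  deg_in <- table(igraph::head_of(g, reg)$name)
  expect_equal(unname(deg_in[c("op_A", "op_B", "op_C")]),
               c(2L, 1L, 1L), ignore_attr = TRUE)
  expect_equal(sum(igraph::E(g)$type == "production"), 6)
  sg <- igraph::E(g)$sign[igraph::E(g)$type == "regulation"]
  expect_setequal(sg, c("activation", "repression"))
  # compact operator-only view
  go <- to_graph(network_oscillator(), operators_only = TRUE)
  expect_equal(igraph::vcount(go), 3)
  expect_equal(igraph::ecount(go), 4)
})

test_that("trivial and contracted graphs are consistent", {
  g <- to_graph(network_source_reporter())
  expect_equal(sum(igraph::V(g)$type == "operator"), 1)
  expect_equal(sum(igraph::V(g)$type == "reporter"), 1)
  expect_equal(sum(igraph::E(g)$type == "production"), 1)
  expect_equal(sum(igraph::E(g)$type == "regulation"), 0)
  # production edge count always equals the summed operator out-degree
  for (net in fixture_nets()) {
    gg <- to_graph(net)
    expect_equal(sum(igraph::E(gg)$type == "production"),
                 sum(lengths(lapply(net$operators, `[[`, "outputs"))))
  }
})

test_that("distinct fixtures give non-isomorphic graphs and writers emit
           files", {
  nets <- fixture_nets()
  gs <- lapply(nets, to_graph)
  for (i in seq_along(gs)) for (j in seq_len(i - 1L))
    expect_false(igraph::isomorphic(gs[[i]], gs[[j]]),
                 info = paste(names(nets)[c(i, j)], collapse = " vs "))
  f1 <- tempfile(fileext = ".graphml")
  f2 <- tempfile(fileext = ".dot")
  write_graphml(gs$oscillator, f1)
  write_dot(gs$oscillator, f2)
  expect_gt(file.size(f1), 0)
  expect_true(any(grepl("digraph", readLines(f2))))
})

test_that("design JSON save/load round trip preserves every field", {
  for (net in fixture_nets()) {
    f <- tempfile(fileext = ".json")
    save_design(net, f)
    expect_identical(load_design(f), net, info = net$name)
    # graph of the round trip equals graph of the original
    expect_true(igraph::identical_graphs(to_graph(load_design(f)),
                                         to_graph(net)))
  }
})

test_that("design loading rejects bad versions and malformed JSON", {
  f <- tempfile(fileext = ".json")
  save_design(network_source_reporter(), f)
  doc <- jsonlite::read_json(f)
  doc$format_version <- "99"
  jsonlite::write_json(doc, f, auto_unbox = TRUE)
  expect_error(load_design(f), "format_version")
  writeLines("{not json", f)
  expect_error(load_design(f), "malformed")
  # hand-written minimal design loads and validates
  minimal <- tempfile(fileext = ".json")
  writeLines('{
    "format_version": "1.0", "name": "mini",
    "products": [{"name": "GFP", "kind": "reporter",
                  "degradation_rate": 1, "init_concentration": 0,
                  "signal_id": "GFP"}],
    "operators": [{"name": "c", "kind": "source", "inputs": [],
                   "outputs": ["GFP"], "params": {"alpha": 3}}]
  }', minimal)
  net <- load_design(minimal)
  expect_length(validate_network(net), 0)
  expect_equal(net$operators[[1]]$params$alpha, 3)
})

test_that("SBOL-style documents obey the structural mapping rules", {
  # 1 NOT operator + regulator + reporter: one unit, one production
  # interaction per output, one inhibition
  net <- genetic_network(
    "not1",
    list(regulator("R", 1, 1), reporter("P", 1, 0, signal_id = "P")),
    list(op_source("cR", "R", 2),
         op_hill1("gate", "R", "P", alpha0 = 10, alpha1 = 0.1,
                  K = 1, n = 2)))
  doc <- to_sbol(net)
  units <- Filter(function(c) identical(c$type, "DNA"), doc$components)
  expect_length(units, 2)
  itypes <- vapply(doc$interactions, `[[`, character(1), "type")
  expect_equal(sum(itypes == "Inhibition"), 1)
  expect_equal(sum(itypes == "GeneticProduction"), 2)
  # oscillator: 3 units, 6 production interactions, model reference
  osc <- to_sbol(network_oscillator())
  ot <- vapply(osc$interactions, `[[`, character(1), "type")
  expect_equal(sum(vapply(osc$components, function(c)
    identical(c$type, "DNA"), logical(1))), 3)
  expect_gte(sum(ot == "GeneticProduction"), 6)
  expect_named(osc$model, c("source", "language", "framework"))
  for (nm in names(fixture_nets()))
    expect_length(validate_sbol(to_sbol(fixture_nets()[[nm]])), 0)
  # serialization
  f <- tempfile(fileext = ".json")
  write_sbol(osc, f)
  expect_true(jsonlite::validate(paste(readLines(f), collapse = "\n")))
})

test_that("regulatory interaction direction follows the parameter signs", {
  osc <- network_oscillator()
  doc <- to_sbol(osc)
  regs <- Filter(function(i) i$type %in% c("Inhibition", "Stimulation"),
                 doc$interactions)
  dir <- vapply(regs, function(i)
    paste(i$participants$regulator, i$type), character(1))
  expect_setequal(dir, c("A Stimulation", "C Inhibition",
                         "A Stimulation", "B Stimulation"))
  # a tied operator warns and defaults to stimulation
  tied <- genetic_network(
    "tie",
    list(regulator("R", 1, 0), reporter("P", 1, 0, signal_id = "P")),
    list(op_source("c", "R", 1),
         op_hill1("g", "R", "P", alpha0 = 2, alpha1 = 2, K = 1, n = 1)))
  expect_warning(dt <- to_sbol(tied), "tie")
  tt <- Filter(function(i) i$type %in% c("Inhibition", "Stimulation"),
               dt$interactions)
  expect_identical(tt[[1]]$type, "Stimulation")
})

test_that("the CLI dispatches simulate, export and validate", {
  dir <- tempfile("cli")
  dir.create(dir)
  dpath <- file.path(dir, "design.json")
  save_design(network_receiver(), dpath)
  spec <- list(design = "design.json",
               growth = list(kind = "constant",
                             params = list(mu0 = 0.5), duration = 24),
               supplements = list(list(AHL = 0), list(AHL = 10)),
               duration = 4, interval = 1, method = "ode")
  apath <- file.path(dir, "assay.json")
  jsonlite::write_json(spec, apath, auto_unbox = TRUE)
  out <- file.path(dir, "m.csv")
  expect_equal(cli_main(c("simulate", "--assay", apath, "--out", out)), 0L)
  tab <- read_measurements(out)
  expect_setequal(unique(tab$signal), c("biomass", "YFP"))
  g1 <- file.path(dir, "net.dot")
  expect_equal(cli_main(c("export", "--format", "dot", "--design", dpath,
                          "--out", g1)), 0L)
  expect_true(file.exists(g1))
  expect_output(expect_equal(
    cli_main(c("validate", "--design", dpath)), 0L), "OK")
})
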