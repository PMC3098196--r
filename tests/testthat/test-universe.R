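test_that("map-formula lines parse, normalize and merge", {
  u <- parse_mapformula("R00001: 00010: C00001 + C00002 => C00003")
  expect_equal(u$id, "R00001")
  expect_false(u$reversible)
  expect_setequal(u$substrates[[1]], c("C00001", "C00002"))
  expect_equal(u$products[[1]], "C00003")

  # same id observed in both directions on two maps -> one reversible rxn
  u2 <- parse_mapformula(c(
    "R00002: 00010: C00001 => C00005",
    "R00002: 00020: C00005 <= C00001",
    "R00002: 00030: C00001 <=> C00005"
  ))
  expect_equal(length(u2$id), 1L)
  expect_true(u2$reversible)
  expect_equal(u2$substrates[[1]], "C00001")

  # stoichiometric coefficients are ignored, duplicates collapse
  u3 <- parse_mapformula("R00003: 00010: 2 C00001 => C00004 + C00004")
  expect_equal(u3$substrates[[1]], "C00001")
  expect_equal(u3$products[[1]], "C00004")

  expect_equal(length(parse_mapformula(character())$id), 0L)
  expect_error(parse_mapformula("not a reaction line"), "line 1")
  expect_error(parse_mapformula("R1: 00010: C00001 -> C00002"), "line 1")
})

test_that("normalization removes vacuous metabolites and empty reactions", {
  u <- metabolic_universe(
    c("a", "b"),
    substrates = list(c("A", "B"), "C"),
    products = list(c("B", "T"), "C2"),
    reversible = c(FALSE, FALSE)
  )
  expect_equal(u$substrates[[1]], "A")  # B was on both sides
  expect_setequal(u$products[[1]], c("B", "T"))
  u2 <- metabolic_universe("x", list("A"), list("A"), FALSE)
  expect_equal(length(u2$id), 0L)
  expect_equal(attr(u2, "dropped"), "x")
})

test_that("universe TSV round-trips exactly", {
  set.seed(10)
  u <- random_toy_universe(20)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_universe(u, f)
  u2 <- read_universe(f)
  expect_equal(u2$id, u$id)
  expect_equal(u2$substrates, u$substrates)
  expect_equal(u2$products, u$products)
  expect_equal(u2$reversible, u$reversible)
})

test_that("currency removal deletes metabolites and drops emptied reactions", {
  u <- parse_mapformula(c(
    "R1: 00: C00001 + X1 => X2",
    "R2: 00: C00001 => X3",
    "R3: 00: X2 => X4 + C00001"
  ))
  out <- remove_currency(u, "C00001")
  rep <- attr(out, "removal_report")
  expect_equal(rep$removed_metabolites, "C00001")
  expect_equal(rep$dropped_reactions, "R2")  # substrate side emptied
  expect_equal(out$id, c("R1", "R3"))
  expect_false("C00001" %in% out$metabolites)
  # empty currency list and no threshold is the identity
  same <- remove_currency(u)
  expect_equal(same$id, u$id)
  expect_equal(same$substrates, u$substrates)
  # degree threshold removes hubs
  hub <- remove_currency(u, degree_threshold = 2)
  expect_false("C00001" %in% hub$metabolites)
})

test_that("simple-graph projection expands reaction hyperedges", {
  u <- metabolic_universe("r", list(c("A", "B")), list("C"), FALSE)
  g <- project_simple_graph(u)
  el <- apply(igraph::as_edgelist(g), 1, paste, collapse = ">")
  expect_setequal(el, c("A>C", "B>C"))

  ur <- metabolic_universe("r", list("A"), list("B"), TRUE)
  gr <- project_simple_graph(ur)
  el <- apply(igraph::as_edgelist(gr), 1, paste, collapse = ">")
  expect_setequal(el, c("A>B", "B>A"))

  g0 <- project_simple_graph(
    metabolic_universe(character(), list(), list(), logical()))
  expect_equal(igraph::vcount(g0), 0)
})

test_that("random spanning trees cover reachable nodes and obey the walk law", {
  # path graph b -> a -> root: unique spanning tree
  u <- parse_mapformula(c("R1: 00: b => a", "R2: 00: a => root"))
  g <- project_simple_graph(u)
  tr <- random_spanning_tree(g, "root", seed = 1)
  expect_equal(tr$n, 3L)
  expect_equal(max(tr$depth), 2L)
  expect_true(toolboxevo:::validate_layered_tree(tr, max_children = Inf))

  # star: k spokes each -> root
  us <- parse_mapformula(sprintf("R%d: 00: s%d => root", 1:5, 1:5))
  ts <- random_spanning_tree(project_simple_graph(us), "root", seed = 1)
  expect_equal(max(ts$depth), 1L)
  expect_equal(length(tree_leaves(ts)), 5L)

  # diamond b -> a -> root, b -> c -> root: by enumeration of the
  # self-avoiding walks, b attaches through a with probability 1/2
  ud <- parse_mapformula(c("R1: 00: b => a", "R2: 00: a => root",
                           "R3: 00: b => c", "R4: 00: c => root"))
  gd <- project_simple_graph(ud)
  set.seed(2)
  n_rep <- 600
  via_a <- replicate(n_rep, {
    t <- random_spanning_tree(gd, "root")
    bi <- match("b", t$names)
    t$names[t$parent[bi]] == "a"
  })
  f <- mean(via_a)
  expect_lte(abs(f - 0.5), 3.5 * sqrt(0.25 / n_rep))

  # unreachable nodes are excluded and reported
  ux <- parse_mapformula(c("R1: 00: b => a", "R2: 00: a => root",
                           "R3: 00: root => z"))
  tx <- random_spanning_tree(project_simple_graph(ux), "root", seed = 1)
  expect_equal(tx$excluded, "z")
  expect_error(random_spanning_tree(gd, "missing"), "not present")
})

test_that("shortest-path trees use true distances and report orphans", {
  u <- parse_mapformula(c("R1: 00: b => a", "R2: 00: a => root",
                          "R3: 00: b => c", "R4: 00: c => root",
                          "R5: 00: root => z"))
  g <- project_simple_graph(u)
  tr <- shortest_path_tree(g, "root", seed = 1)
  expect_equal(tr$excluded, "z")
  expect_equal(tr$depth[match("b", tr$names)], 2L)
  expect_equal(tr$depth[match(c("a", "c"), tr$names)], c(1L, 1L))
  # node-wise, shortest-path levels never exceed random-walk levels
  rw <- random_spanning_tree(g, "root", seed = 3)
  common <- intersect(tr$names, rw$names)
  expect_true(all(tr$depth[match(common, tr$names)] <=
                    rw$depth[match(common, rw$names)]))
})

test_that("synthetic universes are fully reachable from their seed", {
  u <- generate_synthetic_universe(n_metabolites = 300, n_layers = 12,
                                   seed = 21, seed_size = 20)
  ex <- expand_scope(u, attr(u, "seed_metabolites"))
  expect_setequal(ex$reached, u$metabolites)
  # layered construction: first production layer equals the design layer
  lo <- attr(u, "layer_of")
  fl <- ex$first_layer[names(lo)]
  expect_equal(unname(fl), unname(lo))
})

test_that("forcing (1,1) multiplicities degenerates to plain reachability", {
  w <- list(irreversible = matrix(1), reversible = matrix(1))
  u <- generate_synthetic_universe(n_metabolites = 120, n_layers = 8,
                                   multiplicity_weights = w,
                                   reversibility_fraction = 0,
                                   seed = 5, seed_size = 10,
                                   currency_size = 0)
  expect_true(all(lengths(u$substrates) == 1))
  expect_true(all(lengths(u$products) == 1))
  ex <- expand_scope(u, attr(u, "seed_metabolites"))
  g <- project_simple_graph(u)
  d <- igraph::distances(g, v = attr(u, "seed_metabolites"),
                         to = igraph::V(g), mode = "out")
  bfs_level <- apply(d, 2, min)
  fl <- ex$first_layer[names(bfs_level)]
  expect_equal(unname(fl), unname(as.integer(bfs_level)))
})

test_that("generated multiplicities follow the requested weights", {
  u <- generate_synthetic_universe(n_metabolites = 2500, n_layers = 25,
                                   seed = 31, reversibility_fraction = 0)
  w <- kegg_multiplicity_tables()$irreversible
  ns <- lengths(u$substrates)
  np <- lengths(u$products)
  obs <- table(factor(ns, 1:5), factor(np, 1:5))
  keep <- w > 0
  expect_gt(
    chisq.test(as.vector(obs[keep]), p = as.vector(w[keep]) / sum(w[keep]),
               simulate.p.value = TRUE, B = 2000)$p.value,
    0.001
  )
})

test_that("infeasible generator settings error out", {
  expect_error(generate_synthetic_universe(50, 0), "n_layers")
  expect_error(generate_synthetic_universe(50, 5, seed_size = 50), "seed_size")
  expect_error(generate_synthetic_universe(50, 5, seed_size = 10,
                                           currency_size = 11), "currency")
})
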