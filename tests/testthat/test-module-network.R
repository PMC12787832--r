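triangle_net <- function() {
  interaction_network(data.frame(from = c("a", "a", "b"),
                                 to = c("b", "c", "c")))
}

expect_module_network_equal <- function(a, b) {
  expect_identical(a$modules, b$modules)
  expect_identical(a$edges, b$edges)
  expect_identical(a$self_support, b$self_support)
  expect_identical(a$degree, b$degree)
  expect_identical(a$dropped_edges, b$dropped_edges)
}

test_that("module assignment policies resolve multi-pathway nodes deterministically", {
  sets <- gene_sets(list(
    Map04626 = c("n1", "n2", "n3", "n4"),
    Map00941 = c("n2", "n5")))
  asg <- assign_modules(c("n1", "n2", "n9"), sets, "unique_lexicographic")
  expect_equal(asg$mapping[["n1"]], "Map04626")
  # "Map00941" < "Map04626" lexicographically
  expect_equal(asg$mapping[["n2"]], "Map00941")
  expect_equal(asg$unassigned, "n9")
  expect_false("n9" %in% names(asg$mapping))

  asg_small <- assign_modules("n2", sets, "unique_smallest_set")
  expect_equal(asg_small$mapping[["n2"]], "Map00941")  # 2 < 4 members

  sets_tie <- gene_sets(list(B = c("n2", "x"), A = c("n2", "y")))
  asg_tie <- assign_modules("n2", sets_tie, "unique_smallest_set")
  expect_equal(asg_tie$mapping[["n2"]], "A")

  asg_multi <- assign_modules("n2", sets, "multi")
  expect_equal(sort(asg_multi$mapping[["n2"]]), c("Map00941", "Map04626"))
})

test_that("contraction collapses node edges into weighted module edges", {
  net <- interaction_network(data.frame(
    from = c("a", "b", "a"), to = c("c", "d", "b"),
    stringsAsFactors = FALSE))
  sets <- gene_sets(list(M1 = c("a", "b"), M2 = c("c", "d")))
  asg <- assign_modules(net$nodes, sets, "unique_lexicographic")
  mn <- contract(net, asg)
  expect_equal(nrow(mn$edges), 1)
  expect_equal(mn$edges$weight, 2L)
  expect_equal(unname(mn$self_support["M1"]), 1L)
  expect_equal(unname(mn$self_support["M2"]), 0L)
  expect_equal(unname(mn$degree[c("M1", "M2")]), c(1L, 1L))
  expect_module_network_equal(mn, contraction_oracle(net, asg))
})

test_that("degenerate contractions behave as expected", {
  # all nodes in one module: no module edges, self-support = edge count
  net <- triangle_net()
  one <- assign_modules(net$nodes, gene_sets(list(M = net$nodes)),
                        "unique_lexicographic")
  mn1 <- contract(net, one)
  expect_equal(nrow(mn1$edges), 0)
  expect_equal(unname(mn1$self_support["M"]), 3L)
  expect_equal(unname(mn1$degree["M"]), 0L)

  # bijective assignment: module network isomorphic to the node network
  bij <- assign_modules(net$nodes, gene_sets(list(
    Ma = "a", Mb = "b", Mc = "c")), "unique_lexicographic")
  mn2 <- contract(net, bij)
  expect_equal(nrow(mn2$edges), 3)
  expect_true(all(mn2$edges$weight == 1L))
  expect_true(all(mn2$degree == 2L))

  # empty network
  mn0 <- contract(interaction_network(), assign_modules(
    character(0), gene_sets(list(M = "a")), "unique_lexicographic"))
  expect_equal(length(mn0$modules), 0)
  expect_equal(nrow(mn0$edges), 0)

  # edges touching unannotated nodes are dropped but counted
  nsets <- gene_sets(list(M1 = "a", M2 = "b"))
  asg <- assign_modules(net$nodes, nsets, "unique_lexicographic")
  mn3 <- contract(net, asg)
  expect_equal(mn3$dropped_edges, 2L)
  expect_equal(nrow(mn3$edges), 1)
})

test_that("multi-policy contraction counts ordered pathway combinations", {
  net <- interaction_network(data.frame(from = "u", to = "v"))
  sets <- gene_sets(list(A = c("u", "v"), B = c("u", "v")))
  asg <- assign_modules(net$nodes, sets, "multi")
  mn <- contract(net, asg)
  # one node edge, both endpoints in {A, B}: A-B supported twice,
  # self-support 1 for each of A and B
  expect_equal(mn$edges$weight, 2L)
  expect_equal(unname(mn$self_support[c("A", "B")]), c(1L, 1L))
  expect_module_network_equal(mn, contraction_oracle(net, asg))
})

test_that("contraction equals the brute-force oracle on random instances", {
  for (seed in 1:15) {
    policy <- c("unique_lexicographic", "unique_smallest_set",
                "multi")[(seed %% 3) + 1]
    inst <- random_instance(n_nodes = 40, n_modules = 5, edge_p = 0.12,
                            policy = policy, seed = seed)
    mn <- contract(inst$net, inst$assignment)
    expect_module_network_equal(mn, contraction_oracle(inst$net,
                                                       inst$assignment))
    # conservation in unique modes; degree handshake always
    if (policy != "multi") {
      expect_equal(sum(mn$edges$weight) + sum(mn$self_support) +
                     mn$dropped_edges, nrow(inst$net$edges))
    }
    expect_equal(sum(mn$degree), 2 * nrow(mn$edges))
  }
})

test_that("contraction is invariant to node and edge input order", {
  inst <- random_instance(n_nodes = 30, n_modules = 4, seed = 99)
  mn <- contract(inst$net, inst$assignment)
  set.seed(1)
  e <- inst$net$edges[sample(nrow(inst$net$edges)), ]
  swap <- seq_len(nrow(e)) %% 2 == 0
  tmp <- e$from[swap]; e$from[swap] <- e$to[swap]; e$to[swap] <- tmp
  net2 <- interaction_network(e, nodes = rev(inst$net$nodes))
  asg2 <- inst$assignment
  asg2$mapping <- asg2$mapping[rev(names(asg2$mapping))]
  expect_module_network_equal(mn, contract(net2, asg2))
})

test_that("adding a node edge never decreases any module's degree", {
  set.seed(7)
  inst <- random_instance(n_nodes = 30, n_modules = 4, edge_p = 0.08,
                          seed = 7)
  mn <- contract(inst$net, inst$assignment)
  nodes <- inst$net$nodes
  key <- paste(inst$net$edges$from, inst$net$edges$to)
  for (i in 1:20) {
    cand <- sort(sample(nodes, 2))
    if (paste(cand[1], cand[2]) %in% key) next
    e2 <- rbind(inst$net$edges,
                data.frame(from = cand[1], to = cand[2], score = NA_real_))
    mn2 <- contract(interaction_network(e2, nodes = nodes),
                    inst$assignment)
    common <- intersect(names(mn$degree), names(mn2$degree))
    expect_true(all(mn2$degree[common] >= mn$degree[common]))
  }
})

test_that("module ranking orders by connectivity with lexicographic tie-breaks", {
  # star of modules: center first
  net <- interaction_network(data.frame(
    from = c("c1", "c2", "c3", "c4"), to = c("h1", "h2", "h3", "h4")))
  sets <- gene_sets(list(Center = paste0("c", 1:4),
                         L1 = "h1", L2 = "h2", L3 = "h3", L4 = "h4"))
  mn <- contract(net, assign_modules(net$nodes, sets,
                                     "unique_lexicographic"))
  rk <- rank_modules(mn, "degree")
  expect_equal(rk$module[1], "Center")
  expect_equal(rk$value[1], 4)

  # cycle of equal-degree modules: ties broken by module id
  cyc <- interaction_network(data.frame(
    from = c("a", "b", "c", "a"), to = c("b", "c", "d", "d")))
  bij <- assign_modules(cyc$nodes, gene_sets(list(
    Mb = "a", Ma = "b", Md = "c", Mc = "d")), "unique_lexicographic")
  rk2 <- rank_modules(contract(cyc, bij), "degree")
  expect_equal(rk2$module, c("Ma", "Mb", "Mc", "Md"))
  expect_true(all(rk2$value == 2))

  # weighted and unweighted rankings can disagree: one heavy neighbour
  # (weight 10) vs four light neighbours (weight 1 each)
  net3 <- interaction_network(data.frame(
    from = c(rep("a1", 10), "b1", "b2", "b3", "b4"),
    to = c(paste0("x", 1:10), paste0("y", 1:4))))
  sets3 <- gene_sets(c(list(Wide = paste0("b", 1:4), Deep = "a1",
                            X = paste0("x", 1:10)),
                       stats::setNames(as.list(paste0("y", 1:4)),
                                       paste0("Y", 1:4))))
  mn3 <- contract(net3, assign_modules(net3$nodes, sets3,
                                       "unique_lexicographic"))
  unw <- rank_modules(mn3, "degree")
  wt <- rank_modules(mn3, "weighted_degree")
  expect_equal(unw$module[1], "Wide")
  expect_equal(unw$value[1], 4)
  expect_equal(wt$module[1], "Deep")
  expect_equal(wt$value[1], 10)
})

test_that("module networks round-trip their edge and degree tables to TSV", {
  inst <- random_instance(n_nodes = 25, n_modules = 4, seed = 12)
  mn <- contract(inst$net, inst$assignment)
  ep <- tempfile(fileext = ".tsv"); dp <- tempfile(fileext = ".tsv")
  write_module_network(mn, ep, dp)
  e <- read_tsv(ep); d <- read_tsv(dp)
  expect_equal(nrow(e), nrow(mn$edges))
  expect_equal(sum(d$degree), 2 * nrow(mn$edges))
  expect_equal(stats::setNames(d$self_support, d$module)[names(mn$self_support)],
               mn$self_support, ignore_attr = TRUE)
  unlink(c(ep, dp))
})
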