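# Gene interaction hierarchy: induced GOI subnetwork, direct-connection
# counts, tier assignment, and the assembled table.

test_that("inducing the GOI subnetwork keeps only within-GOI edges", {
  nw <- interaction_network(rbind(c("A", "B"), c("B", "D")))
  sub <- suppressMessages(induce_goi_network(nw, c("A", "B", "C")))
  expect_setequal(network_nodes(sub), c("A", "B", "C"))
  expect_equal(network_edges(sub), cbind("A", "B"), ignore_attr = TRUE)
  expect_equal(connection_count(sub, "C"), 0)

  all_iso <- induce_goi_network(nw, c("A", "B", "D"))
  expect_equal(nrow(network_edges(all_iso)), 3 - 1)  # A-B and B-D kept

  disjoint <- suppressMessages(induce_goi_network(nw, c("X", "Y")))
  expect_equal(nrow(network_edges(disjoint)), 0)
})

test_that("induced subnetworks match a brute-force edge filter on random graphs", {
  set.seed(901)
  nodes <- sprintf("N%02d", 1:40)
  edges <- unique(t(replicate(120, sort(sample(nodes, 2)))))
  nw <- interaction_network(edges)
  goi <- sample(nodes, 18)
  sub <- suppressMessages(induce_goi_network(nw, goi))
  expect_identical(network_edges(sub), oracle_induced_edges(edges, goi))
})

test_that("connection counts are deduplicated distinct-neighbour degrees", {
  star <- interaction_network(cbind("JAK2", sprintf("L%02d", 1:15)))
  expect_equal(connection_count(star, "JAK2"), 15)
  expect_equal(connection_count(star, "L01"), 1)

  dup <- interaction_network(rbind(c("A", "B"), c("B", "A"), c("A", "B")))
  expect_equal(connection_count(dup, "A"), 1)

  iso <- interaction_network(nodes = "Z")
  expect_equal(connection_count(iso, "Z"), 0)
  expect_error(connection_count(iso, "Q"), "not in the network")
})

test_that("tier assignment follows the >10 / 5-10 / <5 / 0 rule exactly", {
  expect_identical(as.character(assign_tier(c(15, 7, 11, 10, 5, 4, 1, 0))),
                   c("primary", "secondary", "primary", "secondary",
                     "secondary", "peripheral", "peripheral", "orphan"))
  expect_error(assign_tier(-1), "non-negative")
  # total and monotone over a range of counts
  tiers <- assign_tier(0:30)
  expect_false(anyNA(tiers))
  expect_true(all(diff(5 - as.integer(tiers)) >= 0))
})

test_that("the hierarchy recovers planted tiers on a noise-free synthetic network", {
  sim <- simulate_network(seed = 902)
  gih <- build_gih(sim$network, sim$truth$symbol)
  expect_equal(attr(gih, "tier_totals"),
               c(primary = 20L, secondary = 34L, peripheral = 41L, orphan = 19L))
  expect_equal(attr(gih, "n_connected"), 95)
  m <- merge(as.data.frame(gih)[, c("symbol", "tier")], sim$truth,
             by = "symbol")
  expect_identical(as.character(m$tier.x), as.character(m$tier.y))
  # handshake lemma on the induced graph
  expect_equal(sum(gih$connection_count),
               2 * nrow(network_edges(sim$network)))
})

test_that("tier recovery degrades gracefully under edge rewiring", {
  recovery <- vapply(c(0, 0.3), function(p) {
    sim <- simulate_network(rewire_prob = p, seed = 903)
    gih <- build_gih(sim$network, sim$truth$symbol)
    m <- merge(as.data.frame(gih)[, c("symbol", "tier")], sim$truth,
               by = "symbol")
    mean(as.character(m$tier.x) == as.character(m$tier.y))
  }, numeric(1))
  expect_equal(recovery[1], 1)
  expect_true(recovery[2] >= 0 && recovery[2] <= 1)
})

test_that("removing an edge never increases a connection count", {
  sim <- simulate_network(tier_sizes = c(primary = 3, secondary = 6,
                                         peripheral = 8, orphan = 2),
                          degree_ranges = list(primary = c(11, 12),
                                               secondary = c(5, 7),
                                               peripheral = c(1, 4)),
                          seed = 904)
  goi <- sim$truth$symbol
  full <- build_gih(sim$network, goi)
  e <- network_edges(sim$network)
  smaller <- interaction_network(e[-1, , drop = FALSE], nodes = goi)
  reduced <- build_gih(smaller, goi)
  idx <- match(full$symbol, reduced$symbol)
  expect_true(all(reduced$connection_count[idx] <= full$connection_count))
})

test_that("annotations, fold changes, and layout order are joined deterministically", {
  nw <- interaction_network(rbind(c("A", "B"), c("A", "C"), c("B", "C")))
  ann <- data.frame(symbol = c("A", "B"),
                    compartment = c("nucleus", "extracellular space"),
                    molecule_type = c("transcription regulator", "cytokine"))
  fc <- data.frame(symbol = c("A", "C"), fc_ipsi = c(3.37, -2.5),
                   fc_contra = c(NA, 4))
  expect_warning(gih <- build_gih(nw, c("A", "B", "C", "D"),
                                  annotations = ann, fold_changes = fc),
                 "without annotation")
  expect_identical(gih$symbol, c("B", "A", "C", "D"))  # compartment order
  expect_identical(gih$compartment[gih$symbol == "C"], "unknown")
  expect_equal(gih$fc_ipsi[gih$symbol == "A"], 3.37)
  expect_true(is.na(gih$fc_contra[gih$symbol == "A"]))
  expect_identical(as.character(gih$tier), c("peripheral", "peripheral",
                                             "peripheral", "orphan"))
})

test_that("an all-isolated GOI set yields an all-orphan hierarchy", {
  nw <- interaction_network(rbind(c("X", "Y")))
  gih <- suppressMessages(build_gih(nw, c("P1", "P2", "P3")))
  expect_true(all(gih$tier == "orphan"))
  expect_equal(attr(gih, "n_connected"), 0)
})
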