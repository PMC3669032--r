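# Synthetic-data generators: determinism, validity, and ground-truth
# recovery by the pipeline.

test_that("the expression generator is deterministic and produces valid datasets", {
  a <- simulate_expression(n_genes = 120, seed = 42,
                           class_sizes = c("common-similar-up" = 10,
                                           "ipsi-unique-down" = 5))
  b <- simulate_expression(n_genes = 120, seed = 42,
                           class_sizes = c("common-similar-up" = 10,
                                           "ipsi-unique-down" = 5))
  expect_identical(a$dataset$signal, b$dataset$signal)
  expect_identical(a$dataset$call, b$dataset$call)
  expect_identical(a$truth, b$truth)
  # the constructor validated shape, calls, and groups; spot-check invariants
  expect_true(all(a$dataset$signal >= 0))
  expect_setequal(unique(as.vector(a$dataset$call)), c("P", "A"))
  expect_error(simulate_expression(n_genes = 10,
                                   class_sizes = c("common-different" = 50)),
               "class sizes")
  expect_error(simulate_expression(effect_range = c(1.5, 3)), "at least 2")
})

test_that("the zero-noise pipeline recovers every planted class exactly", {
  sim <- simulate_expression(noise_sd = 0, seed = 43)
  cls <- classify_bilateral(fold_change_records(sim$dataset))
  called <- as.character(cls$category[match(sim$truth$gene_id, cls$gene_id)])
  truth <- ifelse(sim$truth$class == "null", "unchanged", sim$truth$class)
  expect_identical(called, truth)  # diagonal confusion matrix
  # and the default class sizes reproduce the reported summary percentages
  s <- summarize_partition(cls)
  expect_equal(unname(s$percent[c("similar", "different", "similar_up",
                                  "similar_down", "ipsi_unique_up",
                                  "contra_unique_down")]),
               c(75, 25, 54, 21, 95, 74))
})

test_that("screening is near-perfect for >=3-fold effects at the default noise", {
  sim <- simulate_expression(seed = 44)  # noise_sd = 0.1
  rec <- fold_change_records(sim$dataset)
  for (side in c("TBI-I", "TBI-C")) {
    eff <- if (side == "TBI-I") sim$truth$effect_ipsi else sim$truth$effect_contra
    called <- sim$truth$gene_id %in% changed_genes(rec, side)
    strong <- abs(eff) >= 3
    expect_gte(sum(called & strong) / sum(strong), 0.95)          # recall
    truly_changed <- abs(eff) >= 2
    expect_gte(sum(called & truly_changed) / sum(called), 0.95)   # precision
  }
})

test_that("estimated effects converge to planted effects as noise shrinks", {
  mae <- vapply(c(0.3, 0.1, 0), function(sd) {
    sim <- simulate_expression(n_genes = 500, noise_sd = sd, seed = 45)
    rec <- fold_change_records(sim$dataset)
    idx <- match(sim$truth$gene_id, rec$gene_id)
    mean(abs(log2(abs(rec$fc_ipsi[idx])) * sign(rec$fc_ipsi[idx]) -
             log2(abs(sim$truth$effect_ipsi)) * sign(sim$truth$effect_ipsi)))
  }, numeric(1))
  expect_true(all(diff(mae) < 0))
  expect_equal(mae[3], 0, tolerance = 1e-12)
})

test_that("generated datasets survive an I/O round-trip unchanged", {
  sim <- simulate_expression(n_genes = 40, seed = 46,
                             class_sizes = c("contra-unique-down" = 6))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_table(sim$dataset, path)
  back <- read_expression_table(path, sim$dataset$groups)
  expect_equal(back$signal, sim$dataset$signal, tolerance = 1e-12)
})

test_that("the network generator realizes tiered degree sequences exactly", {
  sim <- simulate_network(seed = 47)
  deg <- igraph::degree(sim$network$graph)
  expect_equal(sum(deg) %% 2, 0)  # handshake: even degree total
  truth_deg <- setNames(sim$truth$degree, sim$truth$symbol)
  expect_equal(deg[names(truth_deg)], truth_deg)
  expect_identical(as.character(assign_tier(deg[sim$truth$symbol])),
                   as.character(sim$truth$tier))
  # determinism
  sim2 <- simulate_network(seed = 47)
  expect_identical(network_edges(sim$network), network_edges(sim2$network))
  # the 95 non-orphan nodes form one interconnected component
  comp <- igraph::components(sim$network$graph)
  expect_equal(max(comp$csize), 95)
})

test_that("infeasible network configurations are rejected with guidance", {
  expect_error(simulate_network(tier_sizes = c(primary = 5, secondary = 0,
                                               peripheral = 0, orphan = 0),
                                degree_ranges = list(primary = c(11, 12),
                                                     secondary = c(5, 10),
                                                     peripheral = c(1, 4))),
               "degree reaches|not graphical")
  expect_error(simulate_network(degree_ranges = list(primary = c(8, 12),
                                                     secondary = c(5, 10),
                                                     peripheral = c(1, 4))),
               "inconsistent with the tier rule")
})
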