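# Hub calling, specificity index, active ratios, sigma_RF.

test_that("er_randomize keeps sizes, avoids self-loops/duplicates, saturates", {
  net <- er_randomize(10, 15, seed = 1)
  expect_equal(n_vertices(net), 10)
  expect_equal(n_arcs(net), 15)
  expect_false(any(net$arcs$source == net$arcs$target))
  expect_equal(anyDuplicated(paste(net$arcs$source, net$arcs$target)), 0L)
  full <- er_randomize(5, 20, seed = 2)
  expect_equal(n_arcs(full), 20)                # the complete loop-free digraph
  expect_equal(sort(unname(network_degrees(full, "in"))), rep(4L, 5))
  expect_error(er_randomize(5, 21), "ordered distinct")
})

test_that("er null vertex in-degree matches the binomial expectation", {
  set.seed(77)
  degs <- replicate(2000, {
    net <- er_randomize(10, 15)
    unname(network_degrees(net, "in")[["v1"]])
  })
  se <- sd(degs) / sqrt(2000)
  expect_lt(abs(mean(degs) - 1.5), 3 * se)
})

test_that("hub p-values behave at the extremes", {
  # degree-0 vertices can never beat the null
  nodes <- data.frame(gene_id = paste0("g", 1:20), role = rep("TF", 20))
  net <- regulatory_network(nodes, data.frame(source = "g1", target = "g2"),
                            label = "t")
  calls <- call_hubs(net, "in", n_random = 200, seed = 1)
  expect_true(all(calls$p_value[calls$observed_degree == 0] == 1))
  expect_false(any(calls$is_hub[calls$observed_degree == 0]))
  # a TRN with no arcs: everything has p = 1
  empty <- regulatory_network(nodes, NULL, label = "t")
  calls0 <- call_hubs(empty, "out", n_random = 150, seed = 2)
  expect_true(all(calls0$p_value == 1))
  expect_warning(call_hubs(net, "in", n_random = 50, seed = 3), "unstable")
})

test_that("a planted high-degree vertex is always called a hub", {
  # 200 vertices, 400 arcs: null mean in-degree 2; planted in-degree 50
  set.seed(5)
  ids <- paste0("g", 1:200)
  nodes <- data.frame(gene_id = ids, role = rep("TF", 200))
  feeders <- sample(ids[-1], 50)
  base <- er_randomize(200, 350, vertex_ids = ids)$arcs
  arcs <- unique(rbind(data.frame(source = feeders, target = "g1"), base))
  net <- regulatory_network(nodes, arcs, label = "t", check_roles = FALSE)
  calls <- call_hubs(net, "in", n_random = 500, seed = 6)
  expect_true(calls$is_hub[calls$gene_id == "g1"])
  expect_lt(calls$p_value[calls$gene_id == "g1"], 0.01)
})

test_that("specificity index has the stated boundary and interior values", {
  expect_identical(specificity_index(8, 1), 1)
  expect_identical(specificity_index(8, 8), 0)
  expect_equal(specificity_index(8, 5), 3 / 7)
  expect_error(specificity_index(8, 0), "undefined")
  expect_error(specificity_index(8, 9), "exceed")
  # bijection from n = 1..N onto N distinct values, monotone decreasing
  vals <- specificity_index(8, 1:8)
  expect_equal(length(unique(vals)), 8)
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("active ratio is the realized fraction of reference connections", {
  ids <- c(paste0("r", 1:10), "x")
  nodes <- data.frame(gene_id = ids, role = c(rep("TF", 10), "nonTF"))
  ref <- regulatory_network(nodes, data.frame(source = paste0("r", 1:10),
                                              target = "x"), label = "reference")
  trn <- build_trn(ref, c(paste0("r", 1:4), "x"), "t")
  expect_equal(active_ratio("x", "in", trn, ref), 0.4)
  expect_equal(active_ratio("x", "in", ref, ref), 1)
  trn0 <- build_trn(ref, paste0("r", 1:3), "t0")
  expect_equal(active_ratio("x", "in", trn0, ref), 0)
  expect_error(active_ratio("r1", "in", trn, ref), "undefined")
  tab <- active_ratio_table(ref, list(t = trn), "in")
  expect_equal(tab$active_ratio[tab$gene_id == "x"], 0.4)
})

test_that("strength classification is exhaustive and exclusive", {
  prof <- data.frame(n_expressed = c(5, 5, 5, 3), n_hub = c(5, 2, 0, 3))
  out <- classify_strength(prof)
  expect_equal(out$strength, c("strong", "weak", "non-hub", "strong"))
  expect_true(all(out$strength[out$n_hub > 0] %in% c("strong", "weak")))
})

test_that("hub profiles aggregate calls with SI per the linear form", {
  p <- generator_params(n_tf = 30, n_mirna = 15, n_nontf = 60, n_tissues = 4,
                        seed = 21)
  ref <- generate_reference(p)
  trns <- build_trns(ref, generate_expression(p, ref))
  calls <- call_hubs_tissues(trns, n_random = 200, seed = 22)
  prof <- hub_profiles(calls, trns)
  expect_true(all(prof$n_hub <= prof$n_expressed))
  expect_true(all(prof$n_expressed <= prof$n_tissues))
  hubs <- prof[prof$n_hub > 0, ]
  expect_equal(hubs$si, (4 - hubs$n_hub) / 3)
  expect_true(all(is.na(prof$si[prof$n_hub == 0])))
})

test_that("sigma_RF is zero when the permutation null cannot move", {
  # both TFs are hubs in both tissues: permuting hub labels changes nothing
  nodes <- data.frame(gene_id = c("a", "b", "c"), role = c("TF", "TF", "nonTF"))
  trn1 <- regulatory_network(nodes, data.frame(source = c("a", "b"),
                                               target = c("c", "c")), "t1")
  trns <- list(t1 = trn1, t2 = trn1)
  trns$t2$label <- "t2"
  calls <- data.frame(gene_id = rep(c("a", "b"), 2), role = "TF",
                      tissue = rep(c("t1", "t2"), each = 2),
                      direction = "out", observed_degree = 1,
                      p_value = 0.001, is_hub = TRUE)
  cur <- sigma_rf(calls, trns, "out", "TF", n_random = 50, seed = 1)
  expect_equal(cur$sigma_rf, rep(0, 2))
  expect_true(all(cur$sd_zero))
  expect_equal(sum(cur$rf_real), 1)
  expect_warning(sigma_rf(calls[0, ], trns, "out", "miRNA", n_random = 10),
                 "no miRNA")
})

test_that("shared planted hubs push sigma_RF positive at SI=0 and negative at SI=1", {
  signs_ok <- 0
  for (s in 1:10) {
    pl <- plant_spec(hubs = lapply(1:4, function(i)
      plant_hub("nonTF", "in", 35, tissues = 1:4)))
    p <- generator_params(n_tf = 40, n_mirna = 20, n_nontf = 90, n_tissues = 4,
                          mean_out_degree_tf = 4, mean_out_degree_mirna = 4,
                          seed = 100 + s)
    ref <- generate_reference(p, pl)
    trns <- build_trns(ref, generate_expression(p, ref))
    calls <- call_hubs_tissues(trns, directions = "in", n_random = 300,
                               seed = 200 + s)
    cur <- sigma_rf(calls, trns, "in", "nonTF", n_random = 200, seed = 300 + s,
                    mode = "difference")
    curz <- sigma_rf(calls, trns, "in", "nonTF", n_random = 200, seed = 300 + s)
    if (nrow(cur) && cur$sigma_rf[cur$si == 0] > 0 &&
        cur$sigma_rf[cur$si == 1] < 0 &&
        curz$sigma_rf[curz$si == 1] < 0)
      signs_ok <- signs_ok + 1
  }
  expect_gte(signs_ok, 9)
})
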