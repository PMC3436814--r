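# Colored triad census, signatures, switch randomization, motif calls.

random_adj3 <- function() {
  a <- matrix(rbinom(9, 1, 0.5), 3, 3)
  diag(a) <- 0
  a
}

test_that("triad signatures are invariant under vertex relabeling", {
  set.seed(31)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  for (i in 1:200) {
    roles <- sample(c("TF", "miRNA", "nonTF"), 3, replace = TRUE)
    a <- random_adj3()
    sigs <- vapply(perms, function(pm)
      triad_signature(roles[pm], a[pm, pm]), character(1))
    expect_equal(length(unique(sigs)), 1)
  }
})

test_that("ignoring colors there are exactly 13 connected directed triad classes", {
  sigs <- character(0)
  for (bits in 0:63) {
    a <- matrix(0L, 3, 3)
    ord <- rbind(c(1, 2), c(1, 3), c(2, 1), c(2, 3), c(3, 1), c(3, 2))
    a[ord] <- as.integer(intToBits(bits)[1:6])
    und <- (a | t(a))
    connected <- (und[1, 2] + und[1, 3] + und[2, 3]) >= 2
    if (connected)
      sigs <- c(sigs, triad_signature(rep("TF", 3), a))
  }
  expect_equal(length(unique(sigs)), 13)
})

test_that("the census equals brute-force triple enumeration on random networks", {
  cases <- list(c(8, 4, 8, 40), c(15, 5, 20, 120), c(20, 10, 20, 200))
  for (k in seq_along(cases)) {
    cs <- cases[[k]]
    net <- random_test_network(cs[1], cs[2], cs[3], cs[4], seed = 40 + k)
    expect_census_matches_oracle(net)
  }
  # and agrees with igraph's uncolored triad census on connected classes
  net <- random_test_network(15, 10, 25, 260, seed = 77)
  tc <- igraph::triad_census(network_to_igraph(net))
  expect_equal(sum(enumerate_triads(net)$stats$occurrence),
               sum(tc) - tc[1] - tc[2] - tc[3])
})

test_that("census edge cases: single triad, disconnected vertices", {
  nodes <- data.frame(gene_id = c("A", "B", "C"), role = c("TF", "TF", "nonTF"))
  net <- regulatory_network(nodes, data.frame(source = c("A", "A", "B"),
                                              target = c("B", "C", "C")), "t")
  out <- enumerate_triads(net)
  expect_equal(out$stats$occurrence, 1L)
  expect_equal(classify_structure(out$stats$signature), "FFL")
  iso <- regulatory_network(nodes, NULL, "t")
  expect_equal(nrow(enumerate_triads(iso)$stats), 0)
})

test_that("structural classes follow the loop definitions", {
  adj <- function(...) {
    a <- matrix(0L, 3, 3)
    for (e in list(...)) a[e[1], e[2]] <- 1L
    a
  }
  ffl <- triad_signature(rep("TF", 3), adj(c(1, 2), c(2, 3), c(1, 3)))
  expect_equal(classify_structure(ffl), "FFL")
  fbl <- triad_signature(rep("TF", 3), adj(c(1, 2), c(2, 3), c(3, 1)))
  expect_equal(classify_structure(fbl), "FBL")
  cmplx <- triad_signature(c("miRNA", "TF", "nonTF"),
                           adj(c(1, 2), c(2, 1), c(2, 3), c(1, 3)))
  expect_equal(classify_structure(cmplx), "CMPLX")
  chain <- triad_signature(rep("TF", 3), adj(c(1, 2), c(2, 3)))
  expect_equal(classify_structure(chain), "non-loop")
})

test_that("switch randomization preserves degrees and roles, and mixes", {
  net <- random_test_network(30, 15, 55, 500, seed = 50)
  frac_same <- numeric(20)
  for (s in 1:20) {
    rnd <- switch_randomize(net, n_swap_factor = 10, seed = 60 + s)
    expect_equal(network_degrees(rnd, "in"), network_degrees(net, "in"))
    expect_equal(network_degrees(rnd, "out"), network_degrees(net, "out"))
    expect_false(any(rnd$arcs$source == rnd$arcs$target))
    expect_equal(anyDuplicated(paste(rnd$arcs$source, rnd$arcs$target)), 0L)
    roles <- setNames(rnd$nodes$role, rnd$nodes$gene_id)
    expect_true(all(roles[rnd$arcs$source] %in% c("TF", "miRNA")))
    frac_same[s] <- mean(paste(rnd$arcs$source, rnd$arcs$target) %in%
                           paste(net$arcs$source, net$arcs$target))
  }
  expect_true(all(frac_same < 0.5))
  # reproducible from the seed
  expect_identical(switch_randomize(net, seed = 99)$arcs,
                   switch_randomize(net, seed = 99)$arcs)
})

test_that("motif significance applies the three criteria", {
  net <- random_test_network(25, 10, 35, 260, seed = 70)
  ms <- suppressWarnings(motif_significance(net, n_random = 80, seed = 71))
  expect_false(any(ms$significant[ms$occurrence <= 5]))
  expect_false(any(ms$significant[ms$p_value >= 0.05]))
  expect_false(any(ms$significant[ms$z_score <= 2.2]))
  expect_true(all(ms$p_value > 0 & ms$p_value <= 1))
  inst <- attr(ms, "instances")
  counted <- table(inst$signature)
  expect_equal(as.integer(counted[ms$signature]), ms$occurrence)
})

test_that("a rigid star network yields zero z-scores, flagged and insignificant", {
  # one TF feeding 8 targets: every switch is rejected, so the ensemble is
  # constant and equal to the observed counts
  nodes <- data.frame(gene_id = c("hub", paste0("t", 1:8)),
                      role = c("TF", rep("nonTF", 8)))
  star <- regulatory_network(nodes, data.frame(source = "hub",
                                               target = paste0("t", 1:8)), "t")
  ms <- suppressWarnings(motif_significance(star, n_random = 60, seed = 5))
  expect_true(all(ms$z_score == 0))
  expect_true(all(ms$sd_zero))
  expect_false(any(ms$significant))
  expect_true(any(ms$occurrence > 5))          # occurrence alone is not enough
})

test_that("CM/TS labels follow the all-vs-some rule", {
  mk <- function(sig, signif) data.frame(signature = sig, significant = signif)
  sigA <- "TF-TF-nonTF|110100"
  sigB <- "TF-miRNA-nonTF|110100"
  stats <- list(t1 = mk(c(sigA, sigB), c(TRUE, TRUE)),
                t2 = mk(c(sigA, sigB), c(TRUE, FALSE)),
                t3 = mk(sigA, TRUE))
  cat <- classify_cm_ts(stats)
  expect_equal(cat$label[cat$signature == sigA], "CM")
  expect_equal(cat$label[cat$signature == sigB], "TS")
  stats$t3$significant <- FALSE
  cat2 <- classify_cm_ts(stats)
  expect_equal(cat2$label[cat2$signature == sigA], "TS")
  none <- classify_cm_ts(list(t1 = mk(sigA, FALSE), t2 = mk(sigA, FALSE)))
  expect_equal(none$label, "none")
})

test_that("a planted enriched motif reaches significance", {
  ffl <- rbind(c(1, 2), c(1, 3), c(2, 3))
  hits <- 0
  for (s in 1:5) {
    pl <- plant_spec(motifs = list(
      plant_motif(c("TF", "TF", "nonTF"), ffl, n_instances = 25, tissues = 1)))
    p <- generator_params(n_tf = 120, n_mirna = 30, n_nontf = 150, n_tissues = 2,
                          mean_out_degree_tf = 4, mean_out_degree_mirna = 4,
                          seed = 400 + s)
    ref <- generate_reference(p, pl)
    trns <- build_trns(ref, generate_expression(p, ref))
    ms <- motif_significance(trns[[1]], n_random = 100, seed = 500 + s)
    a <- matrix(0L, 3, 3)
    a[ffl] <- 1L
    sig <- triad_signature(c("TF", "TF", "nonTF"), a)
    row <- ms[ms$signature == sig, ]
    if (nrow(row) == 1 && row$significant) hits <- hits + 1
  }
  expect_gte(hits, 4)
})
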