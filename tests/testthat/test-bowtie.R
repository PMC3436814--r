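# Bow-tie partition, composition, average degrees, permutation tests,
# size ratios and pattern labels.

test_that("partition_genes performs the core / non-core set algebra", {
  out <- partition_genes(c("A", "B", "C"), c("C", "D", "E"))
  expect_equal(out, list(core = "C", noncore_cm = c("A", "B"),
                         noncore_ts = c("D", "E")))
  # no TS instances (liver-like): everything is non-core CM
  out2 <- partition_genes(c("A", "B"), NULL)
  expect_equal(out2$core, character(0))
  expect_equal(out2$noncore_ts, character(0))
  expect_setequal(out2$noncore_cm, c("A", "B"))
  # identical gene sets: everything is core
  out3 <- partition_genes(c("A", "B"), c("B", "A"))
  expect_setequal(out3$core, c("A", "B"))
  expect_equal(length(out3$noncore_cm), 0)
  # instance triples as data.frames are unpacked to genes
  cm <- data.frame(g1 = "A", g2 = "B", g3 = "C")
  ts <- data.frame(g1 = "C", g2 = "D", g3 = "E")
  expect_equal(partition_genes(cm, ts)$core, "C")
})

test_that("partition matches brute-force set operations on random instance lists", {
  set.seed(80)
  for (i in 1:20) {
    genes <- paste0("g", 1:40)
    cm <- sample(genes, sample(0:25, 1))
    ts <- sample(genes, sample(0:25, 1))
    out <- partition_genes(cm, ts)
    expect_setequal(out$core, intersect(cm, ts))
    expect_setequal(out$noncore_cm, setdiff(cm, ts))
    expect_setequal(out$noncore_ts, setdiff(ts, cm))
    expect_equal(anyDuplicated(unlist(out)), 0L)
    expect_setequal(unlist(out), union(cm, ts))
  }
})

test_that("composition fractions sum to one and flag empty sets", {
  roles <- c(a = "TF", b = "TF", c = "nonTF", d = "miRNA")
  comp <- gene_set_composition(list(s = c("a", "b", "c", "d"), e = character(0)),
                               roles)
  s <- comp[comp$set == "s", ]
  expect_equal(s$fraction[s$role == "TF"], 0.5)
  expect_equal(s$fraction[s$role == "miRNA"], 0.25)
  expect_equal(s$fraction[s$role == "nonTF"], 0.25)
  expect_equal(sum(s$fraction), 1)
  expect_true(all(comp$empty[comp$set == "e"]))
})

test_that("average degree follows the source-set normalization (and variants)", {
  arcs <- data.frame(source = c("a", "b"), target = c("b", "c"))
  expect_equal(average_degree(c("a", "b", "c"), arcs = arcs), 2 / 3)
  expect_equal(average_degree(c("a", "b"), c("c"), arcs = arcs), 1 / 2)
  expect_equal(average_degree(c("x", "y"), arcs = arcs), 0)
  expect_error(average_degree(character(0), arcs = arcs), "empty")
  expect_equal(average_degree(c("a", "b", "c"), arcs = arcs,
                              normalization = "density"), 2 / 6)
  expect_equal(average_degree(c("a", "b"), "c", arcs = arcs,
                              normalization = "mean"), 1 / 1.5)
})

test_that("size ratios sum to one and hit the stated examples", {
  pt <- list(core = paste0("c", 1), noncore_cm = paste0("o", 1:7),
             noncore_ts = paste0("i", 1:2))
  sr <- size_ratios(pt)
  expect_equal(unname(sr), c(0.2, 0.1, 0.7))
  expect_equal(sum(sr), 1, tolerance = 1e-12)
  liver <- list(core = character(0), noncore_cm = paste0("o", 1:5),
                noncore_ts = character(0))
  expect_equal(unname(size_ratios(liver)), c(0, 0, 1))
  big <- list(core = paste0("c", 1:9), noncore_cm = paste0("o", 1:3),
              noncore_ts = paste0("i", 1:88))
  expect_equal(size_ratios(big)[["input"]], 0.88)
  expect_error(size_ratios(list(core = character(0), noncore_cm = character(0),
                                noncore_ts = character(0))), "undefined")
})

test_that("pattern classification follows the threshold rules", {
  sr <- function(i, c, o) c(input = i, core = c, output = o)
  expect_equal(classify_pattern(sr(0.15, 0.25, 0.60))$pattern, "output-dominated")
  expect_equal(classify_pattern(sr(0.45, 0.10, 0.45))$pattern, "symmetric")
  expect_equal(classify_pattern(sr(0.70, 0.20, 0.10))$pattern, "input-dominated")
  lv <- classify_pattern(sr(0, 0, 1))
  expect_equal(lv$pattern, "output-dominated")
  expect_true(lv$degenerate)
  kd <- classify_pattern(sr(1, 0, 0))
  expect_equal(kd$pattern, "input-dominated")
  expect_true(kd$degenerate)
  expect_equal(classify_pattern(sr(0.4, 0.35, 0.25))$pattern, "unclassified")
})

test_that("permutation p-values are valid and degenerate cases are ~1", {
  # all genes share one role: composition is constant under any relabeling
  ids <- paste0("g", 1:12)
  nodes <- data.frame(gene_id = ids, role = rep("TF", 12))
  set.seed(91)
  arcs <- data.frame(source = sample(ids, 20, TRUE), target = sample(ids, 20, TRUE))
  arcs <- unique(arcs[arcs$source != arcs$target, ])
  net <- regulatory_network(nodes, arcs, "t")
  part <- list(core = ids[1:4], noncore_cm = ids[5:8], noncore_ts = ids[9:12])
  res <- bowtie_permutation_test(part, net, n_random = 300, seed = 92)
  tf_comp <- res$composition[res$composition$role == "TF", ]
  expect_true(all(abs(tf_comp$p_high - 1) <= 1 / 301 + 1e-12))
  expect_true(all(abs(tf_comp$p_low - 1) <= 1 / 301 + 1e-12))
  ok <- !is.na(res$degree$p_high)
  expect_true(all(res$degree$p_high[ok] > 0 & res$degree$p_high[ok] <= 1))
  expect_true(all(res$degree$p_low[ok] > 0 & res$degree$p_low[ok] <= 1))
  expect_error(bowtie_permutation_test(list(core = "g1", noncore_cm = "g2",
                                            noncore_ts = character(0)), net),
               "at least 3")
})

test_that("planted input->core flow is detected as enriched", {
  pl <- plant_spec(bowtie = plant_bowtie(n_input = 20, n_core = 6, n_output = 10))
  p <- generator_params(n_tf = 30, n_mirna = 30, n_nontf = 40, n_tissues = 2,
                        seed = 95)
  ref <- generate_reference(p, pl)
  bw <- attr(ref, "plants")$bowtie
  bt <- bowtie_decompose(bw$cm_instances, bw$ts_instances, ref,
                         n_random = 400, seed = 96)
  expect_equal(length(bt$noncore_ts), 20)
  expect_equal(length(bt$core), 6)
  expect_equal(length(bt$noncore_cm), 10)
  # the planted input layer is all-miRNA
  comp <- bt$composition
  expect_equal(comp$fraction[comp$set == "input" & comp$role == "miRNA"], 1)
  dg <- bt$tests$degree
  expect_lt(dg$p_high[dg$from_layer == "input" & dg$to_layer == "core"], 0.05)
  expect_lt(dg$p_high[dg$from_layer == "core" & dg$to_layer == "output"], 0.05)
})

test_that("a tissue with no TS motifs degenerates to an output-only bow-tie", {
  ids <- c("t1", "t2", "n1", "n2")
  nodes <- data.frame(gene_id = ids, role = c("TF", "TF", "nonTF", "nonTF"))
  net <- regulatory_network(nodes, data.frame(source = c("t1", "t1", "t2"),
                                              target = c("t2", "n1", "n1")), "liver")
  cm <- data.frame(g1 = "t1", g2 = "t2", g3 = "n1")
  bt <- bowtie_decompose(cm, NULL, net, n_random = 100, seed = 97)
  expect_equal(bt$core, character(0))
  expect_equal(bt$noncore_ts, character(0))
  expect_equal(unname(bt$size_ratios), c(0, 0, 1))
  expect_equal(bt$pattern, "output-dominated")
  expect_true(bt$degenerate)
})
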