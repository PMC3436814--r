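# Independent brute-force oracles, kept deliberately separate from the
# package implementation: plain triple scans over adjacency matrices and a
# string-based triad canonicalization.

# adjacency matrix of a regulatory_network
oracle_adjacency <- function(net) {
  ids <- net$nodes$gene_id
  a <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(net$arcs))
    a[cbind(match(net$arcs$source, ids), match(net$arcs$target, ids))] <- 1L
  a
}

# string-based canonical key of a colored triad: minimum over the 6 vertex
# orderings of "role1/role2/role3:b1b2b3b4b5b6"
oracle_triad_key <- function(roles, adj) {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  keys <- vapply(perms, function(pm) {
    ord <- rbind(c(1, 2), c(1, 3), c(2, 1), c(2, 3), c(3, 1), c(3, 2))
    bits <- adj[cbind(pm[ord[, 1]], pm[ord[, 2]])]
    paste0(paste(roles[pm], collapse = "/"), ":", paste(bits, collapse = ""))
  }, character(1))
  min(keys)
}

# brute-force census: scan every unordered triple, keep weakly connected
# ones (>= 2 undirected edges among 3 vertices always form a connected
# graph), and key each by oracle_triad_key
oracle_census <- function(net) {
  ids <- net$nodes$gene_id
  n <- length(ids)
  if (n < 3) return(data.frame(key = character(), g1 = character(),
                               g2 = character(), g3 = character()))
  a <- oracle_adjacency(net)
  und <- (a | t(a)) * 1L
  tri <- utils::combn(n, 3)
  e <- und[cbind(tri[1, ], tri[2, ])] + und[cbind(tri[1, ], tri[3, ])] +
    und[cbind(tri[2, ], tri[3, ])]
  tri <- tri[, e >= 2, drop = FALSE]
  if (ncol(tri) == 0) return(data.frame(key = character(), g1 = character(),
                                        g2 = character(), g3 = character()))
  roles <- net$nodes$role
  key <- vapply(seq_len(ncol(tri)), function(c) {
    v <- tri[, c]
    oracle_triad_key(roles[v], a[v, v])
  }, character(1))
  data.frame(key = key, g1 = ids[tri[1, ]], g2 = ids[tri[2, ]],
             g3 = ids[tri[3, ]], stringsAsFactors = FALSE)
}

# random role-typed network for oracle comparisons: uniform arcs from
# regulator sources, duplicates excluded
random_test_network <- function(n_tf, n_mirna, n_nontf, n_arcs, seed,
                                label = "test") {
  set.seed(seed)
  ids <- c(sprintf("tf%03d", seq_len(n_tf)), sprintf("mir%03d", seq_len(n_mirna)),
           sprintf("ntf%03d", seq_len(n_nontf)))
  roles <- rep(c("TF", "miRNA", "nonTF"), c(n_tf, n_mirna, n_nontf))
  nodes <- data.frame(gene_id = ids, role = roles, stringsAsFactors = FALSE)
  reg <- ids[roles %in% c("TF", "miRNA")]
  pairs <- expand.grid(source = reg, target = ids, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  pick <- sample(nrow(pairs), min(n_arcs, nrow(pairs)))
  regulatory_network(nodes, pairs[pick, ], label = label)
}

# verify the package census against the oracle census on one network:
# same triples, and the signature grouping is the same partition
expect_census_matches_oracle <- function(net) {
  pkg <- enumerate_triads(net)
  ora <- oracle_census(net)
  trip_key <- function(d, cols) apply(d[, cols, drop = FALSE], 1, function(v)
    paste(sort(v), collapse = "|"))
  pk <- trip_key(pkg$instances, c("g1", "g2", "g3"))
  ok <- trip_key(ora, c("g1", "g2", "g3"))
  expect_setequal(pk, ok)
  m <- match(ok, pk)
  expect_false(anyNA(m))
  # grouping: oracle keys and package signatures induce the same partition
  pkg_sig <- pkg$instances$signature[m]
  expect_true(all(tapply(pkg_sig, ora$key, function(x) length(unique(x)) == 1)))
  expect_true(all(tapply(ora$key, pkg_sig, function(x) length(unique(x)) == 1)))
  # and identical per-class counts
  expect_equal(sort(as.integer(table(pkg_sig))), sort(as.integer(table(ora$key))))
  expect_equal(sum(pkg$stats$occurrence), nrow(ora))
}
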