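#' Construct a role-typed directed regulatory network
#'
#' The central container of the package: a directed graph over genes, each
#' carrying one of the roles `"TF"`, `"miRNA"` or `"nonTF"`. Regulation runs
#' along arcs from a regulator (TF or miRNA) to any target gene. Duplicate
#' arcs are collapsed with a warning (unions of several interaction
#' predictors naturally produce duplicates) and self-loops (autoregulation)
#' are dropped with a warning, so that real and randomized networks stay
#' comparable.
#'
#' @param nodes data.frame with columns `gene_id` (character, unique) and
#'   `role` (one of `"TF"`, `"miRNA"`, `"nonTF"`).
#' @param arcs data.frame with character columns `source` and `target`;
#'   both must be declared in `nodes`.
#' @param label short name for the network (e.g. `"reference"`, a tissue).
#' @param check_roles enforce that every arc source is a TF or miRNA.
#'   Disabled only for null-model networks whose arcs are placed without
#'   regard to roles.
#' @return An object of class `regulatory_network`: a list with elements
#'   `nodes`, `arcs` and `label`.
#' @export
regulatory_network <- function(nodes, arcs, label = "network", check_roles = TRUE) {
  stopifnot(is.data.frame(nodes), all(c("gene_id", "role") %in% names(nodes)))
  nodes <- data.frame(gene_id = as.character(nodes$gene_id),
                      role = as.character(nodes$role),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(nodes$gene_id))
    stop("duplicated gene_id in node table: ",
         paste(head(unique(nodes$gene_id[duplicated(nodes$gene_id)]), 5L), collapse = ", "))
  bad_role <- setdiff(unique(nodes$role), TRN_ROLES)
  if (length(bad_role))
    stop("unknown role(s): ", paste(bad_role, collapse = ", "),
         " (expected TF, miRNA or nonTF)")

  if (is.null(arcs) || nrow(as.data.frame(arcs)) == 0L) {
    arcs <- data.frame(source = character(), target = character(),
                       stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("source", "target") %in% names(arcs)))
    arcs <- data.frame(source = as.character(arcs$source),
                       target = as.character(arcs$target),
                       stringsAsFactors = FALSE)
  }
  missing_v <- setdiff(unique(c(arcs$source, arcs$target)), nodes$gene_id)
  if (length(missing_v))
    stop("arc endpoint(s) not declared as vertices: ",
         paste(head(missing_v, 10L), collapse = ", "))

  self <- arcs$source == arcs$target
  if (any(self)) {
    warning(sum(self), " self-loop(s) dropped from '", label, "'")
    arcs <- arcs[!self, , drop = FALSE]
  }
  dup <- duplicated(paste(arcs$source, arcs$target, sep = "\r"))
  if (any(dup)) {
    warning(sum(dup), " duplicate arc(s) collapsed in '", label, "'")
    arcs <- arcs[!dup, , drop = FALSE]
  }
  if (check_roles && nrow(arcs)) {
    src_role <- nodes$role[match(arcs$source, nodes$gene_id)]
    offenders <- unique(arcs$source[!src_role %in% TRN_REGULATOR_ROLES])
    if (length(offenders))
      stop("non-regulator (nonTF) arc source(s): ",
           paste(head(offenders, 10L), collapse = ", "))
  }
  rownames(nodes) <- NULL
  rownames(arcs) <- NULL
  structure(list(nodes = nodes, arcs = arcs, label = label),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  tab <- table(factor(x$nodes$role, levels = TRN_ROLES))
  cat("regulatory_network '", x$label, "': ",
      nrow(x$nodes), " vertices (", paste(tab, names(tab), collapse = ", "),
      "), ", nrow(x$arcs), " arcs\n", sep = "")
  invisible(x)
}

#' Number of vertices / arcs of a regulatory network
#' @param network a `regulatory_network`.
#' @return integer count.
#' @export
n_vertices <- function(network) nrow(network$nodes)

#' @rdname n_vertices
#' @export
n_arcs <- function(network) nrow(network$arcs)

# In- or out-degree of every vertex, as a named integer vector in node order.
network_degrees <- function(network, direction = c("in", "out")) {
  direction <- match.arg(direction)
  ids <- network$nodes$gene_id
  ends <- if (direction == "in") network$arcs$target else network$arcs$source
  setNames(tabulate(match(ends, ids), nbins = length(ids)), ids)
}

#' Build a tissue regulatory network (TRN) by expression filtering
#'
#' The TRN of a tissue is the subgraph of the reference network induced by
#' the genes expressed in that tissue: its vertices are the expressed genes
#' and its arcs are exactly the reference arcs with both endpoints
#' expressed. Roles are carried over unchanged.
#'
#' @param reference a `regulatory_network` (the reference network).
#' @param expressed character vector of expressed gene ids; must be a subset
#'   of the reference vertices.
#' @param label name for the resulting TRN (typically the tissue).
#' @return A `regulatory_network` restricted to the expressed genes.
#' @export
build_trn <- function(reference, expressed, label = "trn") {
  expressed <- unique(as.character(expressed))
  unknown <- setdiff(expressed, reference$nodes$gene_id)
  if (length(unknown))
    stop("expressed gene(s) absent from reference: ",
         paste(head(unknown, 10L), collapse = ", "))
  nodes <- reference$nodes[reference$nodes$gene_id %in% expressed, , drop = FALSE]
  keep <- reference$arcs$source %in% expressed & reference$arcs$target %in% expressed
  regulatory_network(nodes, reference$arcs[keep, , drop = FALSE], label = label)
}

#' Build the TRN of every tissue in an expression profile
#'
#' @param reference a `regulatory_network`.
#' @param profile an `expression_profile` (see [generate_expression()] or
#'   [read_expression_tsv()]).
#' @return Named list of `regulatory_network` objects, one per tissue.
#' @export
build_trns <- function(reference, profile) {
  stopifnot(inherits(profile, "expression_profile"))
  setNames(lapply(profile$tissues, function(t)
    build_trn(reference, profile$expressed[[t]], label = t)), profile$tissues)
}

#' Per-vertex degree table of a network
#'
#' One row per vertex with its in- and out-degree; the `tissue` column
#' carries the network label so tables from several TRNs can be stacked.
#'
#' @param network a `regulatory_network`.
#' @return data.frame with columns `gene_id`, `role`, `tissue`,
#'   `in_degree`, `out_degree`.
#' @export
degree_table <- function(network) {
  data.frame(gene_id = network$nodes$gene_id,
             role = network$nodes$role,
             tissue = rep(network$label, nrow(network$nodes)),
             in_degree = unname(network_degrees(network, "in")),
             out_degree = unname(network_degrees(network, "out")),
             stringsAsFactors = FALSE)
}

#' Inverse cumulative degree distribution
#'
#' For each observed degree value k, the fraction of vertices with degree
#' >= k — the standard display for heavy-tailed degree distributions.
#'
#' @param degrees non-empty vector of non-negative integer degrees.
#' @return data.frame with columns `degree` and `fraction`, non-increasing
#'   in `degree`; the fraction at the minimum observed degree is 1.
#' @export
inverse_cumulative_distribution <- function(degrees) {
  if (length(degrees) == 0L) stop("empty degree list")
  stopifnot(all(degrees >= 0))
  ks <- sort(unique(degrees))
  data.frame(degree = ks,
             fraction = vapply(ks, function(k) mean(degrees >= k), numeric(1)))
}

# ---- file formats -----------------------------------------------------------

#' Read / write a regulatory network as TSV node and arc tables
#'
#' Node table: columns `gene_id`, `role`. Arc table: columns `source`,
#' `target`. Duplicate arcs are collapsed and self-loops dropped with a
#' warning on read.
#'
#' @param nodes_path,arcs_path paths of the node and arc TSV files.
#' @param label network label.
#' @return `read_network_tsv()` returns a `regulatory_network`;
#'   `write_network_tsv()` returns the network invisibly.
#' @export
read_network_tsv <- function(nodes_path, arcs_path, label = "network") {
  nodes <- read.delim(nodes_path, colClasses = "character")
  arcs <- read.delim(arcs_path, colClasses = "character")
  regulatory_network(nodes, arcs, label = label)
}

#' @rdname read_network_tsv
#' @param network a `regulatory_network`.
#' @export
write_network_tsv <- function(network, nodes_path, arcs_path) {
  write.table(network$nodes, nodes_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(network$arcs, arcs_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(network)
}

#' Convert a regulatory network to an igraph object
#'
#' Vertices carry a `role` attribute; useful for plotting, GraphML export
#' and cross-checks against igraph's graph algorithms.
#'
#' @param network a `regulatory_network`.
#' @return A directed `igraph` graph.
#' @export
network_to_igraph <- function(network) {
  igraph::graph_from_data_frame(network$arcs, directed = TRUE,
                                vertices = network$nodes)
}

#' Export a regulatory network to GraphML
#'
#' @param network a `regulatory_network`.
#' @param path output file path.
#' @return The network, invisibly.
#' @export
write_graphml <- function(network, path) {
  igraph::write_graph(network_to_igraph(network), path, format = "graphml")
  invisible(network)
}
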