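# Hub identification against Erdos-Renyi random ensembles, the tissue
# specificity index, strong/weak hub classification, and sigma_RF curves
# against degree-redistribution nulls.

# sample m distinct ordered vertex pairs uniformly among n*(n-1); shared by
# er_randomize and the hub-calling null so both use the same distribution
er_sample_pairs <- function(n, m) {
  M <- as.double(n) * (n - 1)
  if (m > M) stop("n_arcs exceeds the ", M, " ordered distinct vertex pairs")
  if (m == 0) return(cbind(integer(0), integer(0)))
  idx <- sample.int(M, m)
  s <- ceiling(idx / (n - 1))
  r <- idx - (s - 1) * (n - 1)
  t <- r + (r >= s)
  cbind(as.integer(s), as.integer(t))
}

#' Erdos-Renyi style randomization of a network
#'
#' Keeps the number of vertices and arcs but redistributes the arcs
#' uniformly among distinct ordered vertex pairs (no self-loops, no
#' duplicates). Roles play no part in arc placement, so the result is built
#' without the regulator-source constraint.
#'
#' @param n_vertices,n_arcs size of the random network;
#'   `n_arcs <= n_vertices * (n_vertices - 1)`.
#' @param seed optional integer seed.
#' @param vertex_ids optional vertex names (defaults to `v1..vn`).
#' @param roles optional roles to carry along (not used in arc placement).
#' @return A `regulatory_network` labelled `"er_random"`.
#' @export
er_randomize <- function(n_vertices, n_arcs, seed = NULL, vertex_ids = NULL,
                         roles = NULL) {
  stopifnot(n_vertices >= 2)
  if (!is.null(seed)) set.seed(seed)
  ids <- vertex_ids %||% paste0("v", seq_len(n_vertices))
  stopifnot(length(ids) == n_vertices)
  p <- er_sample_pairs(n_vertices, n_arcs)
  nodes <- data.frame(gene_id = ids,
                      role = roles %||% rep("TF", n_vertices),
                      stringsAsFactors = FALSE)
  regulatory_network(nodes,
                     data.frame(source = ids[p[, 1]], target = ids[p[, 2]],
                                stringsAsFactors = FALSE),
                     label = "er_random", check_roles = FALSE)
}

#' Call in-/out-hubs of a TRN against a random-network ensemble
#'
#' For every vertex, an empirical one-sided P-value is computed as the
#' add-one estimator `(1 + #{replicates with degree >= observed}) /
#' (1 + n_random)` over an ensemble of equivalent random networks with the
#' same vertex and arc counts; a vertex is a hub when `p_value < alpha`.
#'
#' @param trn a non-empty `regulatory_network`.
#' @param direction `"in"` or `"out"`.
#' @param n_random ensemble size (default 2000).
#' @param alpha hub significance level (default 0.01).
#' @param seed optional integer seed.
#' @param null `"er"` (default; arcs among all distinct ordered pairs) or
#'   `"role"` (sources restricted to TF/miRNA vertices — a role-preserving
#'   sensitivity variant).
#' @return data.frame with columns `gene_id`, `role`, `tissue`,
#'   `direction`, `observed_degree`, `p_value`, `is_hub`.
#' @export
call_hubs <- function(trn, direction = c("in", "out"), n_random = 2000,
                      alpha = 0.01, seed = NULL, null = c("er", "role")) {
  stopifnot(inherits(trn, "regulatory_network"))
  direction <- match.arg(direction)
  null <- match.arg(null)
  if (n_vertices(trn) < 2) stop("TRN must have at least 2 vertices")
  if (n_random < 100) warning("n_random < 100: unstable hub p-values")
  if (!is.null(seed)) set.seed(seed)
  n <- n_vertices(trn)
  m <- n_arcs(trn)
  obs <- unname(network_degrees(trn, direction))
  ge <- integer(n)
  if (null == "er") {
    for (r in seq_len(n_random)) {
      p <- er_sample_pairs(n, m)
      deg <- tabulate(p[, if (direction == "in") 2L else 1L], nbins = n)
      ge <- ge + (deg >= obs)
    }
  } else {
    reg <- which(trn$nodes$role %in% TRN_REGULATOR_ROLES)
    if (length(reg) == 0 && m > 0) stop("role null impossible: no regulators")
    M <- as.double(length(reg)) * (n - 1)
    if (m > M) stop("n_arcs exceeds the available regulator-source pairs")
    for (r in seq_len(n_random)) {
      idx <- sample.int(M, m)
      s_i <- ceiling(idx / (n - 1))
      rr <- idx - (s_i - 1) * (n - 1)
      s <- reg[s_i]
      t <- rr + (rr >= s)
      deg <- tabulate(if (direction == "in") t else s, nbins = n)
      ge <- ge + (deg >= obs)
    }
  }
  p_value <- (1 + ge) / (1 + n_random)
  data.frame(gene_id = trn$nodes$gene_id, role = trn$nodes$role,
             tissue = rep(trn$label, n),
             direction = rep(direction, n),
             observed_degree = obs, p_value = p_value,
             is_hub = p_value < alpha,
             stringsAsFactors = FALSE)
}

#' Call hubs across a set of TRNs and directions
#'
#' @param trns named list of `regulatory_network` objects (one per tissue).
#' @param directions which directions to analyse.
#' @param ... passed to [call_hubs()].
#' @return Stacked data.frame of hub calls.
#' @export
call_hubs_tissues <- function(trns, directions = c("in", "out"), ...) {
  do.call(rbind, unlist(lapply(trns, function(trn)
    lapply(directions, function(d) call_hubs(trn, d, ...))),
    recursive = FALSE))
}

#' Tissue specificity index of a hub
#'
#' `SI = (N - n) / (N - 1)`, where `N` is the total number of tissues and
#' `n` the number of tissues in which the gene is a hub. SI is 1 for a gene
#' that is a hub in exactly one TRN and 0 for a gene that is a hub in all
#' of them.
#'
#' @param N total number of tissues (>= 2).
#' @param n number of tissues where the gene is a hub (1 <= n <= N);
#'   vectorized.
#' @return Numeric SI value(s) in \[0, 1\].
#' @export
specificity_index <- function(N, n) {
  stopifnot(length(N) == 1, N >= 2)
  if (any(n < 1)) stop("SI is undefined for a gene that is a hub nowhere (n = 0)")
  if (any(n > N)) stop("n cannot exceed the number of tissues N")
  (N - n) / (N - 1)
}

#' Active ratio of a gene in a tissue
#'
#' The fraction of a gene's possible connections in the reference network
#' that are realized ("active") in a given TRN:
#' `degree in TRN / degree in reference` for the chosen direction. A gene
#' absent from the TRN has active ratio 0.
#'
#' @param gene_id gene identifier, present in the reference with non-zero
#'   degree in `direction`.
#' @param direction `"in"` or `"out"`.
#' @param trn,reference `regulatory_network` objects.
#' @return Numeric in \[0, 1\].
#' @export
active_ratio <- function(gene_id, direction = c("in", "out"), trn, reference) {
  direction <- match.arg(direction)
  if (!gene_id %in% reference$nodes$gene_id)
    stop("gene ", gene_id, " absent from the reference network")
  ref_deg <- network_degrees(reference, direction)[[gene_id]]
  if (ref_deg == 0)
    stop("active ratio undefined: reference ", direction, "-degree of ",
         gene_id, " is 0")
  if (!gene_id %in% trn$nodes$gene_id) return(0)
  network_degrees(trn, direction)[[gene_id]] / ref_deg
}

#' Active ratios of all genes across TRNs
#'
#' @param reference the reference `regulatory_network`.
#' @param trns named list of TRNs.
#' @param direction `"in"` or `"out"`.
#' @return data.frame `gene_id`, `role`, `tissue`, `direction`,
#'   `active_ratio` for every gene with non-zero reference degree,
#'   restricted to tissues where the gene is expressed.
#' @export
active_ratio_table <- function(reference, trns, direction = c("in", "out")) {
  direction <- match.arg(direction)
  ref_deg <- network_degrees(reference, direction)
  eligible <- names(ref_deg)[ref_deg > 0]
  do.call(rbind, lapply(names(trns), function(t) {
    trn <- trns[[t]]
    genes <- intersect(eligible, trn$nodes$gene_id)
    if (!length(genes)) return(NULL)
    deg <- network_degrees(trn, direction)[genes]
    data.frame(gene_id = genes,
               role = reference$nodes$role[match(genes, reference$nodes$gene_id)],
               tissue = t, direction = direction,
               active_ratio = unname(deg / ref_deg[genes]),
               stringsAsFactors = FALSE)
  }))
}

#' Cross-tissue hub profiles with SI and strength class
#'
#' Aggregates per-tissue hub calls into one row per gene and direction:
#' in how many tissues the gene is expressed (`n_expressed`), in how many
#' it is a hub (`n_hub`), its specificity index, and its strength class.
#'
#' @param calls stacked hub calls from [call_hubs_tissues()].
#' @param trns the named list of TRNs the calls were computed on.
#' @return data.frame `gene_id`, `role`, `direction`, `n_tissues`,
#'   `n_expressed`, `n_hub`, `si`, `strength`.
#' @export
hub_profiles <- function(calls, trns) {
  N <- length(trns)
  out <- do.call(rbind, lapply(unique(calls$direction), function(d) {
    sub <- calls[calls$direction == d, , drop = FALSE]
    agg <- stats::aggregate(cbind(n_expressed = rep(1L, nrow(sub)),
                                  n_hub = as.integer(sub$is_hub)),
                            by = list(gene_id = sub$gene_id, role = sub$role),
                            FUN = sum)
    data.frame(gene_id = agg$gene_id, role = agg$role, direction = d,
               n_tissues = N, n_expressed = agg$n_expressed,
               n_hub = agg$n_hub,
               si = ifelse(agg$n_hub > 0 & N >= 2,
                           (N - agg$n_hub) / (N - 1), NA_real_),
               stringsAsFactors = FALSE)
  }))
  classify_strength(out)
}

#' Strong / weak hub classification
#'
#' A strong hub keeps hub status in every tissue where it is expressed
#' (`n_hub = n_expressed > 0`); a weak hub is a hub in some but not all of
#' the tissues where it is expressed; genes never called hubs are
#' `"non-hub"`.
#'
#' @param profiles data.frame with columns `n_hub` and `n_expressed`
#'   (e.g. from [hub_profiles()]).
#' @return The same data.frame with a populated `strength` column.
#' @export
classify_strength <- function(profiles) {
  stopifnot(all(c("n_hub", "n_expressed") %in% names(profiles)))
  profiles$strength <- ifelse(profiles$n_hub == 0, "non-hub",
                              ifelse(profiles$n_hub == profiles$n_expressed,
                                     "strong", "weak"))
  profiles
}

#' sigma_RF: standardized hub frequency versus degree-redistribution nulls
#'
#' The relative frequency RF_real(s) of hubs of one role and direction at
#' each discrete specificity-index value s is compared with an ensemble in
#' which, within every TRN, the degree values of the genes of that role are
#' randomly redistributed among them — which permutes hub status among
#' those genes, since hub calls are a monotone function of degree within a
#' TRN. sigma_RF(s) is the signed z-score
#' `(RF_real(s) - mean(RF_rand(s))) / sd(RF_rand(s))` (or the raw
#' difference with `mode = "difference"`); bins with zero ensemble spread
#' are reported as 0 and flagged.
#'
#' @param calls stacked hub calls from [call_hubs_tissues()].
#' @param trns named list of TRNs (defines tissue membership per gene).
#' @param direction `"in"` or `"out"`.
#' @param role `"TF"`, `"miRNA"` or `"nonTF"`.
#' @param n_random ensemble size (default 2000).
#' @param seed optional integer seed.
#' @param mode `"zscore"` (default) or `"difference"`.
#' @return data.frame with one row per discrete SI value: `si`, `n_hub_tissues`,
#'   `rf_real`, `rf_rand_mean`, `rf_rand_sd`, `sigma_rf`, `sd_zero`.
#' @export
sigma_rf <- function(calls, trns, direction = c("in", "out"), role,
                     n_random = 2000, seed = NULL,
                     mode = c("zscore", "difference")) {
  direction <- match.arg(direction)
  role <- match.arg(role, TRN_ROLES)
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  N <- length(trns)
  stopifnot(N >= 2)
  tissues <- names(trns)

  role_genes <- lapply(trns, function(trn)
    trn$nodes$gene_id[trn$nodes$role == role])
  universe <- sort(unique(unlist(role_genes)))
  if (!length(universe)) {
    warning("no ", role, " genes in any TRN")
    return(data.frame())
  }
  expr <- sapply(tissues, function(t) universe %in% role_genes[[t]])
  hub <- sapply(tissues, function(t) {
    sub <- calls[calls$direction == direction & calls$tissue == t &
                   calls$is_hub, , drop = FALSE]
    universe %in% sub$gene_id
  })
  expr <- matrix(expr, nrow = length(universe))
  hub <- matrix(hub, nrow = length(universe)) & expr

  rf_of <- function(hubmat) {
    nh <- rowSums(hubmat)
    if (!any(nh > 0)) return(rep(NA_real_, N))
    tabulate(nh[nh > 0], nbins = N) / sum(nh > 0)
  }
  rf_real <- rf_of(hub)
  if (anyNA(rf_real)) {
    warning("no ", role, " ", direction, "-hubs: empty sigma_RF curve")
    return(data.frame())
  }
  rf_rand <- matrix(NA_real_, n_random, N)
  for (r in seq_len(n_random)) {
    hr <- hub
    for (t in seq_len(N)) {
      e <- which(expr[, t])
      if (length(e) > 1) hr[e, t] <- hub[e, t][sample.int(length(e))]
    }
    rf_rand[r, ] <- rf_of(hr)
  }
  rf_rand[is.na(rf_rand)] <- 0
  mu <- colMeans(rf_rand)
  sdev <- apply(rf_rand, 2, sd)
  sd_zero <- sdev == 0
  sig <- if (mode == "zscore") ifelse(sd_zero, 0, (rf_real - mu) / sdev)
  else rf_real - mu
  data.frame(si = (N - seq_len(N)) / (N - 1),
             n_hub_tissues = seq_len(N),
             rf_real = rf_real, rf_rand_mean = mu, rf_rand_sd = sdev,
             sigma_rf = sig, sd_zero = sd_zero,
             stringsAsFactors = FALSE)
}
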