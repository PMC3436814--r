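# Colored three-vertex motif analysis: triad census, canonical signatures,
# switch-randomization significance, and common / tissue-specific labels.

# decode canonical integer codes from the C++ census into signature strings
# "ROLE-ROLE-ROLE|bbbbbb", bits in the order (1->2,1->3,2->1,2->3,3->1,3->2);
# a precomputed table over all 27 * 64 codes keeps per-replicate decoding O(1)
.sig_env <- new.env(parent = emptyenv())

sig_decode_table <- function() {
  if (is.null(.sig_env$table)) {
    codes <- 0:(27L * 64L - 1L)
    rcode <- codes %/% 64L
    bits <- codes %% 64L
    bitstr <- paste0(bits %/% 32L %% 2L, bits %/% 16L %% 2L, bits %/% 8L %% 2L,
                     bits %/% 4L %% 2L, bits %/% 2L %% 2L, bits %% 2L)
    .sig_env$table <- paste0(TRN_ROLES[rcode %/% 9L + 1L], "-",
                             TRN_ROLES[(rcode %/% 3L) %% 3L + 1L], "-",
                             TRN_ROLES[rcode %% 3L + 1L], "|", bitstr)
  }
  .sig_env$table
}

decode_signature <- function(code) {
  sig_decode_table()[code + 1L]
}

# parse a signature string back into roles and a 3x3 adjacency matrix
parse_signature <- function(signature) {
  parts <- strsplit(signature, "|", fixed = TRUE)[[1]]
  roles <- strsplit(parts[1], "-", fixed = TRUE)[[1]]
  bits <- as.integer(strsplit(parts[2], "")[[1]])
  a <- matrix(0L, 3, 3)
  ord <- rbind(c(1, 2), c(1, 3), c(2, 1), c(2, 3), c(3, 1), c(3, 2))
  a[ord] <- bits
  list(roles = roles, adj = a)
}

#' Canonical signature of a colored triad
#'
#' A connected three-vertex colored digraph is identified by the
#' lexicographic minimum, over all 6 vertex orderings, of its (role triple,
#' 6-bit adjacency pattern) encoding — so every relabeling of the same
#' colored triad maps to one signature string of the form
#' `"TF-TF-nonTF|110100"` (bits in the order 1→2, 1→3, 2→1, 2→3, 3→1, 3→2).
#'
#' @param roles character vector of length 3 of vertex roles.
#' @param adj 3x3 0/1 adjacency matrix (`adj[i, j]` = arc i→j); the
#'   diagonal is ignored.
#' @return The canonical signature string.
#' @export
triad_signature <- function(roles, adj) {
  stopifnot(length(roles) == 3, all(roles %in% TRN_ROLES),
            is.matrix(adj), all(dim(adj) == c(3, 3)))
  r <- match(roles, TRN_ROLES) - 1L
  best <- Inf
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  shift <- c(5L, 4L, 3L, 2L, 1L, 0L)
  ord <- rbind(c(1, 2), c(1, 3), c(2, 1), c(2, 3), c(3, 1), c(3, 2))
  for (pm in perms) {
    bits <- sum(bitwShiftL(as.integer(adj[cbind(pm[ord[, 1]], pm[ord[, 2]])] != 0), shift))
    code <- ((r[pm[1]] * 3L + r[pm[2]]) * 3L + r[pm[3]]) * 64L + bits
    if (code < best) best <- code
  }
  decode_signature(as.integer(best))
}

#' Enumerate all connected colored triads of a network
#'
#' Scans every unordered vertex triple whose induced subgraph is weakly
#' connected, counting each exactly once under its canonical colored
#' signature and recording the instances (needed later for the bow-tie
#' decomposition).
#'
#' @param trn a `regulatory_network` with at least 3 vertices.
#' @return List with `stats` (data.frame `signature`, `occurrence`) and
#'   `instances` (data.frame `signature`, `g1`, `g2`, `g3`).
#' @export
enumerate_triads <- function(trn) {
  stopifnot(inherits(trn, "regulatory_network"))
  if (n_vertices(trn) < 3) stop("triad enumeration needs at least 3 vertices")
  ids <- trn$nodes$gene_id
  res <- census_triads_cpp(length(ids),
                           match(trn$arcs$source, ids),
                           match(trn$arcs$target, ids),
                           match(trn$nodes$role, TRN_ROLES) - 1L)
  if (length(res$code) == 0L) {
    return(list(stats = data.frame(signature = character(), occurrence = integer(),
                                   stringsAsFactors = FALSE),
                instances = data.frame(signature = character(), g1 = character(),
                                       g2 = character(), g3 = character(),
                                       stringsAsFactors = FALSE)))
  }
  sig <- decode_signature(res$code)
  counts <- table(sig)
  list(stats = data.frame(signature = names(counts),
                          occurrence = as.integer(counts),
                          stringsAsFactors = FALSE),
       instances = data.frame(signature = sig, g1 = ids[res$v1],
                              g2 = ids[res$v2], g3 = ids[res$v3],
                              stringsAsFactors = FALSE))
}

#' Structural class of a triad signature
#'
#' Classifies a connected triad as a feed-forward loop (`"FFL"`: acyclic
#' with a two-step path and its shortcut arc), a three-vertex feedback loop
#' (`"FBL"`: directed 3-cycle without any bidirectional pair), a complex
#' loop (`"CMPLX"`: at least one bidirectional pair — a regulatory dyad —
#' together with a feed-forward pattern, so both feed-forward and feedback
#' are present), or `"non-loop"` otherwise.
#'
#' @param signature signature string(s) as produced by [enumerate_triads()].
#' @return Character vector of structural classes.
#' @export
classify_structure <- function(signature) {
  one <- function(s) {
    a <- parse_signature(s)$adj
    bidir <- any(a == 1L & t(a) == 1L)
    trip <- expand.grid(i = 1:3, j = 1:3, k = 1:3)
    trip <- trip[trip$i != trip$j & trip$j != trip$k & trip$i != trip$k, ]
    has_ffl <- any(a[cbind(trip$i, trip$j)] & a[cbind(trip$j, trip$k)] &
                     a[cbind(trip$i, trip$k)])
    cyc3 <- any(a[cbind(trip$i, trip$j)] & a[cbind(trip$j, trip$k)] &
                  a[cbind(trip$k, trip$i)])
    if (!bidir && !cyc3 && has_ffl) "FFL"
    else if (cyc3 && !bidir) "FBL"
    else if (bidir && has_ffl) "CMPLX"
    else "non-loop"
  }
  vapply(signature, one, character(1), USE.NAMES = FALSE)
}

#' Degree-preserving switch randomization
#'
#' Rewires the arcs of a network by repeated double-arc switches
#' (a→b, c→d becomes a→d, c→b), rejecting any switch that would create a
#' self-loop or duplicate arc. Every vertex keeps its exact in- and
#' out-degree and its role, so role validity is preserved automatically.
#'
#' @param trn a `regulatory_network` with at least 2 arcs.
#' @param n_swap_factor attempted switches per arc (default 10, a standard
#'   mixing heuristic).
#' @param seed optional integer seed.
#' @return A rewired `regulatory_network` with the same vertices and label.
#' @export
switch_randomize <- function(trn, n_swap_factor = 10, seed = NULL) {
  stopifnot(inherits(trn, "regulatory_network"))
  m <- n_arcs(trn)
  if (m < 2) stop("switch randomization needs at least 2 arcs")
  if (!is.null(seed)) set.seed(seed)
  ids <- trn$nodes$gene_id
  res <- switch_randomize_cpp(length(ids),
                              match(trn$arcs$source, ids),
                              match(trn$arcs$target, ids),
                              as.integer(ceiling(n_swap_factor * m)))
  out <- trn
  out$arcs <- data.frame(source = ids[res$from], target = ids[res$to],
                         stringsAsFactors = FALSE)
  out
}

#' Motif over-representation against switch-randomized ensembles
#'
#' For each colored triad signature observed in the network, its occurrence
#' is compared with the distribution of occurrences across an ensemble of
#' degree-preserving switch-randomized networks. A signature is a motif
#' when (i) its occurrence exceeds 5, (ii) the one-sided empirical P-value
#' is below 0.05 and (iii) the Z-score exceeds 2.2.
#'
#' @param trn a `regulatory_network`.
#' @param n_random ensemble size (default 1000).
#' @param seed optional integer seed.
#' @param n_swap_factor passed to [switch_randomize()].
#' @param min_occurrence,max_p,min_z the three significance criteria.
#' @return data.frame with columns `tissue`, `signature`, `structure`,
#'   `occurrence`, `rand_mean`, `rand_sd`, `z_score`, `p_value`, `sd_zero`,
#'   `significant`; the triad instances are attached as
#'   `attr(, "instances")`.
#' @export
motif_significance <- function(trn, n_random = 1000, seed = NULL,
                               n_swap_factor = 10, min_occurrence = 6,
                               max_p = 0.05, min_z = 2.2) {
  stopifnot(inherits(trn, "regulatory_network"))
  if (n_random < 100) warning("n_random < 100: unstable motif p-values")
  if (!is.null(seed)) set.seed(seed)
  ids <- trn$nodes$gene_id
  n <- length(ids)
  from <- match(trn$arcs$source, ids)
  to <- match(trn$arcs$target, ids)
  role <- match(trn$nodes$role, TRN_ROLES) - 1L
  n_attempts <- as.integer(ceiling(n_swap_factor * length(from)))
  res <- if (n >= 3) census_triads_cpp(n, from, to, role) else list(code = integer(0))
  ucodes <- sort(unique(res$code))
  occurrence <- tabulate(match(res$code, ucodes), nbins = length(ucodes))
  stats <- data.frame(signature = decode_signature(ucodes),
                      occurrence = as.integer(occurrence),
                      stringsAsFactors = FALSE)
  instances <- if (length(res$code))
    data.frame(signature = decode_signature(res$code), g1 = ids[res$v1],
               g2 = ids[res$v2], g3 = ids[res$v3], stringsAsFactors = FALSE)
  else data.frame(signature = character(), g1 = character(),
                  g2 = character(), g3 = character(), stringsAsFactors = FALSE)

  if (nrow(stats) == 0L || length(from) < 2) {
    out <- data.frame(tissue = character(), signature = character(),
                      structure = character(), occurrence = integer(),
                      rand_mean = numeric(), rand_sd = numeric(),
                      z_score = numeric(), p_value = numeric(),
                      sd_zero = logical(), significant = logical(),
                      stringsAsFactors = FALSE)
    attr(out, "instances") <- instances
    return(out)
  }

  cnt <- matrix(0L, nrow = n_random, ncol = nrow(stats))
  for (r in seq_len(n_random)) {
    rw <- switch_randomize_cpp(n, from, to, n_attempts)
    codes <- census_triads_cpp(n, rw$from, rw$to, role)$code
    if (length(codes)) {
      hit <- match(codes, ucodes)
      hit <- hit[!is.na(hit)]
      if (length(hit)) cnt[r, ] <- tabulate(hit, nbins = nrow(stats))
    }
  }
  rand_mean <- colMeans(cnt)
  rand_sd <- apply(cnt, 2, sd)
  sd_zero <- rand_sd == 0
  z <- ifelse(sd_zero, 0, (stats$occurrence - rand_mean) / rand_sd)
  p <- (1 + colSums(cnt >= matrix(stats$occurrence, nrow = n_random,
                                  ncol = nrow(stats), byrow = TRUE))) /
    (1 + n_random)
  out <- data.frame(tissue = rep(trn$label, nrow(stats)),
                    signature = stats$signature,
                    structure = classify_structure(stats$signature),
                    occurrence = stats$occurrence,
                    rand_mean = rand_mean, rand_sd = rand_sd,
                    z_score = z, p_value = p, sd_zero = sd_zero,
                    significant = stats$occurrence >= min_occurrence &
                      p < max_p & z > min_z & !sd_zero,
                    stringsAsFactors = FALSE)
  attr(out, "instances") <- instances
  out
}

#' Classify motifs as common (CM) or tissue-specific (TS)
#'
#' A signature significant in every analyzed tissue is a common motif (CM);
#' one significant in at least one but not all tissues is tissue-specific
#' (TS); signatures significant nowhere are labelled `"none"`.
#'
#' @param stats_list named list (tissue → data.frame from
#'   [motif_significance()]).
#' @return data.frame with columns `signature`, `structure`,
#'   `n_significant`, `tissues` (comma-separated list of tissues where
#'   significant) and `label`.
#' @export
classify_cm_ts <- function(stats_list) {
  stopifnot(is.list(stats_list), length(stats_list) >= 1,
            !is.null(names(stats_list)))
  tissues <- names(stats_list)
  sigs <- sort(unique(unlist(lapply(stats_list, function(d) d$signature))))
  sig_in <- vapply(tissues, function(t) {
    d <- stats_list[[t]]
    sigs %in% d$signature[d$significant]
  }, logical(length(sigs)))
  sig_in <- matrix(sig_in, nrow = length(sigs),
                   dimnames = list(sigs, tissues))
  n_sig <- rowSums(sig_in)
  label <- ifelse(n_sig == length(tissues), "CM",
                  ifelse(n_sig > 0, "TS", "none"))
  data.frame(signature = sigs,
             structure = if (length(sigs)) classify_structure(sigs) else character(0),
             n_significant = as.integer(n_sig),
             tissues = vapply(seq_along(sigs), function(i)
               paste(tissues[sig_in[i, ]], collapse = ","), character(1)),
             label = label,
             stringsAsFactors = FALSE)
}
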