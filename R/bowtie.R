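# Bow-tie decomposition of CM/TS motif instances: core / non-core
# partition, composition and average-degree statistics with permutation
# tests, size ratios and pattern classification.

instance_genes <- function(instances) {
  if (is.null(instances)) return(character(0))
  if (is.matrix(instances)) return(unique(as.vector(instances)))
  if (is.data.frame(instances)) {
    cols <- intersect(c("g1", "g2", "g3", "v1", "v2", "v3"), names(instances))
    if (length(cols) < 3) cols <- names(instances)[vapply(instances, is.character, logical(1))]
    return(unique(unlist(instances[cols])))
  }
  unique(as.character(instances))
}

#' Partition motif-instance genes into bow-tie layers
#'
#' Core genes participate in at least one common-motif (CM) instance and at
#' least one tissue-specific-motif (TS) instance; non-core CM genes appear
#' only in CM instances (the output layer) and non-core TS genes only in TS
#' instances (the input layer).
#'
#' @param cm_instances,ts_instances instance triples (data.frame with
#'   columns `g1`,`g2`,`g3`, a 3-column matrix, or a plain vector of gene
#'   ids); either may be empty.
#' @return List with character vectors `core`, `noncore_cm`, `noncore_ts`.
#' @export
partition_genes <- function(cm_instances, ts_instances) {
  cm <- instance_genes(cm_instances)
  ts <- instance_genes(ts_instances)
  list(core = sort(intersect(cm, ts)),
       noncore_cm = sort(setdiff(cm, ts)),
       noncore_ts = sort(setdiff(ts, cm)))
}

#' Molecular composition of gene sets
#'
#' Fraction of TF, miRNA and non-TF genes in each set; fractions sum to 1
#' for non-empty sets, and empty sets are flagged.
#'
#' @param sets named list of character vectors of gene ids.
#' @param roles named character vector mapping gene id to role.
#' @return data.frame `set`, `role`, `fraction`, `empty`.
#' @export
gene_set_composition <- function(sets, roles) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  do.call(rbind, lapply(names(sets), function(s) {
    g <- sets[[s]]
    if (!length(g)) {
      return(data.frame(set = s, role = TRN_ROLES, fraction = 0,
                        empty = TRUE, stringsAsFactors = FALSE))
    }
    r <- roles[g]
    if (anyNA(r)) stop("role unknown for gene(s): ",
                       paste(head(g[is.na(r)], 5L), collapse = ", "))
    tab <- table(factor(r, levels = TRN_ROLES))
    data.frame(set = s, role = TRN_ROLES,
               fraction = as.numeric(tab) / length(g),
               empty = FALSE, stringsAsFactors = FALSE)
  }))
}

#' Average degree within or between gene sets
#'
#' Within a set i, `D_i` = (number of arcs with both endpoints in i) / N_i;
#' from set i to set j, `D_i→j` = (number of arcs from i to j) / N_i, i.e.
#' the mean number of targets in j per source-set gene. Alternative
#' normalizations: `"density"` divides by N_i (N_i − 1) within and
#' N_i N_j between; `"mean"` divides by (N_i + N_j)/2.
#'
#' @param set_i non-empty character vector of gene ids (source set).
#' @param set_j optional target set; omit for the within-set degree.
#' @param arcs data.frame with columns `source`, `target`.
#' @param normalization `"source"` (default), `"density"` or `"mean"`.
#' @return Numeric average degree.
#' @export
average_degree <- function(set_i, set_j = NULL, arcs,
                           normalization = c("source", "density", "mean")) {
  normalization <- match.arg(normalization)
  if (!length(set_i)) stop("empty source set: average degree undefined")
  within <- is.null(set_j)
  if (within) set_j <- set_i else if (!length(set_j)) stop("empty target set")
  cnt <- sum(arcs$source %in% set_i & arcs$target %in% set_j)
  ni <- length(set_i)
  nj <- length(set_j)
  denom <- switch(normalization,
                  source = ni,
                  density = if (within) ni * (ni - 1) else ni * nj,
                  mean = (ni + nj) / 2)
  if (denom == 0) return(0)
  cnt / denom
}

# 3x3 cross-count of arcs between layers and of roles within layers, given
# integer layer labels; shared by the real statistics and the permutation
# replicates so both go through identical code
layer_stats <- function(lab, role_int, src_idx, tgt_idx, sizes, denom_deg,
                        denom_na) {
  comp_cnt <- tabulate((lab - 1L) * 3L + role_int, nbins = 9L)
  comp <- comp_cnt / rep(pmax(sizes, 1L), each = 3L)
  deg_cnt <- if (length(src_idx))
    tabulate((lab[src_idx] - 1L) * 3L + lab[tgt_idx], nbins = 9L) else rep(0L, 9L)
  deg <- deg_cnt / denom_deg
  comp[denom_na$comp] <- NA_real_
  deg[denom_na$deg] <- NA_real_
  c(comp, deg)
}

#' Permutation test on bow-tie composition and average degrees
#'
#' Generates random cases by re-distributing the motif-instance genes over
#' the three bow-tie layers, keeping the layer sizes and the arcs between
#' genes fixed, then recomputes every composition fraction and every
#' within-/between-layer average degree. One-sided empirical P-values are
#' reported in both directions with the add-one estimator:
#' `p_high = (1 + #{rand >= real}) / (1 + n_random)` and analogously
#' `p_low` with `<=`.
#'
#' @param partition list with `core`, `noncore_cm`, `noncore_ts` (from
#'   [partition_genes()]); the union must contain at least 3 genes.
#' @param trn the `regulatory_network` providing roles and arcs.
#' @param n_random number of random cases (default 5000).
#' @param seed optional integer seed.
#' @param normalization degree normalization (see [average_degree()]).
#' @return List with data.frames `composition` (`layer`, `role`, `real`,
#'   `null_mean`, `p_high`, `p_low`) and `degree` (`from_layer`,
#'   `to_layer`, `real`, `null_mean`, `p_high`, `p_low`). Statistics of
#'   empty layers are `NA`.
#' @export
bowtie_permutation_test <- function(partition, trn, n_random = 5000,
                                    seed = NULL,
                                    normalization = c("source", "density", "mean")) {
  normalization <- match.arg(normalization)
  if (!is.null(seed)) set.seed(seed)
  layers <- c("input", "core", "output")
  sets <- list(input = partition$noncore_ts, core = partition$core,
               output = partition$noncore_cm)
  union_genes <- unlist(sets, use.names = FALSE)
  if (length(union_genes) < 3)
    stop("bow-tie permutation test needs at least 3 motif-instance genes")
  lab <- rep(1:3, times = lengths(sets))
  roles <- setNames(trn$nodes$role, trn$nodes$gene_id)
  role_int <- match(roles[union_genes], TRN_ROLES)
  if (anyNA(role_int)) stop("motif-instance gene(s) missing from the TRN")
  keep <- trn$arcs$source %in% union_genes & trn$arcs$target %in% union_genes
  src_idx <- match(trn$arcs$source[keep], union_genes)
  tgt_idx <- match(trn$arcs$target[keep], union_genes)
  sizes <- lengths(sets)

  ni <- rep(sizes, each = 3L)                 # source-layer size per (i,j) cell
  nj <- rep(sizes, times = 3L)
  within <- rep(1:3, each = 3L) == rep(1:3, times = 3L)
  denom_deg <- switch(normalization,
                      source = ni,
                      density = ifelse(within, ni * pmax(ni - 1L, 1L), ni * nj),
                      mean = (ni + nj) / 2)
  denom_deg <- pmax(denom_deg, 1e-300)
  denom_na <- list(comp = rep(sizes, each = 3L) == 0L,
                   deg = ni == 0L | nj == 0L)

  real <- layer_stats(lab, role_int, src_idx, tgt_idx, sizes, denom_deg, denom_na)
  ge <- le <- numeric(length(real))
  acc <- numeric(length(real))
  for (r in seq_len(n_random)) {
    st <- layer_stats(sample(lab), role_int, src_idx, tgt_idx, sizes,
                      denom_deg, denom_na)
    ge <- ge + (st >= real)
    le <- le + (st <= real)
    acc <- acc + ifelse(is.na(st), 0, st)
  }
  p_high <- (1 + ge) / (1 + n_random)
  p_low <- (1 + le) / (1 + n_random)
  null_mean <- acc / n_random
  p_high[is.na(real)] <- NA_real_
  p_low[is.na(real)] <- NA_real_
  null_mean[is.na(real)] <- NA_real_

  comp_idx <- 1:9
  deg_idx <- 10:18
  list(composition = data.frame(layer = rep(layers, each = 3L),
                                role = rep(TRN_ROLES, times = 3L),
                                real = real[comp_idx],
                                null_mean = null_mean[comp_idx],
                                p_high = p_high[comp_idx],
                                p_low = p_low[comp_idx],
                                stringsAsFactors = FALSE),
       degree = data.frame(from_layer = rep(layers, each = 3L),
                           to_layer = rep(layers, times = 3L),
                           real = real[deg_idx],
                           null_mean = null_mean[deg_idx],
                           p_high = p_high[deg_idx],
                           p_low = p_low[deg_idx],
                           stringsAsFactors = FALSE))
}

#' Size ratios of the bow-tie layers
#'
#' Fraction of the motif-instance genes falling into the input (non-core
#' TS), core, and output (non-core CM) layer; the three ratios sum to 1.
#'
#' @param partition list from [partition_genes()], with a non-empty union.
#' @return Named numeric vector `c(input = , core = , output = )`.
#' @export
size_ratios <- function(partition) {
  n <- lengths(list(partition$noncore_ts, partition$core, partition$noncore_cm))
  tot <- sum(n)
  if (tot == 0) stop("size ratios undefined: no motif-instance genes")
  setNames(n / tot, c("input", "core", "output"))
}

#' Classify the bow-tie pattern of a TRN
#'
#' Applies numeric thresholds to the verbal pattern definitions: symmetric
#' when the input and output ratios differ by at most `tau_sym` and both
#' exceed the core ratio; input-dominated when the input ratio is at least
#' `kappa` times the core ratio and the core exceeds the output;
#' output-dominated when the output ratio is at least `kappa` times the
#' core ratio and the input is below the core. A decomposition with an
#' empty layer is flagged degenerate; an empty input with non-empty output
#' (the liver-like case) is labelled output-dominated, and symmetrically
#' for an empty output.
#'
#' @param sr named size-ratio triple from [size_ratios()].
#' @param kappa dominance multiplier (default 2).
#' @param tau_sym symmetry tolerance on `|SR_input - SR_output|`
#'   (default 0.1).
#' @return List with `pattern` (one of `"input-dominated"`, `"symmetric"`,
#'   `"output-dominated"`, `"unclassified"`) and logical `degenerate`.
#' @export
classify_pattern <- function(sr, kappa = 2, tau_sym = 0.1) {
  stopifnot(length(sr) == 3, abs(sum(sr) - 1) < 1e-9)
  sin <- sr[["input"]]
  sco <- sr[["core"]]
  sou <- sr[["output"]]
  degenerate <- any(sr == 0)
  if (sin == 0 && sou > 0)
    return(list(pattern = "output-dominated", degenerate = TRUE))
  if (sou == 0 && sin > 0)
    return(list(pattern = "input-dominated", degenerate = TRUE))
  pattern <-
    if (abs(sin - sou) <= tau_sym && min(sin, sou) > sco) "symmetric"
    else if (sin >= kappa * sco && sco > sou) "input-dominated"
    else if (sou >= kappa * sco && sin < sco) "output-dominated"
    else "unclassified"
  list(pattern = pattern, degenerate = degenerate)
}

#' Full bow-tie decomposition of one TRN
#'
#' Partitions the genes of the CM and TS motif instances into bow-tie
#' layers and computes composition, average-degree statistics with
#' permutation P-values, size ratios, and the pattern label.
#'
#' @param cm_instances,ts_instances instance triples (see
#'   [partition_genes()]).
#' @param trn the tissue `regulatory_network`.
#' @param n_random permutation replicates (default 5000); tests are skipped
#'   with a warning when fewer than 3 genes are involved.
#' @param seed optional integer seed.
#' @param kappa,tau_sym pattern thresholds (see [classify_pattern()]).
#' @param normalization degree normalization (see [average_degree()]).
#' @return Object of class `bowtie_decomposition`.
#' @export
bowtie_decompose <- function(cm_instances, ts_instances, trn,
                             n_random = 5000, seed = NULL, kappa = 2,
                             tau_sym = 0.1,
                             normalization = c("source", "density", "mean")) {
  normalization <- match.arg(normalization)
  part <- partition_genes(cm_instances, ts_instances)
  union_n <- sum(lengths(part))
  sr <- if (union_n > 0) size_ratios(part) else
    setNames(rep(NA_real_, 3), c("input", "core", "output"))
  pat <- if (union_n > 0) classify_pattern(sr, kappa, tau_sym) else
    list(pattern = "unclassified", degenerate = TRUE)
  tests <- NULL
  if (union_n >= 3) {
    tests <- bowtie_permutation_test(part, trn, n_random = n_random,
                                     seed = seed, normalization = normalization)
  } else if (union_n > 0) {
    warning("fewer than 3 motif-instance genes: permutation tests skipped")
  }
  roles <- setNames(trn$nodes$role, trn$nodes$gene_id)
  comp <- gene_set_composition(list(input = part$noncore_ts, core = part$core,
                                    output = part$noncore_cm), roles)
  structure(list(tissue = trn$label, core = part$core,
                 noncore_cm = part$noncore_cm, noncore_ts = part$noncore_ts,
                 composition = comp, tests = tests, size_ratios = sr,
                 pattern = pat$pattern, degenerate = pat$degenerate,
                 normalization = normalization),
            class = "bowtie_decomposition")
}

#' @export
print.bowtie_decomposition <- function(x, ...) {
  cat("bowtie_decomposition of '", x$tissue, "'\n", sep = "")
  cat(sprintf("  layers: input %d, core %d, output %d genes\n",
              length(x$noncore_ts), length(x$core), length(x$noncore_cm)))
  cat(sprintf("  size ratios: input %.3f, core %.3f, output %.3f\n",
              x$size_ratios[["input"]], x$size_ratios[["core"]],
              x$size_ratios[["output"]]))
  cat("  pattern: ", x$pattern,
      if (x$degenerate) " (degenerate)" else "", "\n", sep = "")
  invisible(x)
}
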