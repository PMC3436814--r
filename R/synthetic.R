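#' Parameters of the synthetic regulatory-network generator
#'
#' The generator emulates the statistical structure of a genome-wide
#' predicted regulatory map: role-typed genes where only TFs and miRNAs
#' regulate, heavy-tailed regulator out-degrees, and binary tissue
#' expression made of a shared housekeeping fraction plus per-tissue
#' specific fractions.
#'
#' @param n_tf,n_mirna,n_nontf number of TF / miRNA / non-TF genes.
#' @param n_tissues number of tissues (default 8).
#' @param mean_out_degree_tf,mean_out_degree_mirna mean out-degree of TF and
#'   miRNA regulators.
#' @param degree_tail_exponent Pareto shape (> 1) of the out-degree
#'   distribution; smaller values give heavier tails.
#' @param housekeeping_fraction fraction of genes expressed in every tissue.
#' @param tissue_specific_fraction fraction of genes added independently per
#'   tissue; `housekeeping_fraction + tissue_specific_fraction` must be <= 1.
#' @param seed integer seed (< 2^31); all generation is reproducible from it.
#' @return A validated list of class `generator_params`.
#' @export
generator_params <- function(n_tf, n_mirna, n_nontf, n_tissues = 8L,
                             mean_out_degree_tf = 5, mean_out_degree_mirna = 5,
                             degree_tail_exponent = 2,
                             housekeeping_fraction = 0.5,
                             tissue_specific_fraction = 0.2,
                             seed = 1L) {
  stopifnot(n_tf >= 0, n_mirna >= 0, n_nontf >= 0,
            n_tf + n_mirna + n_nontf >= 3,
            n_tissues >= 1,
            mean_out_degree_tf >= 0, mean_out_degree_mirna >= 0,
            degree_tail_exponent > 1,
            housekeeping_fraction >= 0, housekeeping_fraction <= 1,
            tissue_specific_fraction >= 0, tissue_specific_fraction <= 1,
            housekeeping_fraction + tissue_specific_fraction <= 1,
            is.numeric(seed), length(seed) == 1, abs(seed) < 2^31 - 1)
  structure(list(n_tf = as.integer(n_tf), n_mirna = as.integer(n_mirna),
                 n_nontf = as.integer(n_nontf), n_tissues = as.integer(n_tissues),
                 mean_out_degree_tf = mean_out_degree_tf,
                 mean_out_degree_mirna = mean_out_degree_mirna,
                 degree_tail_exponent = degree_tail_exponent,
                 housekeeping_fraction = housekeeping_fraction,
                 tissue_specific_fraction = tissue_specific_fraction,
                 seed = as.integer(seed)),
            class = "generator_params")
}

#' Specify structures to plant into a synthetic reference network
#'
#' Planted structures are inserted after background sampling, overriding
#' sampled arcs as needed, and are recorded on the generated network so that
#' [generate_expression()] can force the right tissue memberships and so
#' recovery tests know the ground truth.
#'
#' @param hubs list of entries created by [plant_hub()].
#' @param motifs list of entries created by [plant_motif()].
#' @param bowtie optional entry created by [plant_bowtie()].
#' @return A list of class `plant_spec`.
#' @export
plant_spec <- function(hubs = list(), motifs = list(), bowtie = NULL) {
  stopifnot(is.list(hubs), is.list(motifs))
  structure(list(hubs = hubs, motifs = motifs, bowtie = bowtie),
            class = "plant_spec")
}

#' @rdname plant_spec
#' @param role vertex role of the planted hub gene.
#' @param direction `"in"` or `"out"`; an out-hub must be a regulator role.
#' @param target_degree degree the planted gene receives in the reference
#'   network (must not exceed the number of eligible partner vertices).
#' @param tissues integer indices of the tissues in which the planted gene
#'   is forced to be expressed.
#' @export
plant_hub <- function(role, direction, target_degree, tissues) {
  role <- match.arg(role, TRN_ROLES)
  direction <- match.arg(direction, c("in", "out"))
  if (direction == "out" && !role %in% TRN_REGULATOR_ROLES)
    stop("an out-hub must have a regulator role (TF or miRNA)")
  stopifnot(target_degree >= 1, length(tissues) >= 1, all(tissues >= 1))
  list(role = role, direction = direction,
       target_degree = as.integer(target_degree),
       tissues = as.integer(tissues))
}

#' @rdname plant_spec
#' @param roles character vector of length 3: roles of the three motif
#'   positions.
#' @param arcs two-column matrix of position indices (1..3) giving the arcs
#'   of the planted triad; sources must sit on regulator roles and the triad
#'   must be weakly connected.
#' @param n_instances number of vertex-disjoint instances to plant.
#' @export
plant_motif <- function(roles, arcs, n_instances, tissues) {
  stopifnot(length(roles) == 3, all(roles %in% TRN_ROLES),
            is.matrix(arcs), ncol(arcs) == 2, nrow(arcs) >= 2,
            all(arcs %in% 1:3), all(arcs[, 1] != arcs[, 2]),
            n_instances >= 1, length(tissues) >= 1, all(tissues >= 1))
  if (anyDuplicated(paste(arcs[, 1], arcs[, 2]))) stop("duplicate arcs in planted triad")
  if (!all(roles[arcs[, 1]] %in% TRN_REGULATOR_ROLES))
    stop("planted triad has an arc starting at a nonTF position")
  touched <- unique(as.vector(arcs))
  if (length(touched) < 3) stop("planted triad is not connected (an isolated position)")
  list(roles = roles, arcs = arcs, n_instances = as.integer(n_instances),
       tissues = as.integer(tissues))
}

#' @rdname plant_spec
#' @param n_input,n_core,n_output sizes of the planted input (miRNA), core
#'   (TF, at least 2) and output (non-TF) layers. So that every core gene
#'   appears in both a TS-side and a CM-side instance (the defining property
#'   of core genes), `n_input >= n_core` and `2 * n_output >= n_core` are
#'   required.
#' @export
plant_bowtie <- function(n_input, n_core, n_output) {
  stopifnot(n_input >= 0, n_core >= 2, n_output >= 0)
  if (n_input < n_core || 2 * n_output < n_core)
    stop("planted bow-tie needs n_input >= n_core and 2*n_output >= n_core ",
         "so every core gene joins both instance kinds")
  list(n_input = as.integer(n_input), n_core = as.integer(n_core),
       n_output = as.integer(n_output))
}

# Discretized Pareto out-degrees with the requested mean: continuous
# Pareto(shape, scale chosen so the mean matches), stochastically rounded so
# the discretization is unbiased, capped at the number of eligible targets.
sample_out_degrees <- function(n, mean_degree, shape, max_degree) {
  if (n == 0L) return(integer(0))
  if (mean_degree <= 0) return(integer(n))
  xm <- mean_degree * (shape - 1) / shape
  x <- xm * runif(n)^(-1 / shape)
  d <- floor(x) + (runif(n) < (x - floor(x)))
  pmin(as.integer(d), as.integer(max_degree))
}

#' Generate a synthetic reference regulatory network
#'
#' Background arcs: every regulator (TF or miRNA) draws an out-degree from a
#' discretized Pareto distribution with the configured mean and tail
#' exponent, then targets that many distinct genes uniformly among all other
#' genes. Non-TF genes never regulate, no self-loops, no duplicate arcs.
#' Planted hubs, motif instances and bow-tie layers (see [plant_spec()]) are
#' inserted last and recorded in `attr(network, "plants")`.
#'
#' @param params a `generator_params` object.
#' @param plant optional `plant_spec`.
#' @return A `regulatory_network` labelled `"reference"` with a `"plants"`
#'   attribute describing the inserted structures.
#' @export
generate_reference <- function(params, plant = NULL) {
  stopifnot(inherits(params, "generator_params"))
  if (!is.null(plant)) stopifnot(inherits(plant, "plant_spec"))
  set.seed(params$seed)

  ids <- c(sprintf("TF%04d", seq_len(params$n_tf)),
           sprintf("MIR%04d", seq_len(params$n_mirna)),
           sprintf("NTF%04d", seq_len(params$n_nontf)))
  roles <- rep(TRN_ROLES, c(params$n_tf, params$n_mirna, params$n_nontf))
  n <- length(ids)
  nodes <- data.frame(gene_id = ids, role = roles, stringsAsFactors = FALSE)

  regulators <- which(roles %in% TRN_REGULATOR_ROLES)
  mean_deg <- ifelse(roles[regulators] == "TF",
                     params$mean_out_degree_tf, params$mean_out_degree_mirna)
  degs <- integer(length(regulators))
  for (r in c("TF", "miRNA")) {
    sel <- roles[regulators] == r
    if (!any(sel)) next
    degs[sel] <- sample_out_degrees(sum(sel), mean_deg[sel][1],
                                    params$degree_tail_exponent, n - 1L)
  }
  src <- rep(regulators, degs)
  tgt <- integer(length(src))
  pos <- 1L
  for (k in seq_along(regulators)) {
    d <- degs[k]
    if (d == 0L) next
    cand <- seq_len(n)[-regulators[k]]
    tgt[pos:(pos + d - 1L)] <- sample(cand, d)
    pos <- pos + d
  }
  arcs <- data.frame(source = ids[src], target = ids[tgt], stringsAsFactors = FALSE)

  plants <- list(hubs = list(), motifs = list(), bowtie = NULL)
  if (!is.null(plant)) {
    # arc set as an environment-backed key set for O(1) dedup
    key <- function(s, t) paste(s, t, sep = "\r")
    arc_keys <- new.env(parent = emptyenv(), size = max(16L, 2L * nrow(arcs)))
    for (k in key(arcs$source, arcs$target)) assign(k, TRUE, envir = arc_keys)
    add_arcs <- function(s, t) {
      ks <- key(s, t)
      new <- !vapply(ks, exists, logical(1), envir = arc_keys)
      for (k in ks[new]) assign(k, TRUE, envir = arc_keys)
      arcs <<- rbind(arcs, data.frame(source = s[new], target = t[new],
                                      stringsAsFactors = FALSE))
    }
    drop_arcs_within <- function(triple) {
      inside <- arcs$source %in% triple & arcs$target %in% triple
      if (any(inside)) {
        for (k in key(arcs$source[inside], arcs$target[inside]))
          if (exists(k, envir = arc_keys)) rm(list = k, envir = arc_keys)
        arcs <<- arcs[!inside, , drop = FALSE]
      }
    }
    used <- character(0)                      # genes claimed by earlier plants
    claim <- function(role, k, what) {
      free <- ids[roles == role & !ids %in% used]
      if (length(free) < k)
        stop("not enough unclaimed ", role, " genes for planted ", what,
             " (need ", k, ", have ", length(free), ")")
      g <- free[seq_len(k)]
      used <<- c(used, g)
      g
    }

    for (i in seq_along(plant$hubs)) {
      h <- plant$hubs[[i]]
      if (any(h$tissues > params$n_tissues))
        stop("planted hub ", i, ": tissue index exceeds n_tissues")
      g <- claim(h$role, 1L, paste0("hub ", i))
      if (h$direction == "in") {
        partners <- ids[roles %in% TRN_REGULATOR_ROLES & ids != g]
        cur <- unique(arcs$source[arcs$target == g])
      } else {
        partners <- ids[ids != g]
        cur <- unique(arcs$target[arcs$source == g])
      }
      if (h$target_degree > length(partners))
        stop("planted hub ", i, " (", h$role, ", ", h$direction,
             "): target_degree ", h$target_degree, " exceeds the ",
             length(partners), " eligible partner vertices")
      need <- h$target_degree - length(cur)
      if (need > 0) {
        new <- sample(setdiff(partners, cur), need)
        if (h$direction == "in") add_arcs(new, rep(g, need)) else add_arcs(rep(g, need), new)
      }
      plants$hubs[[length(plants$hubs) + 1L]] <-
        list(gene_id = g, role = h$role, direction = h$direction,
             target_degree = h$target_degree, tissues = h$tissues)
    }

    for (i in seq_along(plant$motifs)) {
      m <- plant$motifs[[i]]
      if (any(m$tissues > params$n_tissues))
        stop("planted motif ", i, ": tissue index exceeds n_tissues")
      need <- table(factor(m$roles, levels = TRN_ROLES)) * m$n_instances
      pool <- lapply(TRN_ROLES, function(r) claim(r, need[[r]], paste0("motif ", i)))
      names(pool) <- TRN_ROLES
      taken <- setNames(rep(0L, 3L), TRN_ROLES)
      inst <- matrix("", nrow = m$n_instances, ncol = 3L)
      for (j in seq_len(m$n_instances)) {
        triple <- character(3L)
        for (p in 1:3) {
          r <- m$roles[p]
          taken[r] <- taken[r] + 1L
          triple[p] <- pool[[r]][taken[r]]
        }
        drop_arcs_within(triple)
        add_arcs(triple[m$arcs[, 1]], triple[m$arcs[, 2]])
        inst[j, ] <- triple
      }
      plants$motifs[[length(plants$motifs) + 1L]] <-
        list(roles = m$roles, arcs = m$arcs, instances = inst,
             genes = unique(as.vector(inst)), tissues = m$tissues)
    }

    if (!is.null(plant$bowtie)) {
      b <- plant$bowtie
      input <- claim("miRNA", b$n_input, "bow-tie input layer")
      core <- claim("TF", b$n_core, "bow-tie core layer")
      output <- claim("nonTF", b$n_output, "bow-tie output layer")
      ts_inst <- NULL
      for (j in seq_along(input)) {
        a <- core[(j - 1L) %% length(core) + 1L]
        cb <- core[j %% length(core) + 1L]
        triple <- c(input[j], a, cb)          # miRNA-TF-TF feed-forward loop
        drop_arcs_within(triple)
        add_arcs(c(input[j], input[j], a), c(a, cb, cb))
        ts_inst <- rbind(ts_inst, triple)
      }
      cm_inst <- NULL
      for (j in seq_along(output)) {
        # disjoint consecutive core pairs so n_output instances cover all
        # core genes whenever 2 * n_output >= n_core
        a <- core[(2L * j - 2L) %% length(core) + 1L]
        cb <- core[(2L * j - 1L) %% length(core) + 1L]
        triple <- c(a, cb, output[j])         # TF-TF-nonTF feed-forward loop
        drop_arcs_within(triple)
        add_arcs(c(a, a, cb), c(cb, output[j], output[j]))
        cm_inst <- rbind(cm_inst, triple)
      }
      plants$bowtie <- list(input = input, core = core, output = output,
                            ts_instances = ts_inst, cm_instances = cm_inst)
    }
  }

  net <- regulatory_network(nodes, arcs, label = "reference")
  attr(net, "plants") <- plants
  net
}

#' Generate binary tissue expression profiles
#'
#' Each tissue expresses all housekeeping genes (one fixed random fraction
#' shared by every tissue) plus its own random tissue-specific fraction;
#' any gene left unexpressed everywhere is assigned to one random tissue.
#' Plant annotations on the network are honoured: planted hub genes are
#' forced into their planted tissues, planted motif genes are expressed
#' exactly in their planted tissues, and planted bow-tie genes are
#' housekeeping.
#'
#' @param params the `generator_params` used for the network.
#' @param network the reference `regulatory_network` (typically from
#'   [generate_reference()]).
#' @return An object of class `expression_profile`: list with `tissues`
#'   (character vector `"tissue1"`, ...) and `expressed` (named list of
#'   gene-id vectors).
#' @export
generate_expression <- function(params, network) {
  stopifnot(inherits(params, "generator_params"),
            inherits(network, "regulatory_network"))
  set.seed(params$seed + 1L)
  genes <- network$nodes$gene_id
  n <- length(genes)
  tissues <- paste0("tissue", seq_len(params$n_tissues))
  plants <- attr(network, "plants") %||% list(hubs = list(), motifs = list(), bowtie = NULL)

  excl <- character(0)                        # expressed exactly in planted tissues
  excl_tissues <- list()
  for (m in plants$motifs) {
    excl <- c(excl, m$genes)
    excl_tissues <- c(excl_tissues, setNames(rep(list(m$tissues), length(m$genes)), m$genes))
  }
  forced_hk <- if (!is.null(plants$bowtie))
    c(plants$bowtie$input, plants$bowtie$core, plants$bowtie$output) else character(0)

  hk_n <- round(params$housekeeping_fraction * n)
  hk_pool <- setdiff(genes, c(excl, forced_hk))
  hk <- c(forced_hk, sample(hk_pool, max(0L, min(hk_n - length(forced_hk), length(hk_pool)))))

  ts_n <- round(params$tissue_specific_fraction * n)
  expressed <- setNames(vector("list", length(tissues)), tissues)
  for (ti in seq_along(tissues)) {
    pool <- setdiff(genes, c(hk, excl))
    spec <- if (ts_n > 0 && length(pool)) sample(pool, min(ts_n, length(pool))) else character(0)
    ex <- c(hk, spec)
    for (h in plants$hubs) if (ti %in% h$tissues) ex <- union(ex, h$gene_id)
    ex <- union(ex, names(excl_tissues)[vapply(excl_tissues, function(tt) ti %in% tt, logical(1))])
    expressed[[ti]] <- sort(ex)
  }

  never <- setdiff(genes, unique(unlist(expressed)))
  if (length(never)) {
    assign_to <- sample(length(tissues), length(never), replace = TRUE)
    for (k in seq_along(never)) {
      ti <- assign_to[k]
      expressed[[ti]] <- sort(c(expressed[[ti]], never[k]))
    }
  }
  structure(list(tissues = tissues, expressed = expressed),
            class = "expression_profile")
}

#' @export
print.expression_profile <- function(x, ...) {
  cat("expression_profile: ", length(x$tissues), " tissues, ",
      length(unique(unlist(x$expressed))), " genes expressed somewhere\n", sep = "")
  for (t in x$tissues) cat("  ", t, ": ", length(x$expressed[[t]]), " genes\n", sep = "")
  invisible(x)
}

#' Read / write binary expression profiles as long TSV
#'
#' Format: columns `gene_id`, `tissue`, `expressed` (0/1), one row per
#' gene x tissue pair.
#'
#' @param profile an `expression_profile`.
#' @param path TSV file path.
#' @param genes optional gene universe for writing; defaults to all genes
#'   seen in the profile.
#' @return `read_expression_tsv()` returns an `expression_profile`.
#' @export
write_expression_tsv <- function(profile, path, genes = NULL) {
  stopifnot(inherits(profile, "expression_profile"))
  genes <- genes %||% sort(unique(unlist(profile$expressed)))
  grid <- expand.grid(gene_id = genes, tissue = profile$tissues,
                      stringsAsFactors = FALSE)
  grid$expressed <- as.integer(mapply(function(g, t) g %in% profile$expressed[[t]],
                                      grid$gene_id, grid$tissue))
  write.table(grid, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(profile)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  d <- read.delim(path, colClasses = c("character", "character", "integer"))
  stopifnot(all(c("gene_id", "tissue", "expressed") %in% names(d)))
  tissues <- unique(d$tissue)
  expressed <- lapply(tissues, function(t)
    sort(d$gene_id[d$tissue == t & d$expressed == 1L]))
  structure(list(tissues = tissues, expressed = setNames(expressed, tissues)),
            class = "expression_profile")
}
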