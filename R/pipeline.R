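# End-to-end orchestration: simulate (or load) -> TRNs -> hubs -> sigma_RF
# -> motifs -> bow-tie, with per-stage derived seeds and TSV reports.

# deterministic per-stage seed derived from the global seed and stage name
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) + 9973 * h) %% 2147483647)
}

#' Pipeline configuration
#'
#' Validates and assembles all pipeline settings. Exactly one of `simulate`
#' (a list of [generator_params()] arguments, optionally with a `plant`
#' element) or `inputs` (list with `nodes`, `arcs` and `expression` TSV
#' paths) must be given.
#'
#' @param out_dir output directory (created if missing).
#' @param seed global integer seed; per-stage seeds are derived from it.
#' @param simulate optional list of generator settings.
#' @param inputs optional list of input file paths.
#' @param hub list: `n_random` (default 2000), `alpha` (0.01).
#' @param motif list: `n_random` (1000), `n_swap_factor` (10),
#'   `min_occurrence` (6), `max_p` (0.05), `min_z` (2.2).
#' @param bowtie list: `n_random` (5000), `kappa` (2), `tau_sym` (0.1),
#'   `normalization` (`"source"`).
#' @param sigma_rf list: `enabled` (TRUE), `n_random` (2000),
#'   `mode` (`"zscore"`).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed, simulate = NULL, inputs = NULL,
                            hub = list(), motif = list(), bowtie = list(),
                            sigma_rf = list()) {
  if (is.null(simulate) == is.null(inputs))
    stop("exactly one of 'simulate' or 'inputs' must be configured")
  if (!is.null(inputs)) {
    need <- c("nodes", "arcs", "expression")
    if (!all(need %in% names(inputs)))
      stop("inputs must name the 'nodes', 'arcs' and 'expression' files")
    missing <- need[!vapply(need, function(k) file.exists(inputs[[k]]), logical(1))]
    if (length(missing))
      stop("input file(s) not found: ",
           paste(unlist(inputs[missing]), collapse = ", "))
  }
  hub <- utils::modifyList(list(n_random = 2000, alpha = 0.01), hub)
  motif <- utils::modifyList(list(n_random = 1000, n_swap_factor = 10,
                                  min_occurrence = 6, max_p = 0.05,
                                  min_z = 2.2), motif)
  bowtie <- utils::modifyList(list(n_random = 5000, kappa = 2, tau_sym = 0.1,
                                   normalization = "source"), bowtie)
  sigma_rf <- utils::modifyList(list(enabled = TRUE, n_random = 2000,
                                     mode = "zscore"), sigma_rf)
  stopifnot(hub$n_random >= 1, motif$n_random >= 1, bowtie$n_random >= 1,
            sigma_rf$n_random >= 1, hub$alpha > 0, hub$alpha < 1,
            motif$max_p > 0, motif$max_p <= 1, motif$min_occurrence >= 1,
            bowtie$kappa > 0, bowtie$tau_sym >= 0,
            is.numeric(seed), abs(seed) < 2^31 - 1)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 simulate = simulate, inputs = inputs, hub = hub,
                 motif = motif, bowtie = bowtie, sigma_rf = sigma_rf),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' @param path YAML file whose top-level keys match the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

write_tsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full TRN-architecture pipeline
#'
#' Stages: obtain the reference network and expression profile (simulated
#' or loaded), build one TRN per tissue, call in-/out-hubs and build hub
#' profiles and active ratios, compute sigma_RF curves per role and
#' direction, run motif significance per tissue with CM/TS classification,
#' and decompose the CM/TS instances of every tissue into a bow-tie. All
#' stage outputs are written as TSV under `out_dir` together with a
#' `summary.txt`; every stage uses a seed derived deterministically from
#' the global seed, so rerunning an identical configuration reproduces all
#' outputs.
#'
#' @param config a `pipeline_config`.
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with all in-memory stage results.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[trnarch] ", ...)

  if (!is.null(config$simulate)) {
    sim <- config$simulate
    plant <- sim$plant
    sim$plant <- NULL
    sim$seed <- sim$seed %||% stage_seed(config$seed, "simulate")
    params <- do.call(generator_params, sim)
    say("simulating reference network (seed ", params$seed, ")")
    reference <- generate_reference(params, plant)
    profile <- generate_expression(params, reference)
  } else {
    say("loading reference network and expression profile")
    reference <- read_network_tsv(config$inputs$nodes, config$inputs$arcs,
                                  label = "reference")
    profile <- read_expression_tsv(config$inputs$expression)
  }
  write_network_tsv(reference,
                    file.path(config$out_dir, "reference_nodes.tsv"),
                    file.path(config$out_dir, "reference_arcs.tsv"))
  write_expression_tsv(profile, file.path(config$out_dir, "expression.tsv"),
                       genes = reference$nodes$gene_id)

  trns <- build_trns(reference, profile)
  deg <- do.call(rbind, lapply(trns, degree_table))
  write_tsv(deg, file.path(config$out_dir, "degree_table.tsv"))
  for (t in names(trns))
    write_network_tsv(trns[[t]],
                      file.path(config$out_dir, paste0("trn_", t, "_nodes.tsv")),
                      file.path(config$out_dir, paste0("trn_", t, "_arcs.tsv")))

  say("calling hubs (", config$hub$n_random, " random networks per TRN)")
  set.seed(stage_seed(config$seed, "hubs"))
  calls <- call_hubs_tissues(trns, n_random = config$hub$n_random,
                             alpha = config$hub$alpha)
  write_tsv(calls, file.path(config$out_dir, "hub_calls.tsv"))
  profiles <- hub_profiles(calls, trns)
  write_tsv(profiles, file.path(config$out_dir, "hub_profiles.tsv"))
  ar <- rbind(active_ratio_table(reference, trns, "in"),
              active_ratio_table(reference, trns, "out"))
  write_tsv(ar, file.path(config$out_dir, "active_ratios.tsv"))

  curves <- NULL
  if (isTRUE(config$sigma_rf$enabled)) {
    say("computing sigma_RF curves")
    set.seed(stage_seed(config$seed, "sigma_rf"))
    curves <- do.call(rbind, unlist(lapply(c("in", "out"), function(d)
      lapply(TRN_ROLES, function(r) {
        cur <- suppressWarnings(
          sigma_rf(calls, trns, d, r, n_random = config$sigma_rf$n_random,
                   mode = config$sigma_rf$mode))
        if (nrow(cur)) cbind(direction = d, role = r, cur) else NULL
      })), recursive = FALSE))
    if (!is.null(curves))
      write_tsv(curves, file.path(config$out_dir, "sigma_rf.tsv"))
  }

  say("motif significance (", config$motif$n_random, " switch-randomized networks per TRN)")
  set.seed(stage_seed(config$seed, "motifs"))
  motif_stats <- lapply(trns, function(trn)
    motif_significance(trn, n_random = config$motif$n_random,
                       n_swap_factor = config$motif$n_swap_factor,
                       min_occurrence = config$motif$min_occurrence,
                       max_p = config$motif$max_p, min_z = config$motif$min_z))
  write_tsv(do.call(rbind, motif_stats),
            file.path(config$out_dir, "motif_stats.tsv"))
  catalog <- classify_cm_ts(motif_stats)
  write_tsv(catalog, file.path(config$out_dir, "motif_catalog.tsv"))

  say("bow-tie decomposition (", config$bowtie$n_random, " permutations per TRN)")
  cm_sigs <- catalog$signature[catalog$label == "CM"]
  ts_sigs <- catalog$signature[catalog$label == "TS"]
  bowties <- list()
  layer_rows <- stat_rows <- pattern_rows <- NULL
  for (t in names(trns)) {
    inst <- attr(motif_stats[[t]], "instances")
    sig_tab <- motif_stats[[t]]
    sig_here <- sig_tab$signature[sig_tab$significant]
    cm_inst <- inst[inst$signature %in% intersect(cm_sigs, sig_here), , drop = FALSE]
    ts_inst <- inst[inst$signature %in% intersect(ts_sigs, sig_here), , drop = FALSE]
    if (nrow(cm_inst) + nrow(ts_inst) == 0) {
      pattern_rows <- rbind(pattern_rows,
                            data.frame(tissue = t, sr_input = NA, sr_core = NA,
                                       sr_output = NA, pattern = "unclassified",
                                       degenerate = TRUE, stringsAsFactors = FALSE))
      next
    }
    bt <- suppressWarnings(
      bowtie_decompose(cm_inst, ts_inst, trns[[t]],
                       n_random = config$bowtie$n_random,
                       seed = stage_seed(config$seed, paste0("bowtie_", t)),
                       kappa = config$bowtie$kappa,
                       tau_sym = config$bowtie$tau_sym,
                       normalization = config$bowtie$normalization))
    bowties[[t]] <- bt
    lay <- data.frame(tissue = t,
                      gene_id = c(bt$noncore_ts, bt$core, bt$noncore_cm),
                      layer = rep(c("input", "core", "output"),
                                  c(length(bt$noncore_ts), length(bt$core),
                                    length(bt$noncore_cm))),
                      stringsAsFactors = FALSE)
    layer_rows <- rbind(layer_rows, lay)
    if (!is.null(bt$tests)) {
      comp <- cbind(tissue = t, statistic = "composition", bt$tests$composition)
      names(comp)[names(comp) == "layer"] <- "unit1"
      names(comp)[names(comp) == "role"] <- "unit2"
      degs <- cbind(tissue = t, statistic = "average_degree", bt$tests$degree)
      names(degs)[names(degs) == "from_layer"] <- "unit1"
      names(degs)[names(degs) == "to_layer"] <- "unit2"
      stat_rows <- rbind(stat_rows, comp, degs)
    }
    pattern_rows <- rbind(pattern_rows,
                          data.frame(tissue = t,
                                     sr_input = bt$size_ratios[["input"]],
                                     sr_core = bt$size_ratios[["core"]],
                                     sr_output = bt$size_ratios[["output"]],
                                     pattern = bt$pattern,
                                     degenerate = bt$degenerate,
                                     stringsAsFactors = FALSE))
  }
  if (!is.null(layer_rows))
    write_tsv(layer_rows, file.path(config$out_dir, "bowtie_layers.tsv"))
  if (!is.null(stat_rows))
    write_tsv(stat_rows, file.path(config$out_dir, "bowtie_stats.tsv"))
  if (!is.null(pattern_rows))
    write_tsv(pattern_rows, file.path(config$out_dir, "bowtie_patterns.tsv"))

  summary_path <- file.path(config$out_dir, "summary.txt")
  con <- file(summary_path, "w")
  on.exit(close(con), add = TRUE)
  wl <- function(...) writeLines(paste0(...), con)
  wl("trnarch pipeline summary (seed ", config$seed, ")")
  wl("")
  wl("TRN sizes:")
  for (t in names(trns))
    wl(sprintf("  %-12s %6d vertices %7d arcs", t, n_vertices(trns[[t]]),
               n_arcs(trns[[t]])))
  wl("")
  wl("Hubs in at least one tissue, by role and direction:")
  for (d in c("in", "out")) for (r in TRN_ROLES) {
    sub <- profiles[profiles$direction == d & profiles$role == r, ]
    wl(sprintf("  %-6s %-4s-hubs: %d", r, d, sum(sub$n_hub > 0)))
  }
  wl("")
  wl(sprintf("Motifs: %d CM, %d TS (of %d signatures observed)",
             sum(catalog$label == "CM"), sum(catalog$label == "TS"),
             nrow(catalog)))
  wl("")
  wl("Bow-tie patterns:")
  if (!is.null(pattern_rows))
    for (i in seq_len(nrow(pattern_rows)))
      wl(sprintf("  %-12s %s%s", pattern_rows$tissue[i], pattern_rows$pattern[i],
                 if (isTRUE(pattern_rows$degenerate[i])) " (degenerate)" else ""))

  invisible(list(reference = reference, profile = profile, trns = trns,
                 hub_calls = calls, hub_profiles = profiles,
                 active_ratios = ar, sigma_rf = curves,
                 motif_stats = motif_stats, motif_catalog = catalog,
                 bowties = bowties, patterns = pattern_rows))
}
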