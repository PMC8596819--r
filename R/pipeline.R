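
# The run drivers: one docking experiment from a configuration, sequential
# benchmarking over many configurations, and the analysis runner.

#' Run one docking experiment from a configuration
#'
#' Reads ligands, enumerates states, embeds in 3D, docks against the
#' configured backend and writes the score table (CSV) and poses (SDF)
#' according to the configured write-out mode. Per-ligand failures are
#' carried and counted, never fatal.
#'
#' @param config A `run_configuration` from [parse_run_config()] /
#'   [load_run_config()].
#' @return A run summary: list with counts (`ligands_in`, `ligands_parsed`,
#'   `enumerations`, `embedded`, `docked`, `failed`), the output paths and
#'   the score table.
#' @export
run_docking <- function(config) {
  stopifnot(inherits(config, "run_configuration"))
  emb <- config$embedding
  if (emb$embedder != "builtin")
    fail("embedder '%s' is an external adapter; only 'builtin' is runnable",
         emb$embedder)
  ligs <- read_ligands(emb$input$path, emb$input$format)
  n_in <- length(ligs)
  log_msg("run_docking: %d ligand(s) read from %s", n_in, emb$input$path)

  ff <- if (emb$parameters$force_field %in%
            c("UFF", "MMFF94", "MMFF94s", "GAFF", "Ghemical"))
    emb$parameters$force_field else "UFF"
  espec <- embedder_spec(force_field = ff,
                         max_iterations = emb$parameters$max_iterations)
  cores <- emb$parallelization$cores
  mpc <- emb$parallelization$max_compounds_per_core

  prep_one <- function(l) {
    l <- enumerate_states(l, enumerate_stereo = emb$enumeration$stereo,
                          enumerate_tautomers = emb$enumeration$tautomers,
                          max_states = emb$enumeration$max_states)
    embed_3d(l, espec)
  }
  prepped <- if (cores > 1L && .Platform$OS.type == "unix") {
    chunks <- split(unclass(ligs), ceiling(seq_along(ligs) / mpc))
    unlist(parallel::mclapply(chunks, function(ch) lapply(ch, prep_one),
                              mc.cores = cores),
           recursive = FALSE, use.names = FALSE)
  } else lapply(ligs, prep_one)
  ligs <- ligand_set(prepped)
  enums <- all_enumerations(ligs)
  n_embedded <- sum(vapply(enums, function(e)
    !isTRUE(e$failed) && !is.null(e$molblock), TRUE))
  log_msg("run_docking: %d enumeration(s), %d embedded", length(enums),
          n_embedded)
  if (!is.null(emb$output$path)) write_ligands(ligs, emb$output$path, "sdf")

  receptor <- config$docking$receptor
  if (is.character(receptor)) receptor <- read_receptor(receptor)
  else if (!inherits(receptor, "receptor_profile"))
    receptor <- receptor_profile(receptor$identifier %||% "receptor",
                                 cavity = receptor$cavity,
                                 synthetic = if (!is.null(receptor$synthetic)) {
                                   s <- receptor$synthetic
                                   s$target <- unlist(s$target)
                                   s
                                 },
                                 external = receptor$external)
  report <- dock_batch(enums, receptor, backend = config$docking$backend,
                       cores = cores, max_per_core = mpc,
                       params = config$docking$parameters)
  names_map <- stats::setNames(vapply(ligs, `[[`, "", "name"),
                               vapply(ligs, `[[`, "", "ligand_id"))
  tab <- collate_writeout(report, config$docking$write_out_mode,
                          names = names_map)
  utils::write.csv(tab, config$output$scores_path, row.names = FALSE)
  if (!is.null(config$output$poses_path))
    write_poses_sdf(report, config$output$poses_path,
                    config$docking$write_out_mode)
  n_failed <- sum(vapply(ligs, function(l) isTRUE(l$failed), TRUE)) +
    nrow(report$failures)
  log_msg("run_docking: %d ligand(s) scored, %d failure(s); scores -> %s",
          length(unique(tab$ligand_id)), n_failed,
          config$output$scores_path)
  list(ligands_in = n_in,
       ligands_parsed = sum(!vapply(ligs, function(l) isTRUE(l$failed), TRUE)),
       enumerations = length(enums),
       embedded = n_embedded,
       docked = length(unique(report$poses$ligand_id)),
       failed = n_failed,
       scores_path = config$output$scores_path,
       poses_path = config$output$poses_path,
       scores = tab,
       ok = TRUE)
}

#' Run many docking experiments sequentially
#'
#' Executes each configuration in input order. A failing run is recorded in
#' its summary (with `ok = FALSE` and the error message) and does not abort
#' the remaining runs; the result always has exactly one summary per
#' configuration.
#'
#' @param configs List of `run_configuration` objects or paths to
#'   configuration JSON files (possibly mixed). An empty list returns an
#'   empty list.
#' @return List of run summaries, in input order.
#' @export
run_benchmark <- function(configs) {
  stopifnot(is.list(configs) || is.character(configs))
  if (is.character(configs)) configs <- as.list(configs)
  out <- vector("list", length(configs))
  for (i in seq_along(configs)) {
    log_msg("run_benchmark: configuration %d / %d", i, length(configs))
    out[[i]] <- tryCatch({
      cfg <- configs[[i]]
      if (is.character(cfg)) cfg <- load_run_config(cfg)
      run_docking(cfg)
    }, error = function(e) {
      log_msg("run_benchmark: configuration %d failed: %s", i,
              conditionMessage(e))
      list(ok = FALSE, error = conditionMessage(e))
    })
  }
  out
}

#' Run an analysis over one or more score files
#'
#' Enrichment mode expects labeled score CSVs (`ligand_id`, `score`,
#' `label`) and reports pROC and ROC AUC per input; correlation mode expects
#' paired CSVs (`ligand_id`, `score`, `exp_value`) and reports Spearman rho
#' and Kendall tau-b with tie counts; thresholds mode reports the
#' TP/FP/FN/TN quadrant of each input against the configured boundaries
#' (a value exactly at a threshold counts as active). An unreadable or empty
#' input is reported as failed; the remaining inputs proceed. The combined
#' comparison table is written as CSV when the configuration names an output
#' path.
#'
#' @param conf An `analysis_configuration`.
#' @param tables Optional list of pre-loaded inputs (same length as
#'   `conf$inputs`): [labeled_scores()] for enrichment, data.frames with
#'   `score` and `exp_value` columns otherwise. When NULL, inputs are read
#'   from the configured paths.
#' @return The combined report data.frame (one row per input).
#' @export
run_analysis <- function(conf, tables = NULL) {
  stopifnot(inherits(conf, "analysis_configuration"))
  if (!is.null(tables) && length(tables) != length(conf$inputs))
    fail("`tables` must match the configured inputs in length")
  rows <- vector("list", length(conf$inputs))
  for (i in seq_along(conf$inputs)) {
    inp <- conf$inputs[[i]]
    rows[[i]] <- tryCatch({
      if (conf$mode == "enrichment") {
        d <- if (!is.null(tables)) tables[[i]] else {
          ls0 <- read_labeled_scores(inp$scores)
          labeled_scores(ls0$ligand_id, ls0$score, ls0$label,
                         direction = inp$direction)
        }
        e <- proc_auc(d)
        data.frame(input = inp$scores %||% sprintf("table%d", i),
                   status = "ok", n = e$n, proc_auc = e$proc_auc,
                   roc_auc = e$roc_auc, n_clipped = e$n_clipped)
      } else {
        pm <- if (!is.null(tables) && inherits(tables[[i]],
                                               "paired_measurements"))
          tables[[i]]
        else {
          df <- if (!is.null(tables)) tables[[i]]
                else utils::read.csv(inp$scores, stringsAsFactors = FALSE)
          if (!nrow(df)) fail("empty input")
          if (!all(c("score", "exp_value") %in% names(df)))
            fail("need columns score and exp_value")
          paired_measurements(df$score, df$exp_value,
                              dock_direction = inp$direction,
                              exp_direction = inp$exp_direction)
        }
        if (conf$mode == "correlation") {
          s <- spearman_rho(pm); k <- kendall_tau_b(pm)
          data.frame(input = inp$scores %||% sprintf("table%d", i),
                     status = "ok", n = pm$n, rho = s$rho, tau_b = k$tau_b,
                     C = k$C, D = k$D, T_dock = k$T_dock, T_exp = k$T_exp)
        } else {
          t <- thresholds_report(pm, conf$parameters$score_threshold,
                                 conf$parameters$exp_threshold)
          data.frame(input = inp$scores %||% sprintf("table%d", i),
                     status = "ok", n = pm$n,
                     TP = t$counts[["TP"]], FP = t$counts[["FP"]],
                     FN = t$counts[["FN"]], TN = t$counts[["TN"]])
        }
      }
    }, error = function(e) {
      data.frame(input = conf$inputs[[i]]$scores %||% sprintf("table%d", i),
                 status = paste0("failed: ", conditionMessage(e)))
    })
  }
  # align columns across ok/failed rows
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (cn in setdiff(cols, names(r))) r[[cn]] <- NA
    r[cols]
  })
  report <- do.call(rbind, rows)
  if (!is.null(conf$output))
    utils::write.csv(report, conf$output, row.names = FALSE)
  report
}
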