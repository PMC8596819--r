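
# JSON run/analysis configurations. Validation is strict and total: every
# input either yields a fully defaulted, validated configuration object or a
# structured error naming the offending key path -- unknown keys are errors
# (they are almost always typos that free-form JSON would silently ignore).

# embedders a configuration may name; only "builtin" is runnable here, the
# others are external adapter ids accepted for configuration exchange
EMBEDDER_REGISTRY <- c("builtin", "corina", "ligprep", "omega", "rdkit")

WRITE_OUT_MODES <- c("best_per_ligand", "best_per_enumeration", "all")

check_keys <- function(block, allowed, path) {
  extra <- setdiff(names(block), allowed)
  if (length(extra))
    fail("unknown key '%s.%s' (allowed: %s)", path, extra[1L],
         paste(allowed, collapse = ", "))
}

need_block <- function(block, key, path) {
  if (is.null(block[[key]]))
    fail("missing required block '%s.%s'", path, key)
  block[[key]]
}

resolve_path <- function(p, base_dir) {
  if (is.null(p) || is.null(base_dir)) return(p)
  if (grepl("^(/|~|[A-Za-z]:)", p)) p else file.path(base_dir, p)
}

#' Parse and validate a docking run configuration
#'
#' The configuration dialect has three blocks. `embedding` mirrors the
#' classic ligand-preparation layout (`parallelization` with `cores` and
#' `max_compounds_per_core`, embedder `parameters` including target pH,
#' pH tolerance, force field and maximum minimization iterations, an
#' `input` path/format and an optional `output` path for embedded ligands);
#' `docking` names the backend, the receptor (inline object or JSON path),
#' backend `parameters` such as poses-per-ligand, and the `write_out_mode`;
#' `output` gives the poses and scores paths. Relative paths are resolved
#' against `base_dir` (the configuration file's directory, not the working
#' directory). A missing `schema_version` means version 1.
#'
#' @param json_text JSON text.
#' @param base_dir Directory for resolving relative paths (optional).
#' @return An object of class `run_configuration` with all defaults filled.
#' @export
parse_run_config <- function(json_text, base_dir = NULL) {
  j <- tryCatch(jsonlite::fromJSON(json_text, simplifyVector = TRUE,
                                   simplifyDataFrame = FALSE),
                error = function(e) fail("malformed JSON: %s",
                                         conditionMessage(e)))
  if (!is.list(j)) fail("configuration must be a JSON object")
  check_keys(j, c("schema_version", "embedding", "docking", "output"), "$")
  version <- j$schema_version %||% 1L
  if (!is_count(version, 1)) fail("schema_version must be a positive integer")

  emb <- need_block(j, "embedding", "$")
  check_keys(emb, c("embedder", "parallelization", "parameters",
                    "enumeration", "input", "output"), "embedding")
  embedder <- emb$embedder %||% "builtin"
  if (!is_string(embedder) || !embedder %in% EMBEDDER_REGISTRY)
    fail("unknown embedder '%s'; registry: %s", embedder,
         paste(EMBEDDER_REGISTRY, collapse = ", "))
  par <- emb$parallelization %||% list()
  check_keys(par, c("cores", "max_compounds_per_core"),
             "embedding.parallelization")
  cores <- par$cores %||% 1L
  mpc <- par$max_compounds_per_core %||% 32L
  if (!is_count(cores, 1)) fail("embedding.parallelization.cores must be >= 1")
  if (!is_count(mpc, 1))
    fail("embedding.parallelization.max_compounds_per_core must be >= 1")
  pars <- emb$parameters %||% list()
  check_keys(pars, c("target_ph", "ph_tolerance", "force_field",
                     "max_iterations"), "embedding.parameters")
  target_ph <- pars$target_ph %||% 7.0
  ph_tol <- pars$ph_tolerance %||% 2.0
  if (!is_num(target_ph) || !is_num(ph_tol) || ph_tol < 0)
    fail("embedding.parameters: pH settings must be finite (tolerance >= 0)")
  force_field <- pars$force_field %||% "UFF"
  max_iter <- pars$max_iterations %||% 600L
  if (!is_count(max_iter, 1))
    fail("embedding.parameters.max_iterations must be >= 1")
  enum <- emb$enumeration %||% list()
  check_keys(enum, c("stereo", "tautomers", "max_states"),
             "embedding.enumeration")
  inp <- need_block(emb, "input", "embedding")
  check_keys(inp, c("path", "format"), "embedding.input")
  if (!is_string(inp$path %||% NULL)) fail("embedding.input.path is required")
  fmt <- inp$format %||% "auto"
  if (!fmt %in% c("auto", "smiles", "sdf"))
    fail("embedding.input.format must be auto, smiles or sdf")
  eout <- emb$output %||% list()
  check_keys(eout, "path", "embedding.output")

  dock <- need_block(j, "docking", "$")
  check_keys(dock, c("backend", "receptor", "parameters", "write_out_mode"),
             "docking")
  backend <- dock$backend %||% "synthetic"
  if (!is_string(backend) || !backend %in% list_backends())
    fail("unknown docking backend '%s'; registry: %s", backend,
         paste(list_backends(), collapse = ", "))
  mode <- dock$write_out_mode %||% "best_per_ligand"
  if (!is_string(mode) || !mode %in% WRITE_OUT_MODES)
    fail("docking.write_out_mode must be one of: %s",
         paste(WRITE_OUT_MODES, collapse = ", "))
  dpars <- dock$parameters %||% list()
  check_keys(dpars, "poses", "docking.parameters")
  poses <- dpars$poses %||% 1L
  if (!is_count(poses, 1)) fail("docking.parameters.poses must be >= 1")
  receptor <- dock$receptor
  if (is.null(receptor)) fail("docking.receptor is required")

  out <- need_block(j, "output", "$")
  check_keys(out, c("poses_path", "scores_path"), "output")
  if (!is_string(out$scores_path %||% NULL))
    fail("output.scores_path is required")

  structure(list(
    schema_version = as.integer(version),
    embedding = list(
      embedder = embedder,
      parallelization = list(cores = as.integer(cores),
                             max_compounds_per_core = as.integer(mpc)),
      parameters = list(target_ph = as.numeric(target_ph),
                        ph_tolerance = as.numeric(ph_tol),
                        force_field = force_field,
                        max_iterations = as.integer(max_iter)),
      enumeration = list(stereo = isTRUE(enum$stereo %||% TRUE),
                         tautomers = isTRUE(enum$tautomers %||% FALSE),
                         max_states = as.integer(enum$max_states %||% 32L)),
      input = list(path = resolve_path(inp$path, base_dir), format = fmt),
      output = list(path = resolve_path(eout$path %||% NULL, base_dir))
    ),
    docking = list(
      backend = backend,
      receptor = if (is.character(receptor)) resolve_path(receptor, base_dir)
                 else receptor,
      parameters = list(poses = as.integer(poses)),
      write_out_mode = mode
    ),
    output = list(poses_path = resolve_path(out$poses_path %||% NULL, base_dir),
                  scores_path = resolve_path(out$scores_path, base_dir))
  ), class = "run_configuration")
}

#' Load a run configuration from a file
#'
#' Relative paths inside the file resolve against the file's own directory.
#'
#' @param path JSON file path.
#' @return A `run_configuration`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) fail("configuration file not found: %s", path)
  parse_run_config(paste(readLines(path, warn = FALSE), collapse = "\n"),
                   base_dir = dirname(normalizePath(path)))
}

#' Serialize a run configuration back to JSON
#'
#' Writes the fully defaulted form; `parse_run_config()` of the output
#' reproduces the same configuration.
#'
#' @param config A `run_configuration`.
#' @return JSON text.
#' @export
serialize_run_config <- function(config) {
  stopifnot(inherits(config, "run_configuration"))
  jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                   null = "null", pretty = TRUE)
}

#' Parse and validate an analysis configuration
#'
#' An `analysis` block with a `mode` (`enrichment`, `correlation` or
#' `thresholds`), one or more `inputs` (each a score CSV with per-input
#' direction flags), mode `parameters` (thresholds mode requires
#' `score_threshold` and `exp_threshold`) and an optional report `output`
#' path.
#'
#' @param json_text JSON text.
#' @param base_dir Directory for resolving relative paths (optional).
#' @return An object of class `analysis_configuration`.
#' @export
parse_analysis_config <- function(json_text, base_dir = NULL) {
  j <- tryCatch(jsonlite::fromJSON(json_text, simplifyVector = TRUE,
                                   simplifyDataFrame = FALSE),
                error = function(e) fail("malformed JSON: %s",
                                         conditionMessage(e)))
  if (!is.list(j)) fail("configuration must be a JSON object")
  check_keys(j, c("schema_version", "analysis"), "$")
  a <- need_block(j, "analysis", "$")
  check_keys(a, c("mode", "inputs", "parameters", "output"), "analysis")
  mode <- a$mode %||% NULL
  if (!is_string(mode) || !mode %in% c("enrichment", "correlation",
                                       "thresholds"))
    fail("analysis.mode must be enrichment, correlation or thresholds")
  inputs <- a$inputs
  if (!is.list(inputs) || !length(inputs))
    fail("analysis.inputs needs at least one entry")
  inputs <- lapply(seq_along(inputs), function(i) {
    x <- inputs[[i]]
    if (is.character(x)) x <- list(scores = x)
    check_keys(x, c("scores", "direction", "exp_direction"),
               sprintf("analysis.inputs[%d]", i))
    if (!is_string(x$scores %||% NULL))
      fail("analysis.inputs[%d].scores is required", i)
    dir <- x$direction %||% "lower_better"
    edir <- x$exp_direction %||% "higher_better"
    if (!dir %in% c("lower_better", "higher_better") ||
        !edir %in% c("lower_better", "higher_better"))
      fail("analysis.inputs[%d]: bad direction flag", i)
    list(scores = resolve_path(x$scores, base_dir), direction = dir,
         exp_direction = edir)
  })
  pars <- a$parameters %||% list()
  check_keys(pars, c("score_threshold", "exp_threshold"),
             "analysis.parameters")
  if (mode == "thresholds") {
    if (!is_num(pars$score_threshold %||% NULL) ||
        !is_num(pars$exp_threshold %||% NULL))
      fail("thresholds mode requires analysis.parameters.score_threshold and exp_threshold")
  }
  structure(list(mode = mode, inputs = inputs, parameters = pars,
                 output = resolve_path(a$output %||% NULL, base_dir)),
            class = "analysis_configuration")
}

#' @rdname parse_analysis_config
#' @param path JSON file path.
#' @export
load_analysis_config <- function(path) {
  if (!file.exists(path)) fail("configuration file not found: %s", path)
  parse_analysis_config(paste(readLines(path, warn = FALSE), collapse = "\n"),
                        base_dir = dirname(normalizePath(path)))
}
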