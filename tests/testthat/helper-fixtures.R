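# Shared fixtures, built in code at test time.

quiet <- function(expr) suppressMessages(expr)

# a small embedded ligand set over the toy grammar (built once per process)
fixture_ligands <- local({
  cache <- NULL
  function(n = 8, seed = 101) {
    key <- paste(n, seed)
    if (!is.null(cache) && identical(cache$key, key)) return(cache$value)
    smis <- generate_toy_library(n, seed)
    ls0 <- ligand_set(lapply(seq_along(smis), function(i)
      enumerate_states(ligand(sprintf("L%02d", i), smis[i]))))
    value <- embed_3d(ls0, embedder_spec(minimize = FALSE))
    cache <<- list(key = key, value = value)
    value
  }
})

fixture_receptor <- function(ref = NULL) example_receptor(ref_smiles = ref)

# write a minimal run configuration into dir and return its path
fixture_run_config <- function(dir, input = "lib.smi", backend = "synthetic",
                               mode = "best_per_ligand", cores = 1) {
  write_receptor(fixture_receptor(), file.path(dir, "receptor.json"))
  cfg <- sprintf('{
  "embedding": {
    "embedder": "builtin",
    "parallelization": {"cores": %d, "max_compounds_per_core": 4},
    "parameters": {"max_iterations": 50},
    "input": {"path": "%s", "format": "smiles"}
  },
  "docking": {"backend": "%s", "receptor": "receptor.json",
              "write_out_mode": "%s"},
  "output": {"poses_path": "poses.sdf", "scores_path": "scores.csv"}
}', cores, input, backend, mode)
  path <- file.path(dir, "run.json")
  writeLines(cfg, path)
  path
}

# constant-raw-value scoring component (no chemistry involved)
const_component <- function(name, value, weight = 1) {
  component_spec(name, provider = function(smiles) rep(value, length(smiles)),
                 transform = transform_spec("linear_clip", 0, 1),
                 weight = weight)
}
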