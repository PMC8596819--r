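
# The docking-backend contract and registry. A backend declares its score
# direction at registration (engines disagree: most score lower-better, GOLD
# fitness is higher-better) and a dock function that never raises for a bad
# ligand -- it returns a failure record instead.

.backends <- new.env(parent = emptyenv())

#' Register a docking backend
#'
#' @param name Backend name (registry key).
#' @param score_direction `"lower_better"` or `"higher_better"`.
#' @param dock Function `(enumeration, receptor, params)` returning a list
#'   with either `poses` (data.frame with column `score`, optionally a
#'   `molblock` character column) or `failure` (reason string).
#' @param max_poses Default poses-per-ligand cap (default 1).
#' @param embeds_internally Does the backend accept coordinate-less
#'   enumerations? (default FALSE)
#' @param enabled Is the backend runnable in this session? Adapter stubs for
#'   external engines register disabled until configured.
#' @return Invisibly, the backend contract object.
#' @export
register_backend <- function(name, score_direction, dock, max_poses = 1L,
                             embeds_internally = FALSE, enabled = TRUE) {
  stopifnot(is_string(name), is.function(dock))
  if (!score_direction %in% c("lower_better", "higher_better"))
    fail("score_direction must be 'lower_better' or 'higher_better'")
  contract <- structure(list(
    name = name, score_direction = score_direction, dock = dock,
    max_poses = as.integer(max_poses),
    embeds_internally = isTRUE(embeds_internally), enabled = isTRUE(enabled)
  ), class = "backend_contract")
  assign(name, contract, envir = .backends)
  invisible(contract)
}

#' Look up a registered backend
#'
#' @param name Backend name.
#' @return The `backend_contract`.
#' @export
get_backend <- function(name) {
  if (!is_string(name) || !exists(name, envir = .backends))
    fail("unknown docking backend '%s'; registered: %s", name,
         paste(list_backends(), collapse = ", "))
  get(name, envir = .backends)
}

#' @rdname get_backend
#' @export
list_backends <- function() sort(ls(envir = .backends))

# Adapter stubs for external engines: the contract (name, direction) is
# registered so configurations naming them validate, but they refuse to run
# until an executable is configured. Directions follow the engines' own
# conventions.
register_external_stubs <- function() {
  ext <- list(vina = "lower_better", glide = "lower_better",
              gold = "higher_better", hybrid = "lower_better",
              rdock = "lower_better")
  for (nm in names(ext)) {
    local({
      n <- nm
      register_backend(n, ext[[n]], function(enumeration, receptor, params) {
        list(failure = sprintf(
          "backend '%s' is an external adapter; configure its executable", n))
      }, enabled = FALSE)
    })
  }
}
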