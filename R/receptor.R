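
# Receptor profiles. For the synthetic backend a receptor is a target vector
# in physicochemical descriptor space plus component weights; for external
# adapter backends it is an opaque grid payload path.

#' Create a receptor profile
#'
#' @param identifier Receptor id (string).
#' @param cavity Optional binding-cavity definition: a list with `center`
#'   (xyz, Angstrom) and `size` (edge lengths, Angstrom, default
#'   `c(15, 15, 15)`), or `ref_ligand` coordinates.
#' @param synthetic Optional synthetic payload: list with `target` (named
#'   numeric descriptor vector), `weights` (same length, default all 1),
#'   `scales` (per-descriptor similarity length scales, default built in) and
#'   optional `ref_smiles` (reference ligand for the hashed-fragment
#'   similarity component, weighted by `fragment_weight`, default 1).
#' @param external Optional opaque payload for adapter backends: list with at
#'   least `path`.
#' @return An object of class `receptor_profile`.
#' @export
receptor_profile <- function(identifier, cavity = NULL, synthetic = NULL,
                             external = NULL) {
  stopifnot(is_string(identifier))
  if (!is.null(cavity) && !is.null(cavity$size)) {
    if (length(cavity$size) != 3L || any(cavity$size <= 0))
      fail("cavity box edges must be three positive lengths")
  }
  if (!is.null(synthetic)) {
    tg <- synthetic$target
    if (is.null(names(tg)) || !is.numeric(tg))
      fail("synthetic$target must be a named numeric vector")
    bad <- setdiff(names(tg), SYNTHETIC_DESCRIPTORS)
    if (length(bad))
      fail("unknown synthetic descriptor(s): %s (available: %s)",
           paste(bad, collapse = ", "),
           paste(SYNTHETIC_DESCRIPTORS, collapse = ", "))
    synthetic$weights <- synthetic$weights %||% rep(1, length(tg))
    if (length(synthetic$weights) != length(tg))
      fail("synthetic$weights must match synthetic$target in length")
    synthetic$scales <- synthetic$scales %||%
      unname(SYNTHETIC_SCALES[names(tg)])
    if (length(synthetic$scales) != length(tg))
      fail("synthetic$scales must match synthetic$target in length")
    synthetic$fragment_weight <- synthetic$fragment_weight %||%
      (if (is.null(synthetic$ref_smiles)) 0 else 1)
  }
  structure(list(identifier = identifier, cavity = cavity,
                 synthetic = synthetic, external = external),
            class = "receptor_profile")
}

# descriptor vocabulary of the synthetic backend, with default length scales
SYNTHETIC_DESCRIPTORS <- c("n_heavy", "n_rings", "hbd", "hba", "mw", "logp",
                           "tpsa")
SYNTHETIC_SCALES <- c(n_heavy = 5, n_rings = 1, hbd = 1, hba = 1.5, mw = 75,
                      logp = 1.5, tpsa = 30)

#' Read / write a receptor profile as JSON
#'
#' @param path JSON file path.
#' @return `read_receptor()` returns a `receptor_profile`;
#'   `write_receptor()` invisibly returns `path`.
#' @export
read_receptor <- function(path) {
  if (!file.exists(path)) fail("receptor file not found: %s", path)
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  syn <- j$synthetic
  if (!is.null(syn)) syn$target <- unlist(syn$target)
  receptor_profile(j$identifier, cavity = j$cavity, synthetic = syn,
                   external = j$external)
}

#' @rdname read_receptor
#' @param receptor A `receptor_profile`.
#' @export
write_receptor <- function(receptor, path) {
  stopifnot(inherits(receptor, "receptor_profile"))
  obj <- unclass(receptor)
  if (!is.null(obj$synthetic))
    obj$synthetic$target <- as.list(obj$synthetic$target)  # keep names in JSON
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' A ready-made synthetic receptor for examples and fixtures
#'
#' A drug-like target profile (mid-sized, moderately polar binder) with a
#' 15 Angstrom cubic cavity, usable with the `"synthetic"` backend out of the
#' box.
#'
#' @param identifier Receptor id.
#' @param ref_smiles Optional reference ligand for the fragment-similarity
#'   component.
#' @return A `receptor_profile`.
#' @export
example_receptor <- function(identifier = "synthetic-target",
                             ref_smiles = NULL) {
  receptor_profile(
    identifier,
    cavity = list(center = c(0, 0, 0), size = c(15, 15, 15)),
    synthetic = list(
      target = c(n_heavy = 24, n_rings = 3, hbd = 2, hba = 4, mw = 340,
                 logp = 2.5, tpsa = 75),
      ref_smiles = ref_smiles
    )
  )
}
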