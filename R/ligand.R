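
# Ligand and enumeration records. A ligand is an input compound; its
# enumerations are the specific tautomer/stereoisomer states that actually get
# embedded and docked. Failed ligands are carried through the pipeline as
# flagged records (never silently dropped) so every run can report its failure
# counts.

#' Create a ligand record
#'
#' @param ligand_id Stable identifier, unique within a run.
#' @param smiles Input SMILES string.
#' @param name Optional human-readable name.
#' @return An object of class `ligand`. If the SMILES does not parse the
#'   ligand is returned flagged as failed rather than raising an error.
#' @export
ligand <- function(ligand_id, smiles, name = NULL) {
  stopifnot(is_string(ligand_id), is_string(smiles))
  can <- canonical_smiles(smiles)
  failed <- is.na(can)
  structure(list(
    ligand_id = ligand_id,
    input_smiles = smiles,
    name = name %||% ligand_id,
    canonical = if (failed) NA_character_ else can,
    failed = failed,
    fail_reason = if (failed) "unparsable SMILES" else NA_character_,
    enumerations = list()
  ), class = "ligand")
}

#' Create an enumeration record
#'
#' One tautomer/stereoisomer state of a parent ligand.
#'
#' @param ligand_id Parent ligand identifier.
#' @param index 0-based enumeration index, contiguous within the ligand.
#' @param smiles State-specific canonical SMILES.
#' @param molblock Optional V2000 molblock text holding 3D coordinates.
#' @param prep Preparation metadata (embedder name, seed, convergence flag).
#' @return An object of class `enumeration`.
#' @export
enumeration <- function(ligand_id, index, smiles, molblock = NULL,
                        prep = list()) {
  stopifnot(is_string(ligand_id), is_count(index, 0), is_string(smiles))
  structure(list(
    ligand_id = ligand_id,
    index = as.integer(index),
    smiles = smiles,
    molblock = molblock,
    failed = FALSE,
    fail_reason = NA_character_,
    prep = prep
  ), class = "enumeration")
}

#' Construct a ligand set
#'
#' @param ligands List of [ligand()] records with unique ids.
#' @return An object of class `ligand_set` (a list of ligands).
#' @export
ligand_set <- function(ligands = list()) {
  stopifnot(is.list(ligands))
  ids <- vapply(ligands, function(l) l$ligand_id, "")
  if (anyDuplicated(ids))
    fail("duplicate ligand_id: %s", ids[duplicated(ids)][1L])
  structure(ligands, class = "ligand_set")
}

#' @export
print.ligand_set <- function(x, ...) {
  n <- length(x)
  nfail <- sum(vapply(x, function(l) isTRUE(l$failed), TRUE))
  nenum <- sum(vapply(x, function(l) length(l$enumerations), 1L))
  cat(sprintf("<ligand_set> %d ligand(s), %d enumeration(s), %d failed\n",
              n, nenum, nfail))
  invisible(x)
}

#' @export
print.ligand <- function(x, ...) {
  cat(sprintf("<ligand %s> %s%s, %d enumeration(s)\n", x$ligand_id,
              x$input_smiles, if (x$failed) " [FAILED]" else "",
              length(x$enumerations)))
  invisible(x)
}

# flat list of enumeration records across a ligand set (skips failed ligands)
all_enumerations <- function(ligset) {
  out <- list()
  for (l in ligset) if (!l$failed) out <- c(out, l$enumerations)
  out
}

# per-ligand failure table (ligand_id, stage, reason)
failure_report <- function(ligset) {
  rows <- list()
  for (l in ligset) {
    if (l$failed)
      rows[[length(rows) + 1L]] <- data.frame(
        ligand_id = l$ligand_id, stage = "input", reason = l$fail_reason)
    for (e in l$enumerations) if (isTRUE(e$failed))
      rows[[length(rows) + 1L]] <- data.frame(
        ligand_id = l$ligand_id, stage = "embedding", reason = e$fail_reason)
  }
  if (!length(rows))
    return(data.frame(ligand_id = character(0), stage = character(0),
                      reason = character(0)))
  do.call(rbind, rows)
}
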