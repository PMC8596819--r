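
# The built-in deterministic backend. The "docking score" is a pure function
# of the ligand's canonical SMILES and the receptor payload: minus the
# weighted sum of bounded similarities between the ligand's physicochemical
# descriptor vector and the receptor's target vector (plus, optionally, a
# hashed-fragment Tanimoto term against a reference ligand). Lower is better;
# a ligand sitting exactly on the target achieves the receptor's minimal
# (most negative) score -sum(weights).

# Cauchy-type bounded similarity in (0, 1]; 1 iff d == t.
.bounded_similarity <- function(d, t, scale) 1 / (1 + ((d - t) / scale)^2)

#' Score one enumeration with the synthetic backend
#'
#' @param enum An [enumeration()] (coordinates are passed through to the
#'   pose, the score itself depends only on the SMILES).
#' @param receptor A [receptor_profile()] with a `synthetic` payload.
#' @param params Optional list; `poses` (default 1) duplicates the single
#'   deterministic pose record up to the requested count.
#' @return List with `poses`: data.frame(`score`, `molblock`).
#' @export
synthetic_dock <- function(enum, receptor, params = list()) {
  stopifnot(inherits(receptor, "receptor_profile"))
  syn <- receptor$synthetic
  if (is.null(syn)) return(list(failure = "receptor has no synthetic payload"))
  sc <- synthetic_score(enum$smiles, receptor)
  if (is.na(sc)) return(list(failure = "descriptor calculation failed"))
  nposes <- max(1L, as.integer(params$poses %||% 1L))
  # the synthetic search is deterministic: secondary "poses" are the same
  # geometry at slightly degraded score, mimicking a ranked pose stack
  scores <- sc + 0.1 * abs(sc) * (seq_len(nposes) - 1L)
  list(poses = data.frame(
    score = scores,
    molblock = I(rep(list(enum$molblock), nposes))
  ))
}

#' Synthetic docking score of a SMILES against a receptor
#'
#' Exposed separately so scoring components can dock without building
#' enumeration records.
#'
#' @param smiles Valid SMILES (character vector).
#' @param receptor A `receptor_profile` with a synthetic payload.
#' @return Numeric vector of scores (lower better); NA where descriptors fail.
#' @export
synthetic_score <- function(smiles, receptor) {
  syn <- receptor$synthetic
  if (is.null(syn)) fail("receptor '%s' has no synthetic payload",
                         receptor$identifier)
  desc <- tryCatch(mol_descriptors(smiles), error = function(e) NULL)
  if (is.null(desc)) return(rep(NA_real_, length(smiles)))
  t <- syn$target; w <- syn$weights; sc <- syn$scales
  sim <- matrix(0, nrow(desc), length(t))
  for (i in seq_along(t))
    sim[, i] <- .bounded_similarity(desc[[names(t)[i]]], t[[i]], sc[[i]])
  total <- as.vector(sim %*% w)
  if (!is.null(syn$ref_smiles) && syn$fragment_weight > 0) {
    fps <- circular_fp(c(syn$ref_smiles, smiles))
    fsim <- tanimoto_cross(fps[1, , drop = FALSE], fps[-1, , drop = FALSE])
    total <- total + syn$fragment_weight * as.vector(fsim)
  }
  -total
}

register_builtin_backends <- function() {
  register_backend("synthetic", "lower_better", synthetic_dock,
                   max_poses = 1L, embeds_internally = FALSE)
  register_external_stubs()
}
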