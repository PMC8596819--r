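
# Scaffold generification and the bucket-saturation diversity filter that
# keeps a generative agent from collapsing onto one scaffold.

#' Generic (carbon-skeleton) scaffold key
#'
#' Reduces a molecule to its ring-and-linker framework (iteratively pruning
#' terminal atoms), converts every atom to carbon and every bond to a single
#' bond, and returns the canonical SMILES of that skeleton. The key is
#' insensitive to decorations and heteroatoms: benzene and pyridine share a
#' key, as do toluene and phenol. Ring-free molecules map to the designated
#' `"acyclic"` key.
#'
#' @param smiles A valid SMILES string.
#' @return The scaffold key (canonical SMILES of the generified framework,
#'   or `"acyclic"`).
#' @export
generic_scaffold <- function(smiles) {
  stopifnot(is_string(smiles))
  ct <- smiles_ct(smiles)
  if (is.null(ct)) fail("invalid SMILES: %s", smiles)
  keep <- rep(TRUE, ct$natoms)
  bonds <- ct$bonds
  repeat {
    deg <- tabulate(c(bonds$a[keep[bonds$a] & keep[bonds$b]],
                      bonds$b[keep[bonds$a] & keep[bonds$b]]),
                    nbins = ct$natoms)
    leaves <- which(keep & deg <= 1L)
    if (!length(leaves)) break
    keep[leaves] <- FALSE
  }
  if (!any(keep)) return("acyclic")
  newidx <- cumsum(keep)
  sel <- keep[bonds$a] & keep[bonds$b]
  ct2 <- list(
    natoms = sum(keep),
    elements = rep("C", sum(keep)),
    bonds = data.frame(a = newidx[bonds$a[sel]], b = newidx[bonds$b[sel]],
                       order = rep(1L, sum(sel)))
  )
  key <- ct_to_smiles(ct2)
  if (is.na(key)) fail("scaffold generification failed for %s", smiles)
  key
}

#' Create a scaffold bucket store
#'
#' The diversity filter's memory: generified scaffold keys map to buckets of
#' stored compounds. Buckets have limited capacity (25 by default); once a
#' bucket is full, further compounds matching that scaffold are penalized to
#' push the agent toward new chemical space.
#'
#' @param capacity Bucket size (default 25).
#' @param min_score Minimum total score for a compound to occupy bucket
#'   space (default 0.4; lower-scoring compounds pass through unstored and
#'   unpenalized).
#' @param sim_threshold Scaffold-similarity threshold for penalization.
#'   The default 1 means exact generic-key match; below 1, a compound whose
#'   scaffold's circular-fingerprint Tanimoto against a full bucket's
#'   scaffold reaches the threshold is penalized too.
#' @return An object of class `scaffold_bucket_store`.
#' @export
scaffold_bucket_store <- function(capacity = 25L, min_score = 0.4,
                                  sim_threshold = 1) {
  if (!is_count(capacity, 1)) fail("`capacity` must be >= 1")
  if (!is_num(min_score) || min_score < 0 || min_score > 1)
    fail("`min_score` must be in [0, 1]")
  if (!is_num(sim_threshold) || sim_threshold <= 0 || sim_threshold > 1)
    fail("`sim_threshold` must be in (0, 1]")
  structure(list(capacity = as.integer(capacity), min_score = min_score,
                 sim_threshold = sim_threshold,
                 buckets = list()),
            class = "scaffold_bucket_store")
}

#' Apply the diversity filter to one scored compound
#'
#' Rules, in order: an exact duplicate of a stored SMILES is always
#' penalized (score 0); a compound below the store's minimum score passes
#' through unchanged and unstored; a compound whose (similarity-) matching
#' bucket is full is penalized; otherwise the compound is stored and its
#' score is unchanged.
#'
#' @param smiles Compound SMILES (canonicalized internally).
#' @param total Total score: an `mpo_result` or a number in `[0, 1]`.
#' @param store A [scaffold_bucket_store()].
#' @return List with `score` (adjusted total), `store` (updated), `key`
#'   (scaffold key) and `penalized` flag.
#' @export
diversity_penalty <- function(smiles, total, store) {
  stopifnot(inherits(store, "scaffold_bucket_store"))
  s <- if (inherits(total, "mpo_result")) total$total else total
  if (!is_num(s) || s < 0 || s > 1) fail("total score must be in [0, 1]")
  can <- canonical_smiles(smiles)
  if (is.na(can)) fail("invalid SMILES: %s", smiles)
  key <- generic_scaffold(can)
  stored <- unlist(lapply(store$buckets, function(b) b$smiles),
                   use.names = FALSE)
  if (!is.null(stored) && can %in% stored)
    return(list(score = 0, store = store, key = key, penalized = TRUE))
  if (s < store$min_score)
    return(list(score = s, store = store, key = key, penalized = FALSE))
  bucket <- store$buckets[[key]]
  occupancy <- if (is.null(bucket)) 0L else nrow(bucket)
  full_here <- occupancy >= store$capacity
  full_similar <- FALSE
  if (!full_here && store$sim_threshold < 1 && length(store$buckets)) {
    full_keys <- names(store$buckets)[vapply(store$buckets, nrow, 1L) >=
                                        store$capacity]
    full_keys <- setdiff(full_keys, c(key, "acyclic"))
    if (length(full_keys) && key != "acyclic") {
      fps <- circular_fp(c(key, full_keys))
      sims <- tanimoto_cross(fps[1, , drop = FALSE],
                             fps[-1, , drop = FALSE])
      full_similar <- any(sims >= store$sim_threshold)
    }
  }
  if (full_here || full_similar)
    return(list(score = 0, store = store, key = key, penalized = TRUE))
  add <- data.frame(smiles = can, score = s)
  store$buckets[[key]] <- if (is.null(bucket)) add else rbind(bucket, add)
  list(score = s, store = store, key = key, penalized = FALSE)
}

#' @export
print.scaffold_bucket_store <- function(x, ...) {
  occ <- vapply(x$buckets, nrow, 1L)
  cat(sprintf(
    "<scaffold_bucket_store> %d bucket(s), %d stored, capacity %d, min score %.2f\n",
    length(x$buckets), sum(occ), x$capacity, x$min_score))
  invisible(x)
}
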