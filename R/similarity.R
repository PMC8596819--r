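
# Epoch-wise average-linkage Tanimoto analytics over a generative run: how
# similar are the compound batches proposed at different training epochs?

#' An epoch batch of molecules
#'
#' @param epoch 1-based epoch index.
#' @param smiles Non-empty character vector of SMILES.
#' @return An object of class `epoch_batch`.
#' @export
epoch_batch <- function(epoch, smiles) {
  if (!is_count(epoch, 1)) fail("`epoch` must be a positive count")
  if (!is.character(smiles) || !length(smiles))
    fail("an epoch batch needs at least one molecule")
  structure(list(epoch = as.integer(epoch), smiles = smiles),
            class = "epoch_batch")
}

#' Average linkage similarity between two batches
#'
#' The mean pairwise Tanimoto similarity over all cross pairs:
#' `L = (1 / (N1 N2)) * sum_i sum_j T(x_i, y_j)`, computed on circular
#' fingerprints. `L(b, b)` includes self pairs, so a batch repeating one
#' molecule scores exactly 1.
#'
#' @param b1,b2 [epoch_batch()] objects (or plain character vectors of
#'   SMILES).
#' @param fp A [fingerprint_spec()].
#' @return Similarity in `[0, 1]`.
#' @export
average_linkage <- function(b1, b2, fp = fingerprint_spec()) {
  s1 <- if (inherits(b1, "epoch_batch")) b1$smiles else b1
  s2 <- if (inherits(b2, "epoch_batch")) b2$smiles else b2
  stopifnot(is.character(s1), is.character(s2),
            length(s1) >= 1, length(s2) >= 1)
  can <- canonical_smiles(c(s1, s2))
  if (anyNA(can))
    fail("invalid SMILES: %s", c(s1, s2)[which(is.na(can))[1L]])
  uniq <- unique(can)
  fps <- circular_fp(uniq, fp)
  i1 <- match(can[seq_along(s1)], uniq)
  i2 <- match(can[length(s1) + seq_along(s2)], uniq)
  mean(tanimoto_cross(fps[i1, , drop = FALSE], fps[i2, , drop = FALSE]))
}

#' Epoch-by-epoch similarity matrix
#'
#' Samples the run every `stride` epochs (cell k covers the batch at epoch
#' `1 + (k-1) * stride`) and fills the symmetric matrix of average-linkage
#' similarities; the diagonal is each sampled batch's intra-batch similarity.
#' Fingerprints are computed once per distinct molecule across the whole run.
#'
#' @param batches List of [epoch_batch()] objects covering the run in epoch
#'   order (plain character vectors are accepted).
#' @param stride Epochs per matrix cell (default 5).
#' @param fp A [fingerprint_spec()].
#' @return An object of class `similarity_matrix`: list with `values`
#'   (symmetric numeric matrix with epoch labels), `epochs`, `stride`.
#' @export
similarity_matrix <- function(batches, stride = 5L, fp = fingerprint_spec()) {
  if (!is_count(stride, 1)) fail("`stride` must be >= 1")
  if (!length(batches)) fail("need at least one batch")
  sm <- lapply(batches, function(b)
    if (inherits(b, "epoch_batch")) b$smiles else b)
  sel <- seq(1L, length(sm), by = stride)
  sm <- sm[sel]
  all_can <- canonical_smiles(unlist(sm, use.names = FALSE))
  if (anyNA(all_can))
    fail("invalid SMILES: %s",
         unlist(sm, use.names = FALSE)[which(is.na(all_can))[1L]])
  uniq <- unique(all_can)
  fps <- circular_fp(uniq, fp)
  sizes <- lengths(sm)
  idx <- split(match(all_can, uniq), rep(seq_along(sm), sizes))
  k <- length(sm)
  vals <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) for (j in i:k) {
    v <- mean(tanimoto_cross(fps[idx[[i]], , drop = FALSE],
                             fps[idx[[j]], , drop = FALSE]))
    vals[i, j] <- v; vals[j, i] <- v
  }
  labels <- sel
  dimnames(vals) <- list(paste0("e", labels), paste0("e", labels))
  structure(list(values = vals, epochs = labels, stride = as.integer(stride)),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d x %d (stride %d), mean L = %.3f\n",
              nrow(x$values), ncol(x$values), x$stride, mean(x$values)))
  invisible(x)
}

#' Write a similarity matrix as CSV with epoch labels
#'
#' @param x A `similarity_matrix`.
#' @param path CSV path.
#' @return Invisibly, `path`.
#' @export
write_similarity_matrix <- function(x, path) {
  stopifnot(inherits(x, "similarity_matrix"))
  utils::write.csv(data.frame(epoch = x$epochs, x$values,
                              check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}
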