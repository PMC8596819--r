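
# A minimal, agent-agnostic proposal loop: exercises the scoring function and
# diversity filter exactly the way a reinforcement-learning agent does (one
# batch of compounds per epoch, scores fed back), without any generative
# model. A hill-climbing toy proposer over a fixed library is provided for
# tests and examples.

#' Run the proposal-loop harness
#'
#' Per epoch: draw a batch from the proposer, score every compound with the
#' multi-parameter objective, apply the diversity filter, record summary
#' statistics and feed the scored batch back to the proposer. The harness
#' stops early and cleanly if the proposer is exhausted.
#'
#' @param proposer Function `(epoch, batch_size, state, feedback)` returning
#'   `list(smiles = character(), state = <anything>)`; `feedback` is the
#'   scored data.frame of the previous epoch (NULL at epoch 1). Returning
#'   zero molecules stops the run.
#' @param components List of [component_spec()] defining the objective.
#' @param store A [scaffold_bucket_store()].
#' @param epochs Number of epochs.
#' @param batch_size Compounds per epoch (default 128).
#' @param score_threshold Total-score threshold a compound must pass to
#'   count in the cumulative unique-SMILES tally (default the store's
#'   minimum score).
#' @return List with `records` (data.frame: epoch, mean_total, max_total,
#'   mean_raw_docking, n_unique_cumulative, n_proposed), `store` (final
#'   state) and `top` (data.frame of the best-scoring distinct compounds
#'   seen, for downstream replay).
#' @export
rl_step_harness <- function(proposer, components, store, epochs,
                            batch_size = 128L,
                            score_threshold = NULL) {
  stopifnot(is.function(proposer), is_count(epochs, 1),
            is_count(batch_size, 1),
            inherits(store, "scaffold_bucket_store"))
  score_threshold <- score_threshold %||% store$min_score
  dock_comp <- which(vapply(components, function(comp)
    is.list(comp$provider) && identical(comp$provider$type, "docking"),
    TRUE))
  state <- NULL; feedback <- NULL
  passed <- character(0)
  rows <- list(); top <- list()
  for (ep in seq_len(epochs)) {
    prop <- proposer(ep, batch_size, state, feedback)
    state <- prop$state
    smiles <- prop$smiles
    if (!length(smiles)) break
    scored <- score_batch(components, smiles)
    adj <- numeric(length(smiles)); raw_dock <- rep(NA_real_, length(smiles))
    for (i in seq_along(smiles)) {
      res <- diversity_penalty(smiles[i], scored[[i]], store)
      store <- res$store
      adj[i] <- res$score
      if (length(dock_comp))
        raw_dock[i] <- scored[[i]]$components$raw[dock_comp[1]]
    }
    totals <- vapply(scored, `[[`, 1, "total")
    pass <- adj >= score_threshold & totals >= score_threshold
    passed <- union(passed, canonical_smiles(smiles[pass]))
    rows[[ep]] <- data.frame(
      epoch = ep,
      mean_total = mean(totals),
      max_total = max(totals),
      mean_raw_docking = if (all(is.na(raw_dock))) NA_real_
                         else mean(raw_dock, na.rm = TRUE),
      n_unique_cumulative = length(passed),
      n_proposed = length(smiles))
    feedback <- data.frame(smiles = smiles, total = totals,
                           adjusted = adj, raw_docking = raw_dock)
    keep <- order(totals, decreasing = TRUE)[seq_len(min(8, length(totals)))]
    top[[ep]] <- feedback[keep, , drop = FALSE]
  }
  top_all <- do.call(rbind, top)
  top_all <- top_all[!duplicated(top_all$smiles), , drop = FALSE]
  top_all <- top_all[order(top_all$total, decreasing = TRUE), , drop = FALSE]
  list(records = do.call(rbind, rows), store = store,
       top = utils::head(top_all, 50))
}

#' Toy hill-climbing proposer over a fixed library
#'
#' A deterministic stand-in for a generative agent: samples compounds from a
#' fixed library, concentrating probability mass on compounds observed to
#' score well as feedback accumulates (softmax over best-seen totals, with a
#' floor of uniform exploration). Useful to exercise the harness and verify
#' that docking-guided selection improves mean scores across epochs.
#'
#' @param library_smiles Candidate pool.
#' @param seed Integer seed; each epoch derives its own substream.
#' @param greed Softmax temperature gain per epoch (default 4).
#' @param explore Fraction of each batch drawn uniformly (default 0.2).
#' @return A proposer function for [rl_step_harness()].
#' @export
hill_climb_proposer <- function(library_smiles, seed, greed = 4,
                                explore = 0.2) {
  stopifnot(is.character(library_smiles), length(library_smiles) >= 2L)
  force(seed)
  function(epoch, batch_size, state, feedback) {
    if (is.null(state))
      state <- list(best = rep(0, length(library_smiles)))
    if (!is.null(feedback)) {
      idx <- match(feedback$smiles, library_smiles)
      ok <- !is.na(idx)
      state$best[idx[ok]] <- pmax(state$best[idx[ok]], feedback$total[ok])
    }
    smiles <- with_seed(seed + 7919L * epoch, {
      n_explore <- ceiling(explore * batch_size)
      n_exploit <- batch_size - n_explore
      w <- exp(greed * state$best)
      c(sample(library_smiles, n_exploit, replace = TRUE, prob = w / sum(w)),
        sample(library_smiles, n_explore, replace = TRUE))
    })
    list(smiles = smiles, state = state)
  }
}

#' Write per-epoch harness records as CSV
#'
#' @param result Return value of [rl_step_harness()].
#' @param path CSV path.
#' @return Invisibly, `path`.
#' @export
write_epoch_records <- function(result, path) {
  utils::write.csv(result$records, path, row.names = FALSE)
  invisible(path)
}
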