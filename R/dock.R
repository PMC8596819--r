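
# Batch docking dispatch and write-out collation.

#' Dock a batch of enumerations
#'
#' Dispatches embedded enumerations to a registered backend, optionally in
#' parallel. The report is independent of worker count and input order:
#' results are re-sorted by (ligand_id, enumeration_index) before return, and
#' every input enumeration appears exactly once across pose groups and
#' failures.
#'
#' @param enumerations List of [enumeration()] records (or a `ligand_set`,
#'   which is flattened). Coordinates must be present unless the backend
#'   embeds internally; coordinate-less records become failures.
#' @param receptor A [receptor_profile()].
#' @param backend Backend name (see [list_backends()]) or a
#'   `backend_contract`.
#' @param cores Worker processes (default 1).
#' @param max_per_core Compounds per scheduled task (default 32).
#' @param params Extra backend parameters (e.g. `poses`).
#' @return A `docking_report`: list with `poses` (data.frame ligand_id,
#'   enumeration_index, pose_index, score), `pose_blocks` (molblocks aligned
#'   with `poses` rows), `failures` (data.frame ligand_id,
#'   enumeration_index, reason), `backend`, `direction`, `receptor_id`.
#' @export
dock_batch <- function(enumerations, receptor, backend = "synthetic",
                       cores = 1L, max_per_core = 32L, params = list()) {
  if (inherits(enumerations, "ligand_set"))
    enumerations <- all_enumerations(enumerations)
  stopifnot(is.list(enumerations))
  if (!is_count(cores, 1) || !is_count(max_per_core, 1))
    fail("`cores` and `max_per_core` must be positive counts")
  contract <- if (inherits(backend, "backend_contract")) backend
              else get_backend(backend)
  if (!contract$enabled)
    fail("backend '%s' is registered but not enabled", contract$name)
  stopifnot(inherits(receptor, "receptor_profile"))

  empty_poses <- data.frame(ligand_id = character(0),
                            enumeration_index = integer(0),
                            pose_index = integer(0), score = numeric(0))
  empty_fail <- data.frame(ligand_id = character(0),
                           enumeration_index = integer(0),
                           reason = character(0))
  if (!length(enumerations))
    return(structure(list(poses = empty_poses, pose_blocks = list(),
                          failures = empty_fail, backend = contract$name,
                          direction = contract$score_direction,
                          receptor_id = receptor$identifier),
                     class = "docking_report"))

  dock_one <- function(e) {
    if (!inherits(e, "enumeration"))
      return(list(ok = FALSE, id = "?", idx = NA_integer_,
                  reason = "not an enumeration record"))
    if (isTRUE(e$failed))
      return(list(ok = FALSE, id = e$ligand_id, idx = e$index,
                  reason = e$fail_reason))
    if (!contract$embeds_internally &&
        (is.null(e$molblock) || is.na(e$molblock)))
      return(list(ok = FALSE, id = e$ligand_id, idx = e$index,
                  reason = "missing 3D coordinates"))
    res <- tryCatch(contract$dock(e, receptor, params),
                    error = function(err) list(failure = conditionMessage(err)))
    if (!is.null(res$failure) || is.null(res$poses) || !nrow(res$poses))
      return(list(ok = FALSE, id = e$ligand_id, idx = e$index,
                  reason = res$failure %||% "no poses returned"))
    if (any(!is.finite(res$poses$score)))
      return(list(ok = FALSE, id = e$ligand_id, idx = e$index,
                  reason = "non-finite score"))
    list(ok = TRUE, id = e$ligand_id, idx = e$index, poses = res$poses)
  }

  chunks <- split(enumerations,
                  ceiling(seq_along(enumerations) / max_per_core))
  run_chunk <- function(ch) lapply(ch, dock_one)
  results <- if (cores > 1L && .Platform$OS.type == "unix") {
    unlist(parallel::mclapply(chunks, run_chunk, mc.cores = cores),
           recursive = FALSE, use.names = FALSE)
  } else {
    unlist(lapply(chunks, run_chunk), recursive = FALSE, use.names = FALSE)
  }

  pose_rows <- list(); blocks <- list(); fail_rows <- list()
  for (r in results) {
    if (r$ok) {
      np <- nrow(r$poses)
      pose_rows[[length(pose_rows) + 1L]] <- data.frame(
        ligand_id = r$id, enumeration_index = r$idx,
        pose_index = seq_len(np) - 1L, score = r$poses$score)
      blk <- if ("molblock" %in% names(r$poses)) r$poses$molblock
             else rep(list(NULL), np)
      blocks <- c(blocks, blk)
    } else {
      fail_rows[[length(fail_rows) + 1L]] <- data.frame(
        ligand_id = r$id, enumeration_index = r$idx, reason = r$reason)
    }
  }
  poses <- if (length(pose_rows)) do.call(rbind, pose_rows) else empty_poses
  failures <- if (length(fail_rows)) do.call(rbind, fail_rows) else empty_fail
  ord <- order(poses$ligand_id, poses$enumeration_index, poses$pose_index)
  poses <- poses[ord, , drop = FALSE]
  rownames(poses) <- NULL
  blocks <- blocks[ord]
  failures <- failures[order(failures$ligand_id, failures$enumeration_index), ,
                       drop = FALSE]
  rownames(failures) <- NULL
  structure(list(poses = poses, pose_blocks = blocks, failures = failures,
                 backend = contract$name,
                 direction = contract$score_direction,
                 receptor_id = receptor$identifier),
            class = "docking_report")
}

#' @export
print.docking_report <- function(x, ...) {
  cat(sprintf(
    "<docking_report> backend=%s (%s) receptor=%s: %d pose(s) over %d enumeration(s), %d failure(s)\n",
    x$backend, x$direction, x$receptor_id, nrow(x$poses),
    length(unique(paste(x$poses$ligand_id, x$poses$enumeration_index))),
    nrow(x$failures)))
  invisible(x)
}

#' Reduce a docking report to a score table
#'
#' Applies one of the three write-out modes: `"all"` keeps every pose,
#' `"best_per_enumeration"` keeps the best pose of each tautomer/stereoisomer,
#' `"best_per_ligand"` keeps the single best pose over all enumerations of
#' each ligand. "Best" honours the backend's score direction; ties break on
#' (enumeration_index, pose_index) ascending for determinism.
#'
#' @param report A `docking_report`.
#' @param mode Write-out mode.
#' @param names Optional named character vector mapping ligand_id to display
#'   name for the `name` column.
#' @return data.frame with columns ligand_id, name, enumeration_index,
#'   pose_index, score, backend, direction.
#' @export
collate_writeout <- function(report,
                             mode = c("best_per_ligand",
                                      "best_per_enumeration", "all"),
                             names = NULL) {
  stopifnot(inherits(report, "docking_report"))
  if (is.character(mode) && length(mode) == 1L &&
      !mode %in% c("best_per_ligand", "best_per_enumeration", "all"))
    fail("unknown write-out mode '%s'", mode)
  mode <- match.arg(mode)
  p <- report$poses
  if (nrow(p)) {
    better <- if (report$direction == "lower_better") p$score else -p$score
    ord <- order(better, p$enumeration_index, p$pose_index)
    p <- p[ord, , drop = FALSE]
    keep <- switch(mode,
      all = rep(TRUE, nrow(p)),
      best_per_enumeration =
        !duplicated(paste(p$ligand_id, p$enumeration_index)),
      best_per_ligand = !duplicated(p$ligand_id))
    p <- p[keep, , drop = FALSE]
    p <- p[order(p$ligand_id, p$enumeration_index, p$pose_index), ,
           drop = FALSE]
  }
  rownames(p) <- NULL
  data.frame(
    ligand_id = p$ligand_id,
    name = if (is.null(names)) p$ligand_id
           else unname(ifelse(p$ligand_id %in% base::names(names),
                              names[p$ligand_id], p$ligand_id)),
    enumeration_index = p$enumeration_index,
    pose_index = p$pose_index,
    score = p$score,
    backend = rep(report$backend, nrow(p)),
    direction = rep(report$direction, nrow(p))
  )
}

#' Write docked poses as SDF
#'
#' One record per pose carrying the score in an SDF tag.
#'
#' @param report A `docking_report`.
#' @param path Output SDF path.
#' @param mode Write-out mode passed to [collate_writeout()].
#' @return Invisibly, the number of records written.
#' @export
write_poses_sdf <- function(report, path, mode = "best_per_ligand") {
  tab <- collate_writeout(report, mode)
  key <- paste(report$poses$ligand_id, report$poses$enumeration_index,
               report$poses$pose_index)
  out <- character(0); n <- 0L
  for (i in seq_len(nrow(tab))) {
    j <- match(paste(tab$ligand_id[i], tab$enumeration_index[i],
                     tab$pose_index[i]), key)
    blk <- report$pose_blocks[[j]]
    if (is.null(blk) || is.na(blk)) next
    lines <- strsplit(blk, "\n", fixed = TRUE)[[1]]
    lines[1] <- tab$ligand_id[i]
    out <- c(out, lines,
             ">  <score>", format(tab$score[i], digits = 10), "",
             ">  <enumeration_index>", as.character(tab$enumeration_index[i]),
             "", "$$$$")
    n <- n + 1L
  }
  writeLines(out, path)
  invisible(n)
}
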