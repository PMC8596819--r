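
# Reading and writing ligand collections: SMILES flat files (whitespace
# separated "SMILES [name]" per line) and SDF V2000.

#' Read ligands from a SMILES or SDF file
#'
#' Unparsable records are kept as flagged failed ligands (and their count is
#' logged), so a run can report exactly what was lost at the input stage.
#' For SDF input, consecutive records sharing a title are grouped as
#' enumerations of one ligand and their coordinates are retained.
#'
#' @param path File path.
#' @param format `"smiles"` or `"sdf"`; default guessed from the extension.
#' @return A [ligand_set()].
#' @export
read_ligands <- function(path, format = c("auto", "smiles", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) fail("input file not found: %s", path)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) %in% c("sdf", "sd", "mol"))
      "sdf" else "smiles"
  }
  if (format == "smiles") read_ligands_smiles(path) else read_ligands_sdf(path)
}

read_ligands_smiles <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(ligand_set())
  parts <- strsplit(lines, "\\s+")
  smi <- vapply(parts, `[`, "", 1L)
  nm <- vapply(parts, function(p) if (length(p) > 1L) p[2L] else NA_character_, "")
  ids <- ifelse(is.na(nm), sprintf("lig%d", seq_along(smi)), nm)
  ids <- make.unique(ids, sep = "_")
  can <- canonical_smiles(smi)
  ligs <- lapply(seq_along(smi), function(i) {
    l <- structure(list(
      ligand_id = ids[i], input_smiles = smi[i],
      name = if (is.na(nm[i])) ids[i] else nm[i],
      canonical = can[i], failed = is.na(can[i]),
      fail_reason = if (is.na(can[i])) "unparsable SMILES" else NA_character_,
      enumerations = list()
    ), class = "ligand")
    l
  })
  nbad <- sum(is.na(can))
  if (nbad > 0) log_msg("read_ligands: skipped %d unparsable record(s) in %s",
                        nbad, path)
  ligand_set(ligs)
}

read_ligands_sdf <- function(path) {
  txt <- readLines(path, warn = FALSE)
  recs <- split(txt, cumsum(c(0, head(txt == "$$$$", -1))))
  recs <- Filter(function(r) any(grepl("V2000", r)), recs)
  if (!length(recs)) return(ligand_set())
  titles <- vapply(recs, function(r) trimws(r[1]), "")
  blocks <- vapply(recs, function(r) {
    r <- r[r != "$$$$"]
    end <- grep("^M  END", r)
    if (!length(end)) return(NA_character_)
    paste0(paste(r[seq_len(end[1])], collapse = "\n"), "\n")
  }, "")
  can <- vapply(blocks, function(b) {
    if (is.na(b)) return(NA_character_)
    res <- tryCatch(ChemmineOB::convertFormat("SDF", "CAN", paste0(b, "$$$$\n")),
                    error = function(e) "")
    res <- trimws(sub("\t.*$", "", res))
    if (!nzchar(res)) NA_character_ else res
  }, "", USE.NAMES = FALSE)
  titles[!nzchar(titles)] <- sprintf("lig%d", which(!nzchar(titles)))
  nbad <- sum(is.na(can))
  if (nbad > 0) log_msg("read_ligands: skipped %d unparsable record(s) in %s",
                        nbad, path)
  ids <- unique(titles)
  ligs <- lapply(ids, function(id) {
    sel <- which(titles == id)
    okl <- sel[!is.na(can[sel])]
    if (!length(okl)) {
      return(structure(list(
        ligand_id = id, input_smiles = NA_character_, name = id,
        canonical = NA_character_, failed = TRUE,
        fail_reason = "unparsable SDF record", enumerations = list()
      ), class = "ligand"))
    }
    enums <- lapply(seq_along(okl), function(k) {
      at <- molblock_atoms(blocks[okl[k]])
      has3d <- any(abs(c(at$x, at$y, at$z)) > 1e-8)
      enumeration(id, k - 1L, can[okl[k]],
                  molblock = if (has3d) normalize_molblock(blocks[okl[k]]))
    })
    structure(list(
      ligand_id = id, input_smiles = can[okl[1]], name = id,
      canonical = can[okl[1]], failed = FALSE, fail_reason = NA_character_,
      enumerations = enums
    ), class = "ligand")
  })
  ligand_set(ligs)
}

#' Write ligands to a SMILES or SDF file
#'
#' SMILES output writes one `"<canonical smiles> <id>"` line per non-failed
#' ligand. SDF output writes one V2000 record per enumeration (generating a
#' connection-table-only record when no coordinates are present), titled with
#' the ligand id so that [read_ligands()] reassembles the same grouping.
#'
#' @param ligands A [ligand_set()].
#' @param path Output path.
#' @param format `"smiles"` or `"sdf"`; default guessed from the extension.
#' @return Invisibly, the path.
#' @export
write_ligands <- function(ligands, path, format = c("auto", "smiles", "sdf")) {
  format <- match.arg(format)
  stopifnot(inherits(ligands, "ligand_set"))
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) %in% c("sdf", "sd", "mol"))
      "sdf" else "smiles"
  }
  ok <- Filter(function(l) !l$failed, ligands)
  if (format == "smiles") {
    writeLines(vapply(ok, function(l) paste(l$canonical, l$ligand_id), ""), path)
    return(invisible(path))
  }
  out <- character(0)
  for (l in ok) {
    enums <- l$enumerations
    if (!length(enums)) enums <- list(enumeration(l$ligand_id, 0L, l$canonical))
    for (e in enums) {
      block <- e$molblock
      if (is.null(block) || is.na(block)) {
        raw <- ob_run_smi(paste(e$smiles, l$ligand_id), "-osdf")
        block <- normalize_molblock(sub("\\$\\$\\$\\$.*$", "",
                                        paste(raw, collapse = "\n")))
      }
      lines <- strsplit(block, "\n", fixed = TRUE)[[1]]
      lines[1] <- l$ligand_id
      out <- c(out, lines,
               ">  <enumeration_index>", as.character(e$index), "",
               "$$$$")
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Write the per-ligand failure report
#'
#' @param ligands A [ligand_set()].
#' @param path CSV output path.
#' @return Invisibly, the failure data.frame (ligand_id, stage, reason).
#' @export
write_failure_report <- function(ligands, path) {
  rep <- failure_report(ligands)
  utils::write.csv(rep, path, row.names = FALSE)
  invisible(rep)
}
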