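
# Bridge to the Open Babel toolchain (ChemmineR/ChemmineOB in-process, the
# obabel/obminimize executables for batch work). Everything downstream talks
# SMILES/SDF through this file only.

.ob_tools <- new.env(parent = emptyenv())

ob_exe <- function(name = "obabel") {
  key <- paste0("path_", name)
  if (!is.null(.ob_tools[[key]])) return(.ob_tools[[key]])
  p <- Sys.which(name)
  if (!nzchar(p)) fail("required executable '%s' not found on PATH", name)
  .ob_tools[[key]] <- unname(p)
  .ob_tools[[key]]
}

# Run obabel with a temporary .smi input built from `lines`; returns stdout
# lines. Errors from individual bad records are tolerated (obabel skips them).
ob_run_smi <- function(lines, args) {
  inp <- tempfile(fileext = ".smi")
  on.exit(unlink(inp), add = TRUE)
  writeLines(lines, inp)
  out <- suppressWarnings(
    system2(ob_exe("obabel"), c(shQuote(inp), args), stdout = TRUE, stderr = FALSE)
  )
  out
}

#' Canonicalize SMILES
#'
#' Returns the Open Babel canonical SMILES for each input; invalid SMILES
#' yield `NA`. Canonicalization is idempotent and is the identity used
#' throughout the package to compare, deduplicate and order molecules.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES, `NA` where unparsable.
#' @examples
#' canonical_smiles(c("OCC", "C1CC"))  # "CCO", NA
#' @export
canonical_smiles <- function(smiles) {
  if (length(smiles) == 0L) return(character(0))
  stopifnot(is.character(smiles))
  out <- rep(NA_character_, length(smiles))
  ok <- !is.na(smiles) & nzchar(trimws(smiles))
  if (!any(ok)) return(out)
  idx <- which(ok)
  lines <- paste(trimws(smiles[idx]), paste0("m", idx))
  res <- ob_run_smi(lines, c("-ocan", "-e"))
  res <- res[nzchar(res)]
  if (length(res)) {
    parts <- strsplit(res, "\t", fixed = TRUE)
    smi <- vapply(parts, `[`, "", 1L)
    ttl <- trimws(vapply(parts, function(p) if (length(p) > 1L) p[2L] else "", ""))
    hit <- grepl("^m[0-9]+$", ttl)
    pos <- as.integer(sub("^m", "", ttl[hit]))
    out[pos] <- trimws(smi[hit])
  }
  out
}

# Fast single-molecule canonicalization for SMILES already known valid
# (avoids a process spawn); falls back to NA on failure.
canonical_smiles1 <- function(smiles) {
  res <- tryCatch(
    ChemmineOB::convertFormat("SMI", "CAN", paste0(smiles, "\n")),
    error = function(e) ""
  )
  res <- trimws(sub("\t.*$", "", res))
  if (!nzchar(res)) NA_character_ else res
}

#' Test whether SMILES strings are parseable
#'
#' @param smiles Character vector of SMILES.
#' @return Logical vector.
#' @export
smiles_valid <- function(smiles) !is.na(canonical_smiles(smiles))

# --- connection tables -------------------------------------------------------

# Minimal connection-table view of a molecule: list(natoms, elements, bonds
# [data.frame a,b,order], nrings). Hydrogens implicit. Used by the scaffold
# generifier, the tautomer rules and the synthetic backend descriptors.
smiles_ct <- function(smiles) {
  sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(smiles)),
                  error = function(e) NULL)
  if (is.null(sdf)) return(NULL)
  mol <- sdf[[1]]
  ab <- ChemmineR::atomblock(mol)
  bb <- ChemmineR::bondblock(mol)
  elements <- sub("_[0-9]+$", "", rownames(ab))
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0L || ncol(bb) < 3L) {
    data.frame(a = integer(0), b = integer(0), order = integer(0))
  } else {
    data.frame(a = as.integer(bb[, 1]), b = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  }
  n <- length(elements)
  comp <- ct_components(n, bonds)
  list(natoms = n, elements = elements, bonds = bonds,
       nrings = nrow(bonds) - n + max(comp))
}

# connected components by union-find
ct_components <- function(n, bonds) {
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(bonds)) for (k in seq_len(nrow(bonds))) {
    ra <- find(bonds$a[k]); rb <- find(bonds$b[k])
    if (ra != rb) parent[ra] <- rb
  }
  comp <- vapply(seq_len(n), find, 1L)
  match(comp, unique(comp))
}

# Write a (possibly edited) connection table back to a V2000 molblock and
# canonicalize it through Open Babel. Coordinates are irrelevant here; the
# round trip is used to obtain canonical SMILES of derived structures
# (generified scaffolds, tautomer states).
ct_to_smiles <- function(ct) {
  na <- ct$natoms; nb <- nrow(ct$bonds)
  lines <- c(
    "derived", " screendock", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb),
    sprintf("    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            ct$elements),
    if (nb) sprintf("%3d%3d%3d  0  0  0  0", ct$bonds$a, ct$bonds$b, ct$bonds$order),
    "M  END", "$$$$"
  )
  res <- tryCatch(
    ChemmineOB::convertFormat("SDF", "CAN", paste0(paste(lines, collapse = "\n"), "\n")),
    error = function(e) ""
  )
  res <- trimws(sub("\t.*$", "", res))
  if (!nzchar(res)) NA_character_ else res
}

# --- descriptors -------------------------------------------------------------

#' Physicochemical descriptors for a set of molecules
#'
#' Computes the descriptor block used by the synthetic docking backend and the
#' builtin scoring-component providers: heavy-atom count, smallest-set ring
#' count, hydrogen-bond donors/acceptors, molecular weight, logP and TPSA.
#'
#' @param smiles Character vector of SMILES (must be valid).
#' @return data.frame with one row per molecule and columns
#'   `n_heavy`, `n_rings`, `hbd`, `hba`, `mw`, `logp`, `tpsa`.
#' @export
mol_descriptors <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  batch <- paste0(paste(smiles, paste0("m", seq_along(smiles))), "\n", collapse = "")
  props <- tryCatch({
    mols <- ChemmineOB::forEachMol("SMILES", batch, identity)
    ChemmineOB::prop_OB(mols)
  }, error = function(e) fail("descriptor calculation failed: %s", conditionMessage(e)))
  if (nrow(props) != length(smiles))
    fail("descriptor calculation failed for %d of %d molecules",
         length(smiles) - nrow(props), length(smiles))
  cts <- lapply(smiles, smiles_ct)
  bad <- vapply(cts, is.null, TRUE)
  if (any(bad)) fail("unparsable SMILES at position %d", which(bad)[1L])
  data.frame(
    n_heavy = vapply(cts, function(x) x$natoms, 1L),
    n_rings = vapply(cts, function(x) x$nrings, 1L),
    hbd  = as.numeric(props$HBD),
    hba  = as.numeric(props$HBA1),
    mw   = as.numeric(props$MW),
    logp = as.numeric(props$logP),
    tpsa = as.numeric(props$TPSA)
  )
}

# --- fingerprints ------------------------------------------------------------

#' Circular fingerprint specification
#'
#' @param radius Neighborhood radius of the circular fingerprint (default 3).
#' @param bits Fingerprint width after folding; must be a power of two
#'   (default 1024).
#' @return An object of class `fingerprint_spec`.
#' @export
fingerprint_spec <- function(radius = 3L, bits = 1024L) {
  if (!is_count(radius, 0) || radius > 5)
    fail("`radius` must be an integer in 0..5")
  if (!is_count(bits, 32) || bitwAnd(as.integer(bits), as.integer(bits) - 1L) != 0L)
    fail("`bits` must be a power of two >= 32")
  structure(list(type = "circular", radius = as.integer(radius),
                 bits = as.integer(bits)),
            class = "fingerprint_spec")
}

#' Circular fingerprints for a batch of molecules
#'
#' Extended-connectivity fingerprints of the requested radius, computed by
#' Open Babel and folded to `spec$bits` bits. Results are memoized per
#' canonical SMILES within the returned matrix only (no global state).
#'
#' @param smiles Character vector of valid SMILES.
#' @param spec A [fingerprint_spec()].
#' @return Logical matrix, one row per molecule, `spec$bits` columns.
#' @export
circular_fp <- function(smiles, spec = fingerprint_spec()) {
  stopifnot(inherits(spec, "fingerprint_spec"), is.character(smiles),
            length(smiles) >= 1L)
  fpname <- paste0("ECFP", 2L * spec$radius)
  lines <- paste(smiles, paste0("m", seq_along(smiles)))
  out <- ob_run_smi(lines, c("-ofpt", paste0("-xf", fpname),
                             paste0("-xN", spec$bits), "-xh"))
  mat <- matrix(FALSE, nrow = length(smiles), ncol = spec$bits)
  seen <- logical(length(smiles))
  cur <- NA_integer_
  hexbuf <- character(0)
  flush <- function() {
    if (!is.na(cur) && length(hexbuf)) {
      bits <- hex_to_bits(paste(hexbuf, collapse = ""))
      if (length(bits) == spec$bits) { mat[cur, ] <<- bits; seen[cur] <<- TRUE }
    }
  }
  for (ln in out) {
    if (grepl("^>", ln)) {
      flush()
      ttl <- sub("^>\\s*(\\S+).*$", "\\1", ln)
      cur <- if (grepl("^m[0-9]+$", ttl)) as.integer(sub("^m", "", ttl)) else NA_integer_
      hexbuf <- character(0)
    } else if (grepl("^[0-9a-f ]+$", ln) && nzchar(trimws(ln))) {
      hexbuf <- c(hexbuf, gsub(" ", "", ln))
    }
  }
  flush()
  if (!all(seen))
    fail("fingerprint generation failed for molecule(s) at position(s) %s",
         paste(which(!seen), collapse = ", "))
  mat
}

hex_to_bits <- function(hex) {
  digits <- strtoi(strsplit(hex, "")[[1]], base = 16L)
  as.vector(vapply(digits, function(d) as.logical(bitwAnd(d, c(8L, 4L, 2L, 1L))),
                   logical(4)))
}

#' Tanimoto similarity between two bit vectors
#'
#' @param a,b Logical vectors of equal length.
#' @return Similarity in `[0, 1]`; two empty fingerprints score 0.
#' @export
tanimoto <- function(a, b) {
  stopifnot(length(a) == length(b))
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

# All-pairs Tanimoto between the rows of two logical matrices (vectorized).
tanimoto_cross <- function(A, B) {
  stopifnot(ncol(A) == ncol(B))
  Am <- matrix(as.numeric(A), nrow(A)); Bm <- matrix(as.numeric(B), nrow(B))
  inter <- Am %*% t(Bm)
  ra <- rowSums(Am); rb <- rowSums(Bm)
  uni <- outer(ra, rb, `+`) - inter
  out <- ifelse(uni == 0, 0, inter / uni)
  out
}
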