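
# Tautomer/stereoisomer state enumeration.
#
# Stereo enumeration works at the canonical-SMILES level: for every eligible
# unbracketed aliphatic carbon token we insert @ / @@ chirality markers and
# keep the atom only if Open Babel canonicalization (which normalizes away
# markers on non-stereogenic atoms) yields two distinct molecules. Already
# specified centres are bracket tokens and are never touched, so partial
# specifications are preserved. Tautomer enumeration is a deterministic
# rule-based engine applying 1,3 keto-enol bond-order flips on the kekulized
# connection table (restricted to acyclic sites).

ATOM_TOKEN_RE <- "\\[[^]]+\\]|Cl|Br|B|C|N|O|P|S|F|I|b|c|n|o|p|s"

# positions of atom tokens in a SMILES string
smiles_atom_tokens <- function(s) {
  m <- gregexpr(ATOM_TOKEN_RE, s)[[1]]
  if (m[1] == -1) return(data.frame(start = integer(0), end = integer(0),
                                    token = character(0)))
  data.frame(start = as.integer(m),
             end = as.integer(m) + attr(m, "match.length") - 1L,
             token = regmatches(s, gregexpr(ATOM_TOKEN_RE, s))[[1]])
}

strip_stereo <- function(s) gsub("@", "", s, fixed = TRUE)

# replace the substring [start, end] of s with repl
str_splice <- function(s, start, end, repl) {
  paste0(substr(s, 1L, start - 1L), repl, substr(s, end + 1L, nchar(s)))
}

# Find unspecified tetrahedral centres of canonical SMILES s0. For each
# candidate token returns the bracket replacement pair that preserves the
# molecular graph. Only plain "C" tokens are considered (bracketed atoms are
# either already specified or out of scope for this enumerator). All probe
# canonicalizations run as one batch.
find_unspecified_centres <- function(s0) {
  toks <- smiles_atom_tokens(s0)
  cand <- which(toks$token == "C")
  if (!length(cand)) return(list())
  probes <- character(0); meta <- list()
  for (j in cand) for (h in c("H", "")) {
    v1 <- str_splice(s0, toks$start[j], toks$end[j], paste0("[C@", h, "]"))
    v2 <- str_splice(s0, toks$start[j], toks$end[j], paste0("[C@@", h, "]"))
    meta[[length(meta) + 1L]] <- list(j = j, h = h, base = length(probes))
    probes <- c(probes, strip_stereo(v1), v1, v2)
  }
  can <- canonical_smiles(c(strip_stereo(s0), probes))
  skeleton <- can[1]; can <- can[-1]
  out <- list()
  for (j in cand) {
    hits <- Filter(function(m) m$j == j, meta)
    for (m in hits) {
      cs <- can[m$base + 1:3]
      if (is.na(cs[1]) || !identical(cs[1], skeleton)) next
      if (!is.na(cs[2]) && !is.na(cs[3]) && !identical(cs[2], cs[3]))
        out[[length(out) + 1L]] <- list(start = toks$start[j],
                                        end = toks$end[j], hcount = m$h)
      break
    }
  }
  out
}

# All distinct stereoisomer canonical SMILES reachable by assigning the
# unspecified centres of s0, in deterministic order. Returns list(smiles,
# truncated). Variants are canonicalized in chunks so enumeration can stop
# early at max_states.
enumerate_stereo_states <- function(s0, max_states = 32L) {
  centres <- find_unspecified_centres(s0)
  k <- length(centres)
  if (k == 0L) return(list(smiles = s0, truncated = FALSE))
  ord <- order(vapply(centres, `[[`, 1L, "start"), decreasing = TRUE)
  make_variant <- function(i) {
    v <- s0
    for (j in ord) {   # right-to-left so earlier positions stay valid
      mark <- if (bitwAnd(i, bitwShiftL(1, j - 1L)) > 0) "@@" else "@"
      ctr <- centres[[j]]
      v <- str_splice(v, ctr$start, ctr$end, paste0("[C", mark, ctr$hcount, "]"))
    }
    v
  }
  seen <- character(0)
  truncated <- FALSE
  total <- 2^k
  i <- 0
  chunk <- 64L
  while (i < total) {
    upto <- min(i + chunk, total) - 1
    cv <- canonical_smiles(vapply(i:upto, make_variant, ""))
    for (s in seq_along(cv)) {
      if (!is.na(cv[s]) && !(cv[s] %in% seen)) seen <- c(seen, cv[s])
      if (length(seen) >= max_states) {
        # cap hit before the full assignment space was scanned
        if (s < length(cv) || upto < total - 1) truncated <- TRUE
        break
      }
    }
    i <- upto + 1
    if (truncated || length(seen) >= max_states) break
  }
  list(smiles = seen, truncated = truncated)
}

# --- tautomers ---------------------------------------------------------------

# bonds that are part of a ring: removing the bond keeps endpoints connected
ring_bond_mask <- function(ct) {
  nb <- nrow(ct$bonds)
  if (!nb) return(logical(0))
  vapply(seq_len(nb), function(k) {
    sub <- ct$bonds[-k, , drop = FALSE]
    comp <- ct_components(ct$natoms, sub)
    comp[ct$bonds$a[k]] == comp[ct$bonds$b[k]]
  }, TRUE)
}

implicit_h <- function(ct) {
  val <- c(C = 4, N = 3, O = 2, S = 2, P = 3)
  sums <- numeric(ct$natoms)
  if (nrow(ct$bonds)) for (k in seq_len(nrow(ct$bonds))) {
    o <- ct$bonds$order[k]
    sums[ct$bonds$a[k]] <- sums[ct$bonds$a[k]] + o
    sums[ct$bonds$b[k]] <- sums[ct$bonds$b[k]] + o
  }
  known <- ct$elements %in% names(val)
  out <- rep(0, ct$natoms)
  out[known] <- pmax(0, val[ct$elements[known]] - sums[known])
  out
}

# One round of 1,3 keto-enol transforms (both directions) applied to acyclic
# sites of the molecule behind canonical SMILES s0; returns the distinct
# canonical SMILES of the products.
keto_enol_neighbours <- function(s0) {
  ct <- smiles_ct(s0)
  if (is.null(ct)) return(character(0))
  bonds <- ct$bonds
  if (!nrow(bonds)) return(character(0))
  inring <- ring_bond_mask(ct)
  ringatom <- rep(FALSE, ct$natoms)
  ringatom[unique(c(bonds$a[inring], bonds$b[inring]))] <- TRUE
  hs <- implicit_h(ct)
  el <- ct$elements
  # adjacency with bond row index
  adj <- vector("list", ct$natoms)
  for (k in seq_len(nrow(bonds))) {
    adj[[bonds$a[k]]] <- rbind(adj[[bonds$a[k]]], c(bonds$b[k], k))
    adj[[bonds$b[k]]] <- rbind(adj[[bonds$b[k]]], c(bonds$a[k], k))
  }
  out <- character(0)
  for (k in seq_len(nrow(bonds))) {
    a <- bonds$a[k]; b <- bonds$b[k]; o <- bonds$order[k]
    # keto -> enol: Calpha(-H) - C(=O): single C-C bond k, carbonyl on one end
    if (o == 1L && el[a] == "C" && el[b] == "C" && !ringatom[a] && !ringatom[b]) {
      for (dir in list(c(a, b), c(b, a))) {
        ca <- dir[1]; cc <- dir[2]        # ca: alpha carbon, cc: carbonyl C
        if (hs[ca] < 1) next
        nb <- adj[[cc]]
        dbl_o <- nb[nb[, 1] != ca & el[nb[, 1]] == "O" &
                    bonds$order[nb[, 2]] == 2L, , drop = FALSE]
        if (!nrow(dbl_o)) next
        if (ringatom[dbl_o[1, 1]]) next
        ct2 <- ct
        ct2$bonds$order[k] <- 2L
        ct2$bonds$order[dbl_o[1, 2]] <- 1L
        sm <- ct_to_smiles(ct2)
        if (!is.na(sm)) out <- c(out, sm)
      }
    }
    # enol -> keto: C=C with OH on one carbon
    if (o == 2L && el[a] == "C" && el[b] == "C" && !ringatom[a] && !ringatom[b]) {
      for (dir in list(c(a, b), c(b, a))) {
        c1 <- dir[1]; c2 <- dir[2]        # c1 carries the OH
        nb <- adj[[c1]]
        oh <- nb[nb[, 1] != c2 & el[nb[, 1]] == "O" &
                 bonds$order[nb[, 2]] == 1L, , drop = FALSE]
        oh <- oh[hs[oh[, 1]] >= 1, , drop = FALSE]
        if (!nrow(oh)) next
        ct2 <- ct
        ct2$bonds$order[k] <- 1L
        ct2$bonds$order[oh[1, 2]] <- 2L
        sm <- ct_to_smiles(ct2)
        if (!is.na(sm)) out <- c(out, sm)
      }
    }
  }
  setdiff(unique(out), s0)
}

# closure of keto-enol transforms starting from s0 (bounded breadth-first)
enumerate_tautomer_states <- function(s0, max_states = 32L) {
  seen <- s0
  frontier <- s0
  truncated <- FALSE
  while (length(frontier) && length(seen) < max_states) {
    nxt <- character(0)
    for (s in frontier) {
      for (t in keto_enol_neighbours(s)) {
        if (!(t %in% seen)) {
          seen <- c(seen, t); nxt <- c(nxt, t)
          if (length(seen) >= max_states) { truncated <- TRUE; break }
        }
      }
      if (truncated) break
    }
    frontier <- nxt
    if (truncated) break
  }
  list(smiles = seen, truncated = truncated)
}

#' Enumerate tautomer/stereoisomer states of a ligand
#'
#' Expands a ligand into its enumerations: optional rule-based tautomer
#' expansion (1,3 keto-enol shifts at acyclic sites) followed by optional
#' stereoisomer expansion of unspecified tetrahedral carbons. Specified
#' stereocentres are always preserved. The resulting state list is
#' deterministic: states are deduplicated on canonical SMILES and ordered
#' lexicographically; truncation at `max_states` is flagged in the ligand's
#' `truncated` field.
#'
#' @param lig A [ligand()]; a failed ligand is returned unchanged.
#' @param enumerate_stereo Expand unspecified stereocentres? (default TRUE)
#' @param enumerate_tautomers Apply the tautomer rules? (default FALSE)
#' @param max_states Cap on the number of enumerations (default 32).
#' @return The ligand with `enumerations` populated (always >= 1 state for a
#'   parseable input).
#' @examples
#' \donttest{
#' lig <- enumerate_states(ligand("l1", "OC(C)C(N)CC"))
#' length(lig$enumerations)  # 4: two unspecified stereocentres
#' }
#' @export
enumerate_states <- function(lig, enumerate_stereo = TRUE,
                             enumerate_tautomers = FALSE, max_states = 32L) {
  stopifnot(inherits(lig, "ligand"))
  if (!is_count(max_states, 1)) fail("`max_states` must be a positive count")
  if (lig$failed) return(lig)
  states <- lig$canonical
  truncated <- FALSE
  if (enumerate_tautomers) {
    r <- enumerate_tautomer_states(lig$canonical, max_states)
    states <- r$smiles; truncated <- truncated || r$truncated
  }
  if (enumerate_stereo) {
    expanded <- character(0)
    for (s in states) {
      left <- max_states - length(expanded)
      if (left <= 0L) { truncated <- TRUE; break }
      r <- enumerate_stereo_states(s, left)
      expanded <- unique(c(expanded, r$smiles))
      truncated <- truncated || r$truncated
    }
    states <- expanded
  }
  states <- sort(unique(states))
  if (length(states) > max_states) { states <- states[seq_len(max_states)]; truncated <- TRUE }
  lig$enumerations <- lapply(seq_along(states), function(i)
    enumeration(lig$ligand_id, i - 1L, states[i]))
  lig$truncated <- truncated
  lig
}
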