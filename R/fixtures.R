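
# Synthetic fixtures: labeled active/decoy screens with planted enrichment
# (emulating the composition of curated benchmark sets: 40 actives vs 1200
# property-matched decoys per target) and a toy SMILES library assembled from
# a fixed fragment grammar. Both are deterministic given a seed, so every
# other module is testable without downloading anything.

#' Specification of a synthetic labeled screen
#'
#' @param n_actives,n_decoys Class sizes (defaults 40 / 1200, the composition
#'   of a typical curated enrichment benchmark target).
#' @param delta Planted enrichment: actives' mean score is shifted `delta`
#'   noise units toward "better" per `direction`; 0 plants nothing, so the
#'   expected pROC AUC is the random-selection value 0.434.
#' @param noise Score noise scale (standard deviation; default 1).
#' @param baseline Decoy score distribution: `"gaussian"` or `"heavy"`
#'   (t with 3 df, to stress the FPR clipping policy).
#' @param direction Score direction (default `"lower_better"`).
#' @param seed Mandatory integer seed.
#' @return An object of class `synthetic_screen_spec`.
#' @export
synthetic_screen_spec <- function(n_actives = 40L, n_decoys = 1200L,
                                  delta = 0, noise = 1,
                                  baseline = c("gaussian", "heavy"),
                                  direction = c("lower_better",
                                                "higher_better"),
                                  seed) {
  baseline <- match.arg(baseline)
  direction <- match.arg(direction)
  if (missing(seed)) fail("`seed` is mandatory for a synthetic screen")
  if (!is_count(n_actives, 1) || !is_count(n_decoys, 1))
    fail("class sizes must be positive counts")
  if (!is_num(delta) || delta < 0) fail("`delta` must be >= 0")
  if (!is_num(noise) || noise <= 0) fail("`noise` must be > 0")
  structure(list(n_actives = as.integer(n_actives),
                 n_decoys = as.integer(n_decoys), delta = delta,
                 noise = noise, baseline = baseline, direction = direction,
                 seed = as.integer(seed)),
            class = "synthetic_screen_spec")
}

#' Generate a labeled active/decoy score set
#'
#' Decoy scores are drawn from the baseline distribution centred at -6 score
#' units (a typical docking-score magnitude); active scores are shifted
#' `delta` noise units toward "better". The output is reproducible from the
#' spec's seed.
#'
#' @param spec A [synthetic_screen_spec()].
#' @return A [labeled_scores()].
#' @export
generate_screen <- function(spec) {
  stopifnot(inherits(spec, "synthetic_screen_spec"))
  with_seed(spec$seed, {
    n <- spec$n_actives + spec$n_decoys
    eps <- switch(spec$baseline,
                  gaussian = stats::rnorm(n),
                  heavy = stats::rt(n, df = 3))
    centre <- -6
    shift <- spec$delta * spec$noise *
      (if (spec$direction == "lower_better") -1 else 1)
    score <- centre + spec$noise * eps +
      rep(c(shift, 0), c(spec$n_actives, spec$n_decoys))
    labeled_scores(
      ligand_id = sprintf("%s%d", rep(c("act", "dec"),
                                      c(spec$n_actives, spec$n_decoys)),
                          c(seq_len(spec$n_actives), seq_len(spec$n_decoys))),
      score = score,
      label = rep(c("active", "decoy"), c(spec$n_actives, spec$n_decoys)),
      direction = spec$direction)
  })
}

#' Read / write a labeled score set as CSV
#'
#' The CSV carries columns `ligand_id`, `score`, `label` and `direction`
#' (the same self-contained format the analysis modes consume).
#'
#' @param data A [labeled_scores()].
#' @param path CSV path.
#' @return `write_labeled_scores()` invisibly returns `path`;
#'   `read_labeled_scores()` returns a [labeled_scores()].
#' @export
write_labeled_scores <- function(data, path) {
  stopifnot(inherits(data, "labeled_scores"))
  utils::write.csv(data.frame(ligand_id = data$ligand_id, score = data$score,
                              label = data$label,
                              direction = data$direction),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labeled_scores
#' @export
read_labeled_scores <- function(path) {
  if (!file.exists(path)) fail("score file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("ligand_id", "score", "label")
  miss <- setdiff(need, names(df))
  if (length(miss)) fail("score file %s lacks column(s): %s", path,
                         paste(miss, collapse = ", "))
  if (!nrow(df)) fail("score file %s is empty", path)
  dir <- if ("direction" %in% names(df)) df$direction[1] else "lower_better"
  labeled_scores(df$ligand_id, df$score, df$label, direction = dir)
}

# fixed fragment grammar of the toy library
TOY_RINGS <- c("c1ccccc1", "c1ccncc1", "c1ccsc1", "c1ccoc1", "C1CCCCC1",
               "C1CCNCC1", "C1CCOCC1", "c1ccc2ccccc2c1")
TOY_LINKERS <- c("", "C", "CC", "CCC", "O", "OC", "N(C)", "C(=O)", "C(=O)N",
                 "S(=O)(=O)")
TOY_CAPS <- c("", "C", "CC", "O", "N", "F", "Cl", "OC", "C#N", "C(F)(F)F",
              "C(=O)O")

#' Generate a toy drug-like SMILES library
#'
#' Assembles `n` distinct compounds from a fixed grammar of ring systems,
#' linkers and terminal decorations (ring-linker-ring-cap). All strings are
#' valid SMILES by construction and the sampling is deterministic per seed.
#'
#' @param n Library size (>= 1; at most the grammar's product space, 7040).
#' @param seed Integer seed.
#' @return Character vector of `n` SMILES.
#' @export
generate_toy_library <- function(n, seed) {
  if (!is_count(n, 1)) fail("`n` must be a positive count")
  space <- length(TOY_RINGS) * length(TOY_LINKERS) * length(TOY_RINGS) *
    length(TOY_CAPS)
  if (n > space) fail("`n` exceeds the grammar space (%d)", space)
  with_seed(seed, {
    idx <- sample.int(space, n)
    idx <- idx - 1L
    r1 <- idx %% length(TOY_RINGS)
    idx <- idx %/% length(TOY_RINGS)
    lk <- idx %% length(TOY_LINKERS)
    idx <- idx %/% length(TOY_LINKERS)
    r2 <- idx %% length(TOY_RINGS)
    cp <- idx %/% length(TOY_RINGS)
    paste0(TOY_RINGS[r1 + 1L], TOY_LINKERS[lk + 1L], TOY_RINGS[r2 + 1L],
           TOY_CAPS[cp + 1L])
  })
}
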