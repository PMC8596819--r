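
# Score transformation onto [0, 1] and weighted-geometric-mean aggregation:
# the machinery a reinforcement-learning agent's reward is built from.

#' Score transform specification
#'
#' Maps a raw property value onto `[0, 1]`. `sigmoid` increases in the raw
#' value, `reverse_sigmoid` decreases (the natural choice for lower-better
#' docking scores), `linear_clip` interpolates linearly between the anchors,
#' `step` is the indicator of the `[low, high]` window. Both sigmoids pass
#' through 0.5 at the anchor midpoint; `k` controls steepness (the gain over
#' the anchor span).
#'
#' @param kind One of `"sigmoid"`, `"reverse_sigmoid"`, `"linear_clip"`,
#'   `"step"`.
#' @param low,high Anchors, `low < high`.
#' @param k Steepness, > 0 (default 10, which puts the sigmoid above 0.99 /
#'   below 0.01 at the anchors).
#' @return An object of class `transform_spec`.
#' @export
transform_spec <- function(kind = c("sigmoid", "reverse_sigmoid",
                                    "linear_clip", "step"),
                           low, high, k = 10) {
  kind <- match.arg(kind)
  if (!is_num(low) || !is_num(high) || low >= high)
    fail("need finite anchors with low < high")
  if (!is_num(k) || k <= 0) fail("steepness `k` must be > 0")
  structure(list(kind = kind, low = low, high = high, k = k),
            class = "transform_spec")
}

#' Apply a score transform
#'
#' @param raw Numeric vector of raw property values. Non-finite entries (the
#'   sentinel for failed docking) map to 0, so a failure penalizes the agent
#'   instead of dropping the molecule.
#' @param spec A [transform_spec()].
#' @return Values in `[0, 1]`.
#' @export
apply_transform <- function(raw, spec) {
  stopifnot(inherits(spec, "transform_spec"))
  mid <- (spec$low + spec$high) / 2
  span <- spec$high - spec$low
  out <- switch(spec$kind,
    sigmoid = 1 / (1 + exp(-spec$k * (raw - mid) / span)),
    reverse_sigmoid = 1 / (1 + exp(spec$k * (raw - mid) / span)),
    linear_clip = pmin(1, pmax(0, (raw - spec$low) / span)),
    step = as.numeric(raw >= spec$low & raw <= spec$high))
  out[!is.finite(raw)] <- 0
  pmin(1, pmax(0, out))
}

#' Scoring component specification
#'
#' One property entering the multi-parameter objective: a provider computing
#' the raw value, a transform onto `[0, 1]`, and a non-negative weight.
#'
#' @param name Component name.
#' @param provider Either a builtin descriptor name (one of `"mw"`, `"hbd"`,
#'   `"hba"`, `"tpsa"`, `"logp"`, `"n_rings"`, `"n_heavy"`), a list
#'   `list(type = "docking", backend = ..., receptor = ...)`, or a function
#'   `f(smiles) -> numeric` (the hook for external descriptors such as
#'   drug-likeness scores).
#' @param transform A [transform_spec()].
#' @param weight Weight `w >= 0` (default 1, equal importance).
#' @return An object of class `component_spec`.
#' @export
component_spec <- function(name, provider, transform, weight = 1) {
  stopifnot(is_string(name), inherits(transform, "transform_spec"))
  if (!is_num(weight) || weight < 0) fail("`weight` must be >= 0")
  builtin <- c("mw", "hbd", "hba", "tpsa", "logp", "n_rings", "n_heavy")
  ok <- is.function(provider) ||
    (is_string(provider) && provider %in% builtin) ||
    (is.list(provider) && identical(provider$type, "docking"))
  if (!ok)
    fail("component '%s': provider must be a builtin descriptor (%s), a docking spec or a function",
         name, paste(builtin, collapse = ", "))
  structure(list(name = name, provider = provider, transform = transform,
                 weight = weight),
            class = "component_spec")
}

# raw values of one component for a vector of valid SMILES
component_raw <- function(comp, smiles) {
  p <- comp$provider
  if (is.function(p)) return(as.numeric(p(smiles)))
  if (is_string(p)) return(mol_descriptors(smiles)[[p]])
  backend <- p$backend %||% "synthetic"
  if (!identical(backend, "synthetic"))
    fail("component '%s': only the synthetic backend docks inside the scoring function",
         comp$name)
  synthetic_score(smiles, p$receptor)
}

#' Multi-parameter total score (weighted geometric mean)
#'
#' Aggregates the transformed component scores as
#' `S(x) = (prod_i P_i(x)^w_i)^(1 / sum_i w_i)`, so every property must be
#' reasonably satisfied: any component at zero annihilates the total, and
#' scaling all weights by a constant changes nothing. All-equal weights give
#' the plain geometric mean.
#'
#' @param components List of [component_spec()] with `sum(w) > 0`.
#' @param smiles A single SMILES string.
#' @return An `mpo_result`: list with `total` in `[0, 1]`, `components`
#'   (data.frame name, raw, transformed, weight) and `reason` (NA unless the
#'   molecule is invalid, which scores 0).
#' @export
total_score <- function(components, smiles) {
  if (!is_string(smiles)) fail("`smiles` must be a single string")
  score_batch(components, smiles)[[1]]
}

#' Batch multi-parameter scoring
#'
#' Vectorized form of [total_score()]: component providers are called once
#' per batch rather than once per molecule, which is how the proposal-loop
#' harness scores an epoch. Invalid molecules score 0.
#'
#' @param components List of [component_spec()].
#' @param smiles Character vector.
#' @return List of `mpo_result`, one per input.
#' @export
score_batch <- function(components, smiles) {
  stopifnot(length(components) >= 1L, is.character(smiles))
  for (comp in components) stopifnot(inherits(comp, "component_spec"))
  w <- vapply(components, `[[`, 1, "weight")
  if (sum(w) <= 0) fail("component weights must sum to > 0")
  nms <- vapply(components, `[[`, "", "name")
  can <- canonical_smiles(smiles)
  valid <- !is.na(can)
  raw <- matrix(NA_real_, length(smiles), length(components))
  if (any(valid)) {
    vs <- smiles[valid]
    for (k in seq_along(components)) {
      v <- tryCatch(component_raw(components[[k]], vs),
                    error = function(e) rep(NA_real_, length(vs)))
      if (length(v) == length(vs)) raw[valid, k] <- v
    }
  }
  lapply(seq_along(smiles), function(i) {
    if (!valid[i]) {
      return(structure(list(
        total = 0,
        components = data.frame(name = nms, raw = NA_real_, transformed = 0,
                                weight = w),
        reason = "invalid molecule"), class = "mpo_result"))
    }
    p <- vapply(seq_along(components), function(k)
      apply_transform(raw[i, k], components[[k]]$transform), 1)
    total <- if (any(p == 0 & w > 0)) 0 else prod(p^w)^(1 / sum(w))
    structure(list(
      total = total,
      components = data.frame(name = nms, raw = raw[i, ], transformed = p,
                              weight = w),
      reason = NA_character_), class = "mpo_result")
  })
}

#' @export
print.mpo_result <- function(x, ...) {
  cat(sprintf("<mpo_result> S(x) = %.4f%s\n", x$total,
              if (!is.na(x$reason)) paste0(" [", x$reason, "]") else ""))
  print(x$components, row.names = FALSE)
  invisible(x)
}
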