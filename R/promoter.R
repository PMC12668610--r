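#' The four HXT repressors
#'
#' Canonical repressor names in canonical order: the glucose-"pulled" pair
#' (Mth1, Std1, acting through DNA-bound Rgt1) then the glucose-"pushed" pair
#' (Mig1, Mig2).
#' @export
hxt_repressors <- function() c("Mth1", "Std1", "Mig1", "Mig2")

canon_repressor <- function(x) {
  pool <- hxt_repressors()
  idx <- match(tolower(x), tolower(pool))
  if (anyNA(idx)) {
    rlang::abort(paste0("unknown repressor(s): ", paste(x[is.na(idx)], collapse = ", ")))
  }
  pool[idx]
}

#' Enumerate promoter structures
#'
#' A promoter structure is a non-empty subset of the repressor pool assumed to
#' bind the promoter (at least one binds, at most all do); for the four HXT
#' repressors there are 15 structures. Order is canonical and stable: by
#' subset size, then lexicographically within size (in pool order).
#'
#' @param repressor_pool Character vector of repressor names
#'   (default all four).
#' @return A list of character vectors, each a sorted repressor subset.
#' @export
#' @examples
#' length(promoter_structures()) # 15
promoter_structures <- function(repressor_pool = hxt_repressors()) {
  if (length(repressor_pool) == 0) rlang::abort("repressor pool must be non-empty")
  pool <- canon_repressor(unique(repressor_pool))
  pool <- pool[order(match(pool, hxt_repressors()))]
  out <- list()
  for (k in seq_along(pool)) {
    combos <- utils::combn(pool, k, simplify = FALSE)
    ord <- order(vapply(
      combos,
      function(s) paste(sprintf("%02d", match(s, pool)), collapse = ""),
      character(1)
    ))
    out <- c(out, combos[ord])
  }
  out
}

#' Canonical label of a promoter structure
#' @param structure Character vector of repressor names.
#' @return A single string, e.g. `"Mth1+Mig1"`.
#' @export
structure_label <- function(structure) {
  s <- canon_repressor(structure)
  paste(s[order(match(s, hxt_repressors()))], collapse = "+")
}

#' Promoter parameters
#'
#' Bundles a promoter structure with its kinetic parameters: maximal synthesis
#' rate `aH`, glucose-dependent degradation bounds (`dHmax` at zero glucose,
#' `dHmin` in saturating glucose, half-saturation `K_dH`), and, for each
#' repressor in the structure, a dissociation constant `K_i` (same units as
#' the repressor state) and Hill number `n_i`. Repressors outside the
#' structure carry no parameters, so structure choice and parameter dimension
#' are linked — as required for joint model/parameter inference.
#'
#' @param structure Character vector, non-empty subset of [hxt_repressors()].
#' @param aH Maximal synthesis rate (a.u./h), > 0.
#' @param dHmax,dHmin Degradation rate (1/h) at zero and saturating glucose;
#'   `dHmax >= dHmin >= 0` (the Hxt degrades faster when glucose is absent).
#' @param K_dH Glucose half-saturation of degradation (% w/v), > 0.
#' @param K Named numeric of dissociation constants, one per structure member.
#' @param n Named numeric of Hill numbers in `[1, 8]`, one per member.
#' @return A `promoter_params` object (list).
#' @export
promoter_params <- function(structure, aH, dHmax, dHmin, K_dH, K, n) {
  structure <- canon_repressor(structure)
  structure <- structure[order(match(structure, hxt_repressors()))]
  if (length(structure) == 0) rlang::abort("promoter structure must be non-empty")
  if (aH <= 0) rlang::abort("aH must be > 0")
  if (!(dHmax >= dHmin && dHmin >= 0)) rlang::abort("need dHmax >= dHmin >= 0")
  if (K_dH <= 0) rlang::abort("K_dH must be > 0")
  K <- K[structure]
  n <- n[structure]
  if (anyNA(K) || anyNA(n)) {
    rlang::abort("K and n must be named and cover every repressor in the structure")
  }
  if (any(K <= 0)) rlang::abort("dissociation constants must be > 0")
  if (any(n < 1 | n > 8)) rlang::abort("Hill numbers must lie in [1, 8]")
  structure(
    list(
      structure = structure, aH = aH, dHmax = dHmax, dHmin = dHmin,
      K_dH = K_dH, K = K, n = n
    ),
    class = "promoter_params"
  )
}

#' @export
print.promoter_params <- function(x, ...) {
  cat("<promoter_params> ", structure_label(x$structure), "\n", sep = "")
  cat(sprintf("  aH = %.4g, dH in [%.4g, %.4g], K_dH = %.4g\n", x$aH, x$dHmin, x$dHmax, x$K_dH))
  for (r in x$structure) {
    cat(sprintf("  %s: K = %.4g, n = %.3g\n", r, x$K[[r]], x$n[[r]]))
  }
  invisible(x)
}

check_levels <- function(levels, structure) {
  miss <- setdiff(structure, names(levels))
  if (length(miss) > 0) {
    rlang::abort(paste0("missing repressor level(s): ", paste(miss, collapse = ", ")))
  }
}

#' Promoter repression weight
#'
#' The weight by which bound repressors diminish expression:
#' `W = sum_i (R_i / K_i)^(n_i)` over the repressors in the structure, where
#' `R_i` is the active (nuclear) amount of repressor `i`. Additive over
#' repressors and zero when all included levels are zero.
#'
#' @param levels Named numeric of repressor amounts; must cover the structure.
#' @param promoter A [promoter_params()].
#' @return Non-negative scalar.
#' @export
repression_weight <- function(levels, promoter) {
  check_levels(levels, promoter$structure)
  R <- unlist(levels)[promoter$structure]
  sum((R / promoter$K)^promoter$n)
}

#' Promoter transcription rate
#'
#' `aH / (1 + W)` with `W` the [repression_weight()]: equals `aH` when
#' unrepressed and decreases strictly in every included repressor level.
#'
#' @inheritParams repression_weight
#' @return Rate (a.u./h).
#' @export
transcription_rate <- function(levels, promoter) {
  promoter$aH / (1 + repression_weight(levels, promoter))
}

#' Repression weight of one repressor pair
#'
#' Partial sum of the repression weight restricted to the glucose-pulled pair
#' (`"MthStd"`: Mth1 + Std1) or the glucose-pushed pair (`"MigMig"`:
#' Mig1 + Mig2). Repressors absent from the structure contribute zero, so the
#' two pair weights always add to the total weight.
#'
#' @inheritParams repression_weight
#' @param pair `"MthStd"` or `"MigMig"`.
#' @return Non-negative scalar.
#' @export
pair_repression <- function(levels, promoter, pair = c("MthStd", "MigMig")) {
  pair <- match.arg(pair)
  members <- if (pair == "MthStd") c("Mth1", "Std1") else c("Mig1", "Mig2")
  present <- intersect(promoter$structure, members)
  if (length(present) == 0) return(0)
  check_levels(levels, present)
  R <- unlist(levels)[present]
  sum((R / promoter$K[present])^promoter$n[present])
}

#' Serialise / deserialise promoter parameters as JSON
#'
#' Schema: `{"structure": ["Mth1","Mig1"], "aH": ..., "dHmax": ...,
#' "dHmin": ..., "K_dH": ..., "K": {...}, "n": {...}}`. Structure strings are
#' case-insensitive on read.
#'
#' @param promoter A [promoter_params()].
#' @param path File path.
#' @return `read_promoter_params()` returns a [promoter_params()];
#'   `write_promoter_params()` returns `path` invisibly.
#' @export
write_promoter_params <- function(promoter, path) {
  jsonlite::write_json(
    list(
      structure = promoter$structure, aH = promoter$aH, dHmax = promoter$dHmax,
      dHmin = promoter$dHmin, K_dH = promoter$K_dH,
      K = as.list(promoter$K), n = as.list(promoter$n)
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_promoter_params
#' @export
read_promoter_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  promoter_params(
    structure = x$structure, aH = x$aH, dHmax = x$dHmax, dHmin = x$dHmin,
    K_dH = x$K_dH, K = unlist(x$K), n = unlist(x$n)
  )
}
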