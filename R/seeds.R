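# Seed plumbing: one root seed per analysis, child streams derived per
# (operation, unit) so results do not depend on iteration order.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a root seed and a stream label
#'
#' Deterministic 31-bit integer hash mixing the root seed with a label
#' (e.g. `"beta_nti:S1:S4"`), so per-pair random streams are independent
#' of the order in which pairs are visited.
#'
#' @param seed integer root seed.
#' @param ... label components, coerced to character and joined by ":".
#' @return integer in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, ...) {
  label <- paste(vapply(list(...), as.character, character(1L)), collapse = ":")
  h <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(label)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}
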