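#' @keywords internal
"_PACKAGE"

#' Sentinel label for pixels whose region has no selected ancestor
#'
#' Custom-granularity region maps use this value for atlas regions that are
#' not absorbed by any selected region of the hierarchy. It is distinct from
#' background (0). Rendered as "Unassigned" in reports.
#'
#' @format An integer scalar, `-1L`.
#' @export
UNASSIGNED <- -1L

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All stochastic operations in the package
# route through this so generators are pure functions of (parameters, seed).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
    set.seed(seed)
  }
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}
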