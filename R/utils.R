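# Internal helpers: seeded RNG scoping, argument checks, small array utilities.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that library code never perturbs the
#' caller's RNG stream. All stochastic operations in the package run through
#' this helper, which is what makes runs pure functions of their seeds.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministically derive a child seed from a master seed and an index.
# Kept below 2^31 - 1; a simple LCG-style mix is enough for stream separation.
derive_seed <- function(master, index) {
  m <- 2147483647
  as.integer((as.double(master) * 48271 + as.double(index) * 16807 + 12345) %% m)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_binary <- function(x, tol = 0) {
  all(x %in% c(0, 1)) || all(abs(x) <= tol | abs(x - 1) <= tol)
}

# uint8 image array helpers ---------------------------------------------------

check_rgb <- function(image) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L)
    stopf("expected an H x W x 3 image array, got dims [%s]",
          paste(d, collapse = ", "))
  invisible(d)
}

# round-half-up (base R round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)
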