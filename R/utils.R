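#' @keywords internal
#' @useDynLib mcfdti, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

## Seed plumbing: one user-facing seed fans out to named sub-streams so that
## sampling, parameter init, shuffling and dropout are independently
## reproducible.  Derived seeds stay below 2^31 - 1.
derive_seed <- function(seed, what) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offsets <- c(sampling = 101L, init = 211L, shuffle = 307L, dropout = 401L,
               folds = 503L, drugs = 601L, targets = 701L, pairs = 809L,
               noise = 907L, kd = 1009L, train = 1103L)
  off <- offsets[[what]]
  as.integer((as.double(seed) * 48271 + off * 1009) %% 2147483647)
}

## Evaluate expr under a temporary RNG state; the global stream is restored.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

## The 20 standard amino-acid one-letter codes.
AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
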