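#' @importFrom Matrix Matrix sparseMatrix rowSums colSums t crossprod Diagonal
#' @importFrom methods as is new
#' @importFrom stats rnbinom rlnorm runif rnorm quantile p.adjust prcomp
#'   pnorm dpois cor sd var setNames
#' @importFrom utils head read.delim write.csv combn packageVersion
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible 31-bit sub-seed from a base seed and a stage name, so
# pipeline stages can be rerun in isolation with the same stream.
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(as.integer(charToRaw(stage)) * seq_along(charToRaw(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_dgc <- function(m) as(as(as(m, "dMatrix"), "generalMatrix"), "CsparseMatrix")

stop_regioglia <- function(...) stop(sprintf(...), call. = FALSE)
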