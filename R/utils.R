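#' @useDynLib polysel, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef cov glm lm quantile quasibinomial quasipoisson
#'   rgeom rmultinom rpois sd setNames var
#' @importFrom utils combn packageVersion read.csv write.csv
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## Run `expr` under a local RNG state seeded with `seed`; the caller's
## .Random.seed is restored afterwards so library code never perturbs the
## user's stream.  seed = NULL means "use the current stream".
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

## Derive a reproducible per-stage seed from a top-level seed, keeping the
## result inside the 32-bit integer range.
substream_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  offs <- c(simulate = 101L, bootstrap = 211L, randomize = 307L,
            resample = 401L, pipeline = 503L)
  off <- offs[[stage]]
  as.integer((as.numeric(seed) * 7919 + off) %% 2147483647)
}

stop_polysel <- function(...) {
  stop(paste0(...), call. = FALSE)
}
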