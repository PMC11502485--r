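`%||%` <- function(x, y) if (is.null(x)) y else x

# Run code with a temporary RNG state; restores .Random.seed afterwards so
# estimator-internal bootstraps do not perturb the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

DNA_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(a1, a2) DNA_COMPLEMENT[a1] == a2

# smallest representable two-sided p, used to keep p-values in (0, 1]
clamp_pval <- function(p) pmax(p, .Machine$double.xmin)
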