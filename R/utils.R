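#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

# Dirichlet sampler via normalized gammas; alpha recycled to length k.
rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  s <- sum(x)
  if (s == 0) {
    # extremely small alphas can underflow; fall back to a point mass
    x[sample.int(length(alpha), 1L)] <- 1
    s <- 1
  }
  x / s
}

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

n1pas_log <- function(...) {
  message("[n1pas] ", ...)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
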