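#' @keywords internal
"_PACKAGE"

#' @importFrom stats cov dist kmeans pchisq pnorm qnorm rbinom rexp rnorm runif
#'   sd setNames aggregate rweibull
#' @importFrom utils read.csv write.csv head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Run `expr` under a fixed RNG seed without disturbing the caller's stream.
## seed = NULL leaves the current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

## Derive a child seed from a base seed; keeps values well inside 32-bit range.
child_seed <- function(seed, ...) {
  if (is.null(seed)) return(NULL)
  offsets <- c(...)
  s <- as.double(seed)
  for (o in offsets) s <- (s * 1103L + as.double(o)) %% 2147480000
  as.integer(s)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stopf("`%s` must be a single positive finite number", name)
  }
  invisible(x)
}
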