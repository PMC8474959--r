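# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate code with a local, restored RNG state
#'
#' Seeds the RNG, runs `code`, then restores whatever RNG state existed
#' before the call, so seeded package routines do not perturb the caller's
#' random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-stream seed derived from a base seed and a path of
# labels. Hierarchical splitting means adding populations/chromosomes never
# perturbs draws belonging to earlier labels. Kept below 2^31 - 1.
subseed <- function(seed, ...) {
  path <- paste(c(format(seed), ...), collapse = "/")
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(path)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
msgf  <- function(fmt, ...) message(sprintf(fmt, ...))
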