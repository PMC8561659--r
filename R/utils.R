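#' @importFrom methods new validObject is slot
#' @importFrom stats rnorm rpois rmultinom rbinom runif median cor.test
#'   t.test lm coef cmdscale setNames var dist
#' @importFrom utils read.delim write.table read.csv write.csv head
NULL

# Deterministic sub-seed so the cohort, event, count and qPCR stages can be
# regenerated independently from one user-facing seed.  Plain polynomial hash
# folded into the 31-bit range accepted by set.seed().
substreamSeed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(seed) * 48271 + h) %% 2147483629 + 1)
}

withSeed <- function(seed, expr) {
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

# Renormalise a non-negative vector to a probability simplex.
renorm <- function(x) {
  s <- sum(x)
  if (s <= 0) stop("cannot renormalise a vector with non-positive sum")
  x / s
}

# log-space tilt: multiply composition by exp(delta) and renormalise.
tiltComposition <- function(p, delta) renorm(p * exp(delta))

msg <- function(...) message("[microload] ", ...)
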