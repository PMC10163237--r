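#' Derive a reproducible child seed from a global seed and a stage tag
#'
#' Every stochastic stage of the pipeline draws its own seed from the single
#' global seed through this splitting rule, so any stage can be re-run in
#' isolation and still reproduce its output. The rule hashes the tag string
#' into an integer offset and mixes it with the parent seed by a
#' linear-congruential step, keeping the result in `[0, 2^31 - 2]`.
#'
#' @param seed Integer parent seed.
#' @param tag Character scalar naming the consumer (e.g. `"schedule"`,
#'   `"behavior.day2"`).
#' @return A single integer seed.
#' @examples
#' child_seed(1, "schedule")
#' child_seed(1, "population")
#' @export
child_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(tag))
  m <- 2147483647 # 2^31 - 1, prime
  h <- 0
  for (k in utf8ToInt(tag)) h <- (h * 131 + k) %% m
  s <- (as.double(seed) %% m)
  as.integer((s * 48271 + h) %% m)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
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
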