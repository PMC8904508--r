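## Reproducible sub-streams.  A single user-facing integer seed is folded
## together with string/integer keys (stage, group, individual, ...) into a
## 31-bit seed, so every simulation stage gets its own stream and results do
## not depend on evaluation order.

.RNG_M <- 2147483647  # 2^31 - 1, Mersenne prime; all arithmetic exact in doubles

#' Derive a deterministic sub-seed from a base seed and arbitrary keys
#'
#' Folds the base seed and any number of string/numeric keys into a single
#' integer in `[1, 2^31 - 2]` with a multiplicative string hash. Used
#' throughout the simulators so that per-stage, per-group and per-individual
#' random streams are independent of the order in which stages run.
#'
#' @param seed Integer base seed.
#' @param ... Keys (coerced to character) identifying the sub-stream.
#' @return A single integer seed.
#' @export
#' @examples
#' subSeed(1, "frequencies", "popA")
subSeed <- function(seed, ...) {
  parts <- unlist(lapply(list(...), as.character), use.names = FALSE)
  h <- as.numeric(seed) %% .RNG_M
  for (p in parts) {
    for (cc in utf8ToInt(p)) h <- (h * 31 + cc) %% .RNG_M
    h <- (h * 131 + 17) %% .RNG_M
  }
  as.integer(h %% (.RNG_M - 2) + 1)
}

## Evaluate `expr` under `set.seed(seed)` and restore the caller's RNG state.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Vectorised per-site uniform in (0, 1), keyed by (seed, chrom, pos, lib).
## A small multiplicative congruential mix: exact in double precision because
## 48271 * 2^31 < 2^53.  Stable under row permutation and subsetting, which is
## what makes pseudo-haploid calls reproducible site by site.
siteUniform <- function(seed, chrom, pos, lib = "") {
  M <- .RNG_M
  ch <- vapply(unique(as.character(chrom)), function(s) subSeed(0L, s), 1L)
  li <- vapply(unique(as.character(lib)), function(s) subSeed(0L, s), 1L)
  h <- rep(as.numeric(seed) %% M, length(pos))
  h <- (h * 48271 + as.numeric(ch[as.character(chrom)])) %% M
  h <- (h * 48271 + as.numeric(pos)) %% M
  h <- (h * 48271 + as.numeric(li[as.character(lib)])) %% M
  h <- (h * 48271 + 11) %% M
  h <- (h * 48271 + 13) %% M
  (h + 0.5) / M
}
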