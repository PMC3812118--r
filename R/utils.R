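# Shared internal helpers: seeded substreams and permutation p-values.

#' Derive a deterministic sub-seed from a master seed and a component name
#'
#' All stochastic components of the package draw their random numbers from a
#' named substream so that, e.g., adding genes to a simulation does not
#' reshuffle the parental draws. The sub-seed is a 31-bit integer obtained by
#' hashing the component name into the master seed.
#'
#' Related `(seed, name)` inputs must give effectively independent streams:
#' a plain additive hash leaves constant offsets between related names, and
#' generator streams seeded at constant offsets can carry detectable
#' structure across replicate datasets. The hash is therefore scrambled
#' through one Mersenne-Twister draw, which decorrelates the derived
#' seeds; the caller's RNG state is left untouched.
#'
#' @param seed master integer seed.
#' @param name character scalar naming the substream.
#' @return an integer in `[1, 2^31 - 1)` suitable for [set.seed()].
#' @examples
#' substream_seed(1, "parental") != substream_seed(1, "residual")
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(name))
  codes <- utf8ToInt(name)
  h <- 0
  for (k in codes) h <- (h * 131 + k) %% 2147483647
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
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
  set.seed((abs(seed) + h) %% 2147483647)
  sample.int(2147483645L, 1)
}

with_substream <- function(seed, name, expr) {
  set.seed(substream_seed(seed, name))
  expr
}

#' Permutation p-value with add-one correction
#'
#' Returns `(b + 1) / (n + 1)` where `b` counts null statistics at least as
#' extreme as the observed one, so a permutation p-value is never exactly 0.
#'
#' @param null_stats numeric vector of null statistics.
#' @param observed observed statistic.
#' @return p-value in `(0, 1]`.
#' @export
perm_pvalue <- function(null_stats, observed) {
  null_stats <- null_stats[is.finite(null_stats)]
  (sum(null_stats >= observed) + 1) / (length(null_stats) + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# file checksum used by the pipeline manifest
file_checksum <- function(path) unname(tools::md5sum(path))
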