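#' Derive a reproducible sub-stream seed
#'
#' Maps a master seed plus an arbitrary character key to an integer seed in
#' `[1, 2^31 - 2]`. Used so that every randomised unit of work (a plot pair, a
#' technical replicate, a simulation repeat) draws from its own stream and the
#' result does not depend on evaluation order.
#'
#' @param master integer master seed.
#' @param key character scalar naming the sub-stream.
#' @return integer seed.
#' @export
derive_seed <- function(master, key) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(key),
            length(key) == 1L)
  m <- 2147483647   # 2^31 - 1, Mersenne prime
  h <- as.double(master %% m)
  for (code in utf8ToInt(key)) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h %% (m - 2)) + 1L
}

#' Unordered plot-pair key
#'
#' Canonical key for a pair of plot ids, independent of argument order.
#' @param a,b character vectors of plot ids.
#' @return character vector of keys.
#' @keywords internal
pair_key <- function(a, b) {
  ifelse(a < b, paste(a, b, sep = "|"), paste(b, a, sep = "|"))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
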