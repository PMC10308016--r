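#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic 32-bit string hash (djb2), used for seed substreams and
# model checksums; keeps every derived seed well inside .Machine$integer.max
hash32 <- function(s) {
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  as.integer(h)
}

#' Derive a reproducible substream seed
#'
#' Fans a single user-facing seed out to named pipeline stages so that each
#' stage (generation, splitting, fitting, ...) is independently reproducible.
#'
#' @param seed Integer master seed.
#' @param label Character stage label.
#' @return An integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  hash32(paste0(format(seed, scientific = FALSE), "/", label))
}

stop_domain <- function(...) stop(..., call. = FALSE)

assert_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop_domain(name, " must be a probability in [0, 1]")
  }
  invisible(x)
}
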