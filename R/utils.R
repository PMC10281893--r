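#' @keywords internal
"_PACKAGE"

# Classed error helper: every condition carries "breath4dct_error" plus a
# specific subclass that tests and callers can dispatch on.
b4_stop <- function(subclass, msg, call. = FALSE) {
  stop(errorCondition(msg, class = c(subclass, "breath4dct_error", "error")))
}

b4_assert <- function(ok, subclass, msg) {
  if (!isTRUE(ok)) b4_stop(subclass, msg)
  invisible(TRUE)
}

#' Derive a child seed from a master seed
#'
#' Stable integer hash used to give every synthetic curve its own
#' reproducible random stream.  The hash is a Lehmer-style multiplicative
#' step modulo the Mersenne prime 2^31 - 1, so child seeds stay inside the
#' 32-bit integer range regardless of cohort size.
#'
#' @param master_seed integer master seed.
#' @param index non-negative integer (e.g. curve index within a cohort).
#' @param salt optional extra integer to separate independent streams
#'   (e.g. one value per cohort).
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(master_seed, index, salt = 0L) {
  m <- 2147483647 # 2^31 - 1
  h <- (abs(as.numeric(master_seed)) %% m)
  h <- (h * 48271 + abs(as.numeric(salt))) %% m
  h <- (h * 48271 + abs(as.numeric(index))) %% m
  h <- (h * 48271 + 1) %% m
  as.integer(h %% (m - 1) + 1)
}

# Nearly-equal helper for uniform-spacing checks.
rel_diff <- function(x, y) abs(x - y) / pmax(abs(y), .Machine$double.eps)
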