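# Internal helpers shared across modules.

#' Raise a typed error
#'
#' All errors raised by the package carry class `"ahadjust_error"` plus a
#' more specific subclass so callers (notably the bootstrap and the
#' simulation engine) can catch and count them without string matching.
#'
#' @param message error message.
#' @param class specific condition class, e.g. `"ahadjust_input_error"`.
#' @noRd
ah_error <- function(message, class) {
  stop(errorCondition(message, class = c(class, "ahadjust_error", "error")))
}

#' Derive a reproducible substream seed
#'
#' Maps a (master seed, index) pair to an integer in `[0, 2^31 - 2]` so that
#' replicate `i` always sees the same seed regardless of how many other
#' substreams were consumed. The multiplier/increment are from classical
#' Lehmer-style mixers; all arithmetic stays exact in doubles.
#'
#' @param seed integer master seed.
#' @param i nonnegative integer substream index.
#' @return an integer seed usable with [set.seed()].
#' @export
#' @examples
#' substream_seed(42, 1)
substream_seed <- function(seed, i) {
  s <- (as.double(seed) %% 2147483647) * 69069 %% 2147483647
  as.integer((s + as.double(i) * 104729) %% 2147483647)
}

# Build a design matrix from term labels such as "X1" or "X5^2"; the only
# transform supported is squaring, written with the "^2" suffix.
term_matrix <- function(terms, x) {
  if (length(terms) == 0L) {
    return(matrix(numeric(0), nrow = nrow(x), ncol = 0))
  }
  cols <- lapply(terms, function(tm) {
    base <- sub("\\^2$", "", tm)
    if (!base %in% names(x)) {
      ah_error(sprintf("term '%s' refers to unknown covariate '%s'", tm, base),
               "ahadjust_input_error")
    }
    v <- as.numeric(x[[base]])
    if (grepl("\\^2$", tm)) v^2 else v
  })
  m <- do.call(cbind, cols)
  colnames(m) <- terms
  m
}
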