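#' Channel and structure naming
#'
#' Channels are labeled A, B, C, ... in chain order. A *structure* is a
#' contiguous span of channels: for k = 3 the six structures are
#' ABC, AB, BC, A, B, C. Structure names are the concatenated channel
#' letters of the span.
#'
#' @param k number of channels (2--26)
#' @return `structure_names()` returns all contiguous-span names ordered by
#'   decreasing length, then left-to-right start; `channel_letters()` the
#'   per-channel labels.
#' @examples
#' structure_names(3) # "ABC" "AB" "BC" "A" "B" "C"
#' @export
structure_names <- function(k) {
  stopifnot(k >= 1, k <= 26)
  out <- character(0)
  for (len in seq(k, 1)) {
    for (start in seq_len(k - len + 1)) {
      out <- c(out, paste(LETTERS[start:(start + len - 1)], collapse = ""))
    }
  }
  out
}

#' @rdname structure_names
#' @export
channel_letters <- function(k) LETTERS[seq_len(k)]

# span (start, end) for a structure name like "BC"; error if the name is
# not a contiguous channel run
structure_span <- function(name, k) {
  chars <- strsplit(name, "")[[1]]
  idx <- match(chars, LETTERS[seq_len(k)])
  if (anyNA(idx)) {
    stop("unknown channel letter in structure name '", name, "'")
  }
  if (length(idx) > 1 && any(diff(idx) != 1L)) {
    stop("structure '", name, "' is not a contiguous channel span; ",
         "chains are contiguous by construction")
  }
  c(idx[1], idx[length(idx)])
}

span_name <- function(start, end) {
  paste(LETTERS[start:end], collapse = "")
}

# all contiguous spans of length >= 2, longest first, left-to-right:
# the default Mode I leftover priority (full span excluded by the caller)
default_priority <- function(k) {
  nm <- structure_names(k)
  nm[nchar(nm) >= 2]
}
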