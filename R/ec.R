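#' Enzyme Commission (EC) number utilities
#'
#' EC identifiers are four dot-separated fields, each a number or a dash
#' wildcard (family-level identifiers such as `"6.3.-.-"` are common in
#' pathway databases and are kept verbatim throughout this package).
#'
#' `ec_is_valid()` checks the shape. `ec_match()` tests whether a concrete or
#' family-level EC falls under a (possibly wildcarded) pattern: every non-dash
#' field of the pattern must equal the corresponding field of `ec`.
#'
#' @param ec,pattern EC strings such as `"2.4.1.203"` or `"2.4.1.-"`.
#' @return `ec_is_valid()` a logical vector; `ec_match()` a logical vector.
#' @examples
#' ec_match("2.4.1.203", "2.4.1.-")   # TRUE
#' ec_match("1.14.13.93", "1.14.11.-") # FALSE
#' @export
ec_match <- function(ec, pattern) {
  if (length(pattern) == 1L && length(ec) > 1L) pattern <- rep(pattern, length(ec))
  stopifnot(length(ec) == length(pattern))
  bad <- !ec_is_valid(ec) | !ec_is_valid(pattern)
  if (any(bad)) {
    stop("malformed EC string(s): ",
         paste(unique(c(ec[!ec_is_valid(ec)], pattern[!ec_is_valid(pattern)])), collapse = ", "))
  }
  mapply(function(e, p) {
    ef <- strsplit(e, ".", fixed = TRUE)[[1]]
    pf <- strsplit(p, ".", fixed = TRUE)[[1]]
    all(pf == "-" | pf == ef)
  }, ec, pattern, USE.NAMES = FALSE)
}

#' @rdname ec_match
#' @export
ec_is_valid <- function(ec) {
  grepl("^([0-9]+|-)\\.([0-9]+|-)\\.([0-9]+|-)\\.([0-9]+|-)$", ec)
}

# Sortable key for node identifiers. EC numbers sort by their numeric fields
# (dashes after any number, so "1.3.1.-" precedes "1.14.17.4"); other ids sort
# as plain strings. Used to canonicalize routes, paths and cycles.
node_sort_key <- function(ids) {
  vapply(ids, function(id) {
    if (isTRUE(ec_is_valid(id))) {
      f <- strsplit(id, ".", fixed = TRUE)[[1]]
      n <- ifelse(f == "-", 99999L, suppressWarnings(as.integer(f)))
      paste(sprintf("%05d", n), collapse = ".")
    } else {
      id
    }
  }, character(1), USE.NAMES = FALSE)
}

# TRUE when a precedes b under the node ordering.
node_lt <- function(a, b) node_sort_key(a) < node_sort_key(b)

# Arabidopsis-style locus shape: two letters, chromosome digit, 'G', digits.
# `permissive = TRUE` accepts any non-empty token (synthetic datasets).
locus_is_valid <- function(ids, permissive = FALSE) {
  if (permissive) nzchar(ids) else grepl("^[A-Za-z]{2}[0-9]G[0-9]+$", ids)
}
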