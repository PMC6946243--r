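# Shared low-level helpers: alias normalization and tokenization.

# Normalized matching key: case-folded with all non-alphanumerics removed,
# so "IL-6", "il 6" and "IL6" share the key "il6".
normalizeKey <- function(x) {
  gsub("[^a-z0-9]", "", tolower(x))
}

# Alphanumeric token runs with 0-based half-open character positions.
# Returns one data.frame row per token; `item` indexes the input string.
tokenizeAll <- function(strings) {
  m <- gregexpr("[A-Za-z0-9]+", strings)
  lens <- vapply(m, function(x) if (x[1] == -1L) 0L else length(x), 0L)
  item <- rep(seq_along(strings), lens)
  start <- unlist(lapply(m, function(x) if (x[1] == -1L) integer(0) else as.integer(x)))
  width <- unlist(lapply(m, function(x) {
    if (x[1] == -1L) integer(0) else attr(x, "match.length")
  }))
  if (is.null(start)) start <- integer(0)
  if (is.null(width)) width <- integer(0)
  token <- substring(strings[item], start, start + width - 1L)
  data.frame(item = item, start = start - 1L, end = start - 1L + width,
             token = token, stringsAsFactors = FALSE)
}

# 0-based half-open substring extraction.
substr0 <- function(x, start, end) substring(x, start + 1L, end)

# Canonicalize an unordered gene pair: a < b lexicographically.
canonicalPair <- function(a, b) {
  swap <- a > b
  list(a = ifelse(swap, b, a), b = ifelse(swap, a, b))
}

stopifnotScalarProb <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1)
    stop(sprintf("%s must be a single probability in (0, 1)", name),
         call. = FALSE)
}
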