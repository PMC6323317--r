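#' Tokenize text into tokens with character spans
#'
#' Splits on whitespace, then peels leading and trailing punctuation
#' characters off each chunk as single-character tokens. A trailing closing
#' bracket is kept attached when its matching opener occurs inside the same
#' chunk, so units such as `P2Y(2)` survive as one token. Offsets are
#' 0-based, half-open, relative to `text`.
#'
#' @param text A single character string.
#' @return A data.frame with columns `token`, `start`, `end`.
#' @examples
#' tokenize_text("SGT interacts with the GHR.")
#' @export
tokenize_text <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- data.frame(token = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(text)) return(empty)

  m <- gregexpr("\\S+", text)[[1]]
  if (m[1] == -1) return(empty)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")

  out_tok <- character(0)
  out_start <- integer(0)
  for (i in seq_along(starts)) {
    chunk <- substr(text, starts[i], starts[i] + lens[i] - 1L)
    pos <- starts[i]
    parts <- .peel_chunk(chunk)
    for (p in parts) {
      out_tok <- c(out_tok, p)
      out_start <- c(out_start, pos)
      pos <- pos + nchar(p)
    }
  }
  data.frame(token = out_tok,
             start = out_start - 1L,              # to 0-based
             end = out_start - 1L + nchar(out_tok),
             stringsAsFactors = FALSE)
}

.openers <- c(")" = "(", "]" = "[", "}" = "{")

.peel_chunk <- function(chunk) {
  lead <- character(0)
  trail <- character(0)
  repeat {
    n <- nchar(chunk)
    if (n <= 1L) break
    first <- substr(chunk, 1L, 1L)
    last <- substr(chunk, n, n)
    if (grepl("^[[:punct:]]$", first) && !first %in% c("(", "[", "{")) {
      lead <- c(lead, first); chunk <- substr(chunk, 2L, n); next
    }
    if (first %in% c("(", "[", "{")) {
      # keep an opener only if it is closed within the chunk
      closer <- names(.openers)[match(first, .openers)]
      if (!grepl(closer, chunk, fixed = TRUE)) {
        lead <- c(lead, first); chunk <- substr(chunk, 2L, n); next
      }
    }
    if (grepl("^[[:punct:]]$", last)) {
      if (last %in% names(.openers) &&
          grepl(.openers[[last]], chunk, fixed = TRUE)) break
      trail <- c(last, trail); chunk <- substr(chunk, 1L, n - 1L); next
    }
    break
  }
  c(lead, chunk, trail)
}

# Abbreviations that do not terminate a sentence when followed by a period.
.abbreviations <- c(
  "e.g", "i.e", "cf", "vs", "ca", "approx", "etc", "al", "et", "fig", "figs",
  "ref", "refs", "no", "nos", "dr", "mr", "mrs", "ms", "prof", "inc", "ltd",
  "st", "jr", "sr", "sp", "spp", "var", "min", "max", "mol", "wt", "vol"
)

#' Split text into sentences
#'
#' Rule-based splitter: a run of `.`, `!` or `?` followed by whitespace and
#' an upper-case letter, digit, or opening quote/bracket ends a sentence,
#' unless the word preceding the terminator is a known abbreviation or a
#' single letter (initials). Tab and newline characters are hard sentence
#' boundaries (the title/body separator of a ChemProt document is a tab).
#' Deterministic; whole text as one sentence is a legal output.
#'
#' @param text A single character string.
#' @param abbreviations Character vector of abbreviation tokens (without the
#'   trailing period, case-insensitive) that never end a sentence.
#' @return A data.frame with columns `start`, `end` (0-based half-open spans
#'   into `text`, trimmed of surrounding whitespace) and `text`.
#' @export
split_sentences <- function(text, abbreviations = .abbreviations) {
  stopifnot(is.character(text), length(text) == 1L)
  n <- nchar(text)
  if (n == 0L) {
    return(data.frame(start = integer(), end = integer(), text = character(),
                      stringsAsFactors = FALSE))
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  breaks <- integer(0)  # 1-based index of last char of a sentence
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c("\t", "\n")) {
      breaks <- c(breaks, i - 1L)
      i <- i + 1L
      next
    }
    if (ch %in% c(".", "!", "?")) {
      j <- i
      while (j < n && chars[j + 1L] %in% c(".", "!", "?")) j <- j + 1L
      # require whitespace then an upper-case/digit/open-quote lookahead
      k <- j + 1L
      if (k > n) { breaks <- c(breaks, j); break }
      if (grepl("^[ \t\n]$", chars[k])) {
        while (k <= n && grepl("^[ \t\n]$", chars[k])) k <- k + 1L
        ok <- k <= n && grepl('^[A-Z0-9"\'(\\[]$', chars[k])
        if (ok && ch == ".") {
          word <- sub(".*?([A-Za-z0-9.]+)$", "\\1",
                      substr(text, max(1L, i - 30L), i - 1L))
          word <- sub("\\.+$", "", word)
          # an upper-case single letter is an initial, not a sentence end
          if (tolower(word) %in% tolower(abbreviations) ||
              grepl("^[A-Z]$", word)) ok <- FALSE
        }
        if (ok) breaks <- c(breaks, j)
      }
      i <- j + 1L
      next
    }
    i <- i + 1L
  }
  bounds <- unique(c(breaks, n))
  start <- 1L
  out <- list()
  for (b in bounds) {
    seg <- substr(text, start, b)
    # trim whitespace but keep offsets
    lead <- regmatches(seg, regexpr("^[ \t\n]*", seg))
    tr <- regmatches(seg, regexpr("[ \t\n]*$", seg))
    s0 <- start + nchar(lead)
    e0 <- b - nchar(tr)
    if (e0 >= s0) {
      out[[length(out) + 1L]] <- data.frame(
        start = s0 - 1L, end = e0,
        text = substr(text, s0, e0), stringsAsFactors = FALSE)
    }
    start <- b + 1L
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(), text = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
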