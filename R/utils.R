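# Internal helpers shared across modules.

# Unit separator: never occurs in normalized lemmas, safe pair-key delimiter.
.PAIR_SEP <- "\u001f"

#' Normalize text for matching
#'
#' Applies Unicode NFKC normalization followed by case folding (lower case).
#' All substring matching in the package -- profile search, dictionary
#' lookup, synonym lookup, node identity -- goes through this function, so
#' full-width/half-width script variants and case differences collapse to a
#' single form.
#'
#' @param x character vector.
#' @return character vector of the same length, NFKC-normalized and
#'   case-folded.
#' @export
#' @examples
#' normalize_text(c("CT", "ＣＴ"))  # both become "ct"
normalize_text <- function(x) {
  stringi::stri_trans_tolower(stringi::stri_trans_nfkc(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
    x == as.integer(x)
}

.is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

# Encode an unordered pair as a single sorted key (and back).
.pair_key <- function(w1, w2) {
  lo <- pmin(w1, w2)
  hi <- pmax(w1, w2)
  paste(lo, hi, sep = .PAIR_SEP)
}

.split_pair_keys <- function(keys) {
  if (length(keys) == 0L) {
    return(matrix(character(0), ncol = 2L,
                  dimnames = list(NULL, c("word1", "word2"))))
  }
  parts <- stringi::stri_split_fixed(keys, .PAIR_SEP, simplify = TRUE)
  colnames(parts) <- c("word1", "word2")
  parts
}

.parse_time <- function(x, where = "posted_at") {
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC")
  bad <- is.na(out) & !is.na(x)
  if (any(bad)) {
    stop(sprintf("invalid ISO-8601 UTC timestamp in %s: '%s'",
                 where, x[which(bad)[1L]]), call. = FALSE)
  }
  out
}

.format_time <- function(x) {
  format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
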