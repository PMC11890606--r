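#' @useDynLib tweetformer, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif
#' @importFrom utils head tail
NULL

# package-local cache (emoji table etc.)
.tf_cache <- new.env(parent = emptyenv())

#' Preprocessing options
#'
#' Switches for the tweet-normalization pipeline. Defaults reproduce the
#' standard pipeline: lowercase everything, map digit runs to the reserved
#' token `number`, cap letter elongations at two repeats, and strip `#`/`@`
#' so hashtags and mentions fall back to their bare word.
#'
#' @param caps_marker prepend `allcaps_` to words written in ALL CAPS before
#'   lowercasing (default `FALSE`).
#' @param replace_numbers replace each maximal digit run with the reserved
#'   token `number` (default `TRUE`; `FALSE` keeps digits).
#' @param elongation_cap maximum number of consecutive repeats of a character
#'   kept in the output (default 2, so `"soooo"` becomes `"soo"`).
#' @param mention_token replace `@user` mentions with the reserved token
#'   `mention` instead of stripping the `@` (default `FALSE`).
#' @return A list of class `tf_preprocess_options`.
#' @export
preprocess_options <- function(caps_marker = FALSE, replace_numbers = TRUE,
                               elongation_cap = 2L, mention_token = FALSE) {
  stopifnot(elongation_cap >= 1L)
  structure(list(caps_marker = isTRUE(caps_marker),
                 replace_numbers = isTRUE(replace_numbers),
                 elongation_cap = as.integer(elongation_cap),
                 mention_token = isTRUE(mention_token)),
            class = "tf_preprocess_options")
}

emoji_table <- function() {
  if (is.null(.tf_cache$emoji)) {
    path <- system.file("extdata", "emoji_names.tsv", package = "tweetformer")
    tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                             col.names = c("hex", "name"),
                             colClasses = "character", quote = "")
    chars <- vapply(strsplit(tab$hex, "[+ ]"), function(h) {
      intToUtf8(strtoi(h, base = 16L))
    }, character(1))
    # longest first so multi-codepoint sequences (if any) win
    ord <- order(-nchar(chars))
    .tf_cache$emoji <- list(chars = chars[ord], names = tab$name[ord])
  }
  .tf_cache$emoji
}

#' Replace URLs with the reserved token `URL`
#'
#' Every maximal substring starting with `http://`, `https://` or `www.`
#' becomes the single token `URL`; all other text is untouched.
#'
#' @param text character vector.
#' @return character vector of the same length.
#' @examples
#' replace_urls("see https://t.co/abc now")
#' @export
replace_urls <- function(text) {
  stringi::stri_replace_all_regex(text, "(?i)(?:https?://|www\\.)\\S+", "URL")
}

#' Replace emoji with textual short names
#'
#' Each emoji codepoint listed in the package's versioned short-name table
#' (`inst/extdata/emoji_names.tsv`) is replaced by its underscore-joined
#' short name, surrounded by single spaces. Variation selector U+FE0F is
#' stripped before matching. Emoji absent from the table are left in place
#' (the later non-alphanumeric removal step of [normalize_text()] drops
#' them).
#'
#' @param text character vector.
#' @return character vector of the same length.
#' @examples
#' replace_emojis("ok \U0001F44D")
#' @export
replace_emojis <- function(text) {
  tab <- emoji_table()
  text <- stringi::stri_replace_all_fixed(text, "\uFE0F", "")
  hit <- stringi::stri_detect_charclass(
    text, "[\\x{2600}-\\x{27BF}\\x{2B00}-\\x{2BFF}\\x{1F000}-\\x{1FAFF}]")
  hit[is.na(hit)] <- FALSE
  if (!any(hit)) return(text)
  out <- text
  out[hit] <- stringi::stri_replace_all_fixed(
    out[hit], tab$chars, paste0(" ", tab$names, " "), vectorize_all = FALSE)
  out[hit] <- stringi::stri_trim_both(
    stringi::stri_replace_all_regex(out[hit], "\\s+", " "))
  out
}

# minimal HTML entity unescaping: named entities common in tweet dumps plus
# numeric character references; `&amp;` is resolved last so that
# double-escaped text is unescaped exactly one level per call.
unescape_html <- function(text) {
  named <- c("&lt;" = "<", "&gt;" = ">", "&quot;" = "\"", "&apos;" = "'",
             "&#39;" = "'", "&nbsp;" = " ", "&hellip;" = "…",
             "&mdash;" = "—", "&ndash;" = "–",
             "&rsquo;" = "’", "&lsquo;" = "‘",
             "&rdquo;" = "”", "&ldquo;" = "“")
  text <- stringi::stri_replace_all_fixed(text, names(named), unname(named),
                                          vectorize_all = FALSE)
  # numeric references &#NNN; and &#xHH;
  refs <- unique(unlist(stringi::stri_extract_all_regex(
    text, "&#x?[0-9a-fA-F]+;", omit_no_match = TRUE)))
  if (length(refs)) {
    vals <- vapply(refs, function(r) {
      body <- substr(r, 3L, nchar(r) - 1L)
      cp <- if (startsWith(tolower(body), "x")) {
        strtoi(substr(body, 2L, nchar(body)), base = 16L)
      } else strtoi(body, base = 10L)
      if (is.na(cp) || cp <= 0L || cp > 0x10FFFF) "" else intToUtf8(cp)
    }, character(1))
    text <- stringi::stri_replace_all_fixed(text, refs, vals,
                                            vectorize_all = FALSE)
  }
  stringi::stri_replace_all_fixed(text, "&amp;", "&")
}

#' Normalize raw tweet text
#'
#' Deterministic, idempotent normalization applied before tokenization, in
#' this fixed order: (1) HTML-entity unescaping; (2) URL replacement;
#' (3) emoji replacement with textual short names; (4) lowercasing;
#' (5) digit-run replacement with the reserved token `number`;
#' (6) elongation capping (no character three times in a row);
#' (7) replacement of remaining non-alphanumeric characters (except spaces
#' and underscores) with spaces; (8) whitespace collapse and trim.
#'
#' Replacements run before removal so that URLs and emoji are still intact
#' when they are rewritten; the reserved tokens come out lowercase (`url`,
#' `number`) because lowercasing applies to the whole string. The output
#' alphabet is exactly lowercase letters, digits, single spaces and
#' underscores, and `normalize_text(normalize_text(x)) == normalize_text(x)`.
#'
#' @param raw character vector of raw texts (may contain HTML entities,
#'   URLs, emoji, hashtags, elongations).
#' @param opts a [preprocess_options()] list.
#' @return character vector of normalized texts (possibly empty strings).
#' @examples
#' normalize_text("soooo   SICK!!! 102 fever")
#' @export
normalize_text <- function(raw, opts = preprocess_options()) {
  x <- as.character(raw)
  x[is.na(x)] <- ""
  x <- unescape_html(x)
  x <- replace_urls(x)
  if (opts$mention_token) {
    x <- stringi::stri_replace_all_regex(x, "@\\w+", " mention ")
  }
  x <- replace_emojis(x)
  if (opts$caps_marker) {
    x <- stringi::stri_replace_all_regex(x, "\\b([A-Z]{2,})\\b", "allcaps_$1")
  }
  x <- stringi::stri_trans_tolower(x)
  if (opts$replace_numbers) {
    x <- stringi::stri_replace_all_regex(x, "[0-9]+", " number ")
  }
  cap <- opts$elongation_cap
  x <- stringi::stri_replace_all_regex(
    x, sprintf("([^ ])\\1{%d,}", cap), paste(rep("$1", cap), collapse = ""))
  x <- stringi::stri_replace_all_regex(x, "[^a-z0-9_ ]+", " ")
  x <- stringi::stri_replace_all_regex(x, "\\s+", " ")
  stringi::stri_trim_both(x)
}

#' Normalize a corpus data frame
#'
#' Applies [normalize_text()] to the `text` column of a data frame with
#' columns `id`, `text` and optionally `label`.
#'
#' @param docs data frame with columns `id`, `text` and optionally `label`.
#' @param opts a [preprocess_options()] list.
#' @return the same data frame with normalized `text`.
#' @export
normalize_corpus <- function(docs, opts = preprocess_options()) {
  stopifnot(is.data.frame(docs), all(c("id", "text") %in% names(docs)))
  docs$text <- normalize_text(docs$text, opts)
  docs
}
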