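## Text preprocessing: tokenization, stop-word filtering, Porter stemming.
## The stemmer is a from-scratch implementation of the classic Porter (1980)
## algorithm including the author's later official revisions (bli -> ble,
## logi -> log); no stemming library ships with the runtime.

.pkg_cache <- new.env(parent = emptyenv())

#' The bundled English stop-word list
#'
#' The standard Snowball-style English stop-word list, shipped as a plain
#' text file (one word per line) and user-overridable wherever stop words
#' are consumed.
#'
#' @param path optional path to an alternative list (plain text, one word
#'   per line).
#' @return character vector of stop words.
#' @examples
#' head(defaultStopwords())
#' @export
defaultStopwords <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(.pkg_cache$stopwords)) {
      f <- system.file("extdata", "stopwords_en.txt", package = "gevit",
                       mustWork = TRUE)
      .pkg_cache$stopwords <- readLines(f, warn = FALSE)
    }
    return(.pkg_cache$stopwords)
  }
  readLines(path, warn = FALSE)
}

.consvec <- function(b) {
  n <- length(b)
  v <- logical(n)
  for (i in seq_len(n)) {
    ch <- b[i]
    v[i] <- if (ch %in% c("a", "e", "i", "o", "u")) FALSE
            else if (ch == "y") { if (i == 1L) TRUE else !v[i - 1L] }
            else TRUE
  }
  v
}

## measure m of the stem b[1:j]: number of vowel->consonant transitions
.pmeasure <- function(consv, j) {
  if (j <= 0L) return(0L)
  r <- rle(consv[seq_len(j)])$values
  if (length(r) && r[1L]) r <- r[-1L]
  sum(r)
}

.vowelinstem <- function(consv, j) j > 0L && any(!consv[seq_len(j)])

.doublec <- function(b, consv, j) {
  j >= 2L && b[j] == b[j - 1L] && consv[j]
}

## consonant-vowel-consonant ending where the final consonant is not w,x,y
.cvc <- function(b, consv, j) {
  j >= 3L && consv[j] && !consv[j - 1L] && consv[j - 2L] &&
    !(b[j] %in% c("w", "x", "y"))
}

.ends <- function(b, suf) {
  k <- length(suf); n <- length(b)
  if (n <= k) return(-1L)     # suffix must leave a non-empty stem
  if (identical(b[(n - k + 1L):n], suf)) n - k else -1L
}

.step2_rules <- list(
  list(c("a","t","i","o","n","a","l"), c("a","t","e")),
  list(c("t","i","o","n","a","l"), c("t","i","o","n")),
  list(c("e","n","c","i"), c("e","n","c","e")),
  list(c("a","n","c","i"), c("a","n","c","e")),
  list(c("i","z","e","r"), c("i","z","e")),
  list(c("b","l","i"), c("b","l","e")),
  list(c("a","l","l","i"), c("a","l")),
  list(c("e","n","t","l","i"), c("e","n","t")),
  list(c("e","l","i"), c("e")),
  list(c("o","u","s","l","i"), c("o","u","s")),
  list(c("i","z","a","t","i","o","n"), c("i","z","e")),
  list(c("a","t","i","o","n"), c("a","t","e")),
  list(c("a","t","o","r"), c("a","t","e")),
  list(c("a","l","i","s","m"), c("a","l")),
  list(c("i","v","e","n","e","s","s"), c("i","v","e")),
  list(c("f","u","l","n","e","s","s"), c("f","u","l")),
  list(c("o","u","s","n","e","s","s"), c("o","u","s")),
  list(c("a","l","i","t","i"), c("a","l")),
  list(c("i","v","i","t","i"), c("i","v","e")),
  list(c("b","i","l","i","t","i"), c("b","l","e")),
  list(c("l","o","g","i"), c("l","o","g")))

.step3_rules <- list(
  list(c("i","c","a","t","e"), c("i","c")),
  list(c("a","t","i","v","e"), character()),
  list(c("a","l","i","z","e"), c("a","l")),
  list(c("i","c","i","t","i"), c("i","c")),
  list(c("i","c","a","l"), c("i","c")),
  list(c("f","u","l"), character()),
  list(c("n","e","s","s"), character()))

.step4_sufs <- list(
  c("e","m","e","n","t"), c("a","n","c","e"), c("e","n","c","e"),
  c("a","b","l","e"), c("i","b","l","e"), c("m","e","n","t"),
  c("e","n","t"), c("a","n","t"), c("i","o","n"), c("i","s","m"),
  c("a","t","e"), c("i","t","i"), c("o","u","s"), c("i","v","e"),
  c("i","z","e"), c("a","l"), c("e","r"), c("i","c"), c("o","u"))

.porter1 <- function(w) {
  if (nchar(w) < 3L) return(w)
  b <- strsplit(w, "", fixed = TRUE)[[1L]]
  cv <- .consvec(b)

  ## Step 1a: plurals
  n <- length(b)
  if (b[n] == "s") {
    if (.ends(b, c("s","s","e","s")) > 0L) b <- b[seq_len(n - 2L)]
    else if (.ends(b, c("i","e","s")) > 0L) b <- b[seq_len(n - 2L)]
    else if (n >= 2L && b[n - 1L] != "s") b <- b[seq_len(n - 1L)]
  }

  ## Step 1b: -eed / -ed / -ing
  n <- length(b)
  did_1b2 <- FALSE
  j <- .ends(b, c("e","e","d"))
  if (j > 0L) {
    if (.pmeasure(cv, j) > 0L) b <- b[seq_len(n - 1L)]
  } else {
    j <- .ends(b, c("e","d"))
    if (j > 0L && .vowelinstem(cv, j)) { b <- b[seq_len(j)]; did_1b2 <- TRUE }
    else {
      j <- .ends(b, c("i","n","g"))
      if (j > 0L && .vowelinstem(cv, j)) { b <- b[seq_len(j)]; did_1b2 <- TRUE }
    }
  }
  if (did_1b2) {
    n <- length(b)
    ends_any <- function(s) {
      k <- length(s)
      n >= k && identical(b[(n - k + 1L):n], s)
    }
    if (ends_any(c("a","t")) || ends_any(c("b","l")) || ends_any(c("i","z"))) {
      b <- c(b, "e")
    } else if (.doublec(b, cv, n) && !(b[n] %in% c("l","s","z"))) {
      b <- b[seq_len(n - 1L)]
    } else if (.pmeasure(cv, n) == 1L && .cvc(b, cv, n)) {
      b <- c(b, "e")
    }
    cv <- .consvec(b)
  }

  ## Step 1c: terminal y -> i when the stem has a vowel
  n <- length(b)
  if (n > 1L && b[n] == "y" && .vowelinstem(cv, n - 1L)) {
    b[n] <- "i"
    cv <- .consvec(b)
  }

  ## Step 2
  for (rule in .step2_rules) {
    j <- .ends(b, rule[[1L]])
    if (j >= 0L) {
      if (j > 0L && .pmeasure(cv, j) > 0L) {
        b <- c(b[seq_len(j)], rule[[2L]])
        cv <- .consvec(b)
      }
      break
    }
  }

  ## Step 3
  for (rule in .step3_rules) {
    j <- .ends(b, rule[[1L]])
    if (j >= 0L) {
      if (j > 0L && .pmeasure(cv, j) > 0L) {
        b <- c(b[seq_len(j)], rule[[2L]])
        cv <- .consvec(b)
      }
      break
    }
  }

  ## Step 4: drop suffix when the remaining stem has measure > 1
  for (suf in .step4_sufs) {
    j <- .ends(b, suf)
    if (j >= 0L) {
      ion <- identical(suf, c("i","o","n"))
      ok <- j > 0L && .pmeasure(cv, j) > 1L &&
        (!ion || b[j] %in% c("s", "t"))
      if (ok) { b <- b[seq_len(j)]; cv <- .consvec(b) }
      break
    }
  }

  ## Step 5a: remove trailing e
  n <- length(b)
  if (n > 1L && b[n] == "e") {
    a <- .pmeasure(cv, n - 1L)
    if (a > 1L || (a == 1L && !.cvc(b, cv, n - 1L))) b <- b[seq_len(n - 1L)]
  }

  ## Step 5b: -ll -> -l for measure > 1
  n <- length(b)
  if (n > 1L && b[n] == "l" && .doublec(b, cv, n) &&
      .pmeasure(cv, n) > 1L) {
    b <- b[seq_len(n - 1L)]
  }
  paste(b, collapse = "")
}

#' Porter-stem a vector of tokens
#'
#' Classic Porter (1980) stemming with the author's later revisions;
#' produces the truncated forms used in automatic cluster topic names
#' (e.g. "virus" -> "viru", "genomes" -> "genom", "sequences" -> "sequenc").
#'
#' @param tokens character vector of lowercase tokens.
#' @return character vector of stems, same length and order.
#' @examples
#' porterStem(c("influenza", "virus", "genomes"))
#' @export
porterStem <- function(tokens) {
  if (!length(tokens)) return(character())
  u <- unique(tokens)
  stems <- vapply(u, .porter1, "", USE.NAMES = FALSE)
  stems[match(tokens, u)]
}

## lowercase, strip punctuation, drop standalone numbers
.tokenize_raw <- function(text) {
  if (is.na(text) || !nzchar(text)) return(character())
  t <- chartr("’", "'", tolower(text))
  t <- gsub("'", "", t, fixed = TRUE)
  toks <- strsplit(gsub("[^a-z0-9]+", " ", t), " ", fixed = TRUE)[[1L]]
  toks <- toks[nzchar(toks)]
  toks[!grepl("^[0-9]+$", toks)]
}

#' Preprocess free text into stemmed tokens
#'
#' The unigram pipeline: lowercase; strip punctuation and standalone
#' numbers; remove stop words; drop tokens shorter than three characters;
#' Porter-stem the remainder. Order is preserved. Deterministic; an empty
#' input yields an empty token list.
#'
#' @param text a character scalar (may be empty or `NA`).
#' @param stopwords stop-word list; defaults to [defaultStopwords()].
#' @param min_chars minimum raw-token length retained (default 3).
#' @return character vector of stemmed tokens.
#' @examples
#' preprocessText("Influenza virus genomes")  # "influenza" "viru" "genom"
#' @export
preprocessText <- function(text, stopwords = defaultStopwords(),
                           min_chars = 3L) {
  toks <- .tokenize_raw(text)
  toks <- toks[nchar(toks) >= min_chars]
  toks <- toks[!(toks %in% stopwords)]
  porterStem(toks)
}

## bigram-side tokens: lowercased, stop words removed, unstemmed, short
## tokens kept (pathogen abbreviations like "e coli" stay intact)
.tokenize_bigram <- function(text, stopwords = defaultStopwords()) {
  toks <- .tokenize_raw(text)
  toks[!(toks %in% stopwords)]
}

#' Adjacent-token bigrams of a text
#'
#' Bigrams are formed over lowercased, stop-word-filtered, unstemmed tokens
#' (stemming would corrupt the human-readable phrases used for manual
#' concept mapping).
#'
#' @param text character scalar.
#' @param stopwords stop-word list; defaults to [defaultStopwords()].
#' @return character vector of "token token" bigrams (may be empty).
#' @examples
#' textBigrams("vancomycin resistance in enterococci")
#' @export
textBigrams <- function(text, stopwords = defaultStopwords()) {
  toks <- .tokenize_bigram(text, stopwords)
  n <- length(toks)
  if (n < 2L) return(character())
  paste(toks[-n], toks[-1L])
}
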