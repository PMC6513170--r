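#' @import methods
#' @importFrom Matrix sparseMatrix colSums rowSums t
#' @importFrom stats dist prcomp rbinom rgeom runif
#' @importFrom utils head read.delim write.table packageVersion
NULL

## Label constants for the two non-cluster document categories.
.UNCLUSTERED <- "currently-unclustered"
.NEVER <- "never-clustered"

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state, so seeded operations inside the
#' package never perturb the caller's random number stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Doubles serialized at 17 significant digits round-trip exactly through
## character representation; jsonlite's own digits = NA does not.
.num2chr <- function(x) {
  out <- vapply(as.numeric(x), function(v) {
    if (is.na(v)) NA_character_ else format(v, digits = 17, scientific = TRUE)
  }, character(1))
  out
}

.chr2num <- function(x) as.numeric(x)

.read_ndjson <- function(path, simplify = TRUE) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = simplify),
      error = function(e) stop(sprintf("format error at line %d of '%s': %s",
                                       i, path, conditionMessage(e)), call. = FALSE))
    rec
  })
}

.write_ndjson <- function(records, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (rec in records) {
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null",
                                digits = NA),
               con, useBytes = TRUE)
  }
  invisible(path)
}

.file_md5 <- function(path) unname(tools::md5sum(path))

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## portable ceiling that is robust to floating fuzz (e.g. 0.1 * 30)
.ceil_frac <- function(frac, n) as.integer(ceiling(frac * n - 1e-9))
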