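#' @include gbmsim-package.R
NULL

## Minimal TOML subset used by run configurations: [section] and
## [section.sub] headers, key = value pairs with string, boolean, number and
## flat-array values, and # comments. No installed package provides TOML, and
## run configs only need this subset.

tomlStripComment <- function(line) {
  out <- character(1L)
  in_str <- FALSE
  chars <- strsplit(line, "", fixed = TRUE)[[1L]]
  for (k in seq_along(chars)) {
    ch <- chars[k]
    if (ch == '"') in_str <- !in_str
    if (ch == "#" && !in_str) return(substr(line, 1L, k - 1L))
  }
  line
}

tomlParseValue <- function(txt) {
  txt <- trimws(txt)
  if (txt == "") stop("empty TOML value")
  if (startsWith(txt, "[")) {
    if (!endsWith(txt, "]")) stop(sprintf("unterminated array: %s", txt))
    inner <- trimws(substr(txt, 2L, nchar(txt) - 1L))
    if (inner == "") return(list())
    parts <- strsplit(inner, ",")[[1L]]
    vals <- lapply(parts, tomlParseValue)
    return(unlist(vals))
  }
  if (startsWith(txt, '"')) {
    if (nchar(txt) < 2L || !endsWith(txt, '"')) stop(sprintf("unterminated string: %s", txt))
    return(substr(txt, 2L, nchar(txt) - 1L))
  }
  if (txt %in% c("true", "false")) return(txt == "true")
  num <- suppressWarnings(as.numeric(txt))
  if (is.na(num)) stop(sprintf("cannot parse TOML value: %s", txt))
  num
}

#' Parse a TOML configuration file (subset)
#'
#' Supports the subset run configurations use: \code{[section]} and
#' \code{[section.sub]} headers, \code{key = value} pairs with strings,
#' booleans, numbers and flat arrays, and \code{#} comments.
#'
#' @param path file path, or \code{text =} a character vector of lines.
#' @param text optional character vector of TOML lines (overrides
#'   \code{path}).
#' @return a nested named list.
#' @export
parseTOML <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(path)
  out <- list()
  section <- character(0)
  for (raw in lines) {
    line <- trimws(tomlStripComment(raw))
    if (line == "") next
    if (startsWith(line, "[")) {
      if (!endsWith(line, "]")) stop(sprintf("malformed section header: %s", raw))
      section <- strsplit(substr(line, 2L, nchar(line) - 1L), ".", fixed = TRUE)[[1L]]
      section <- trimws(section)
      next
    }
    eq <- regexpr("=", line, fixed = TRUE)
    if (eq < 0) stop(sprintf("malformed TOML line: %s", raw))
    key <- trimws(substr(line, 1L, eq - 1L))
    val <- tomlParseValue(substr(line, eq + 1L, nchar(line)))
    out <- tomlAssign(out, c(section, key), val)
  }
  out
}

tomlAssign <- function(lst, path, val) {
  if (length(path) == 1L) {
    lst[[path]] <- val
    return(lst)
  }
  sub <- lst[[path[1L]]]
  if (is.null(sub)) sub <- list()
  lst[[path[1L]]] <- tomlAssign(sub, path[-1L], val)
  lst
}

tomlFormatValue <- function(v) {
  if (is.character(v) && length(v) == 1L) return(sprintf('"%s"', v))
  if (is.logical(v) && length(v) == 1L) return(if (v) "true" else "false")
  fmt1 <- function(x) {
    if (is.character(x)) sprintf('"%s"', x) else format(x, digits = 17, scientific = FALSE)
  }
  if (length(v) == 1L) return(fmt1(v))
  sprintf("[%s]", paste(vapply(v, fmt1, character(1L)), collapse = ", "))
}

#' Serialize a nested list as TOML (subset)
#'
#' Inverse of [parseTOML()] for the supported subset; round-trips losslessly
#' up to numeric formatting (17 significant digits).
#'
#' @param x nested named list (two levels: sections of key-value pairs; any
#'   top-level scalar keys are written first).
#' @param path output file path, or \code{NULL} to return the lines.
#' @return (invisibly) the character vector of lines.
#' @export
writeTOML <- function(x, path = NULL) {
  lines <- character(0)
  scalars <- names(x)[!vapply(x, is.list, logical(1L))]
  for (k in scalars) lines <- c(lines, sprintf("%s = %s", k, tomlFormatValue(x[[k]])))
  sections <- names(x)[vapply(x, is.list, logical(1L))]
  for (s in sections) {
    lines <- c(lines, sprintf("[%s]", s))
    for (k in names(x[[s]])) {
      v <- x[[s]][[k]]
      if (is.list(v)) stop("writeTOML supports at most one nesting level of sections")
      lines <- c(lines, sprintf("%s = %s", k, tomlFormatValue(v)))
    }
    lines <- c(lines, "")
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
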