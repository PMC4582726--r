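# Term helpers. Resources are CURIE strings; literals are stored wrapped
# in double quotes so the two spaces cannot collide.

#' Construct a literal term
#'
#' @param x value (character or numeric); numeric vectors of length 3 are
#'   encoded as a single space-separated 3-vector literal.
#' @return character scalar, the internal literal encoding.
#' @examples
#' lit(10)
#' lit(c(0, 0, 1))
#' @export
lit <- function(x) {
  if (is.numeric(x) && length(x) == 3L) x <- paste(fmtNum(x), collapse = " ")
  else if (is.numeric(x)) x <- fmtNum(x)
  stopifnot(length(x) == 1L)
  paste0("\"", x, "\"")
}

#' Test whether a term is a literal
#' @param x character vector of terms.
#' @export
isLit <- function(x) startsWith(x, "\"")

#' Extract the value of a literal term
#' @param x literal term(s) as stored in a graph.
#' @return character, the unquoted lexical form.
#' @export
litValue <- function(x) sub("^\"(.*)\"$", "\\1", x)

#' Numeric value of a literal term
#' @param x literal term.
#' @export
litNum <- function(x) as.numeric(litValue(x))

#' 3-vector value of a space-separated literal term
#' @param x literal term encoding three decimal numbers.
#' @export
litVec <- function(x) {
  v <- as.numeric(strsplit(litValue(x), "[[:space:]]+")[[1]])
  stopifnot(length(v) == 3L)
  v
}

# decimal formatting without scientific notation, stable across platforms
fmtNum <- function(x) {
  out <- vapply(x, function(xi) format(xi, scientific = FALSE, trim = TRUE,
                                       digits = 15), character(1))
  out
}

isVar <- function(x) startsWith(x, "?")
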