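# RDF I/O: Turtle, N-Triples and RDF/XML readers and writers.
#
# The graph model is deliberately blank-node free and the writers emit a
# plain, line-oriented style; the Turtle reader additionally accepts
# prefixed names, full IRIs, `a`, semicolon/comma continuation lists,
# numeric literals and comments, which covers hand-authored input files.

SERIALIZATIONS <- c("turtle", "ntriples", "rdfxml")

normalizeFormat <- function(format) {
  f <- tolower(gsub("[-_ ]", "", format))
  f <- switch(f, ttl = "turtle", turtle = "turtle",
              nt = "ntriples", ntriples = "ntriples",
              rdf = "rdfxml", rdfxml = "rdfxml", xml = "rdfxml",
              f)
  if (!f %in% SERIALIZATIONS)
    stop("unknown serialization name: ", format,
         " (expected one of turtle, ntriples, rdfxml)")
  f
}

formatFromPath <- function(path) {
  switch(tolower(tools::file_ext(path)),
         ttl = "turtle", nt = "ntriples", rdf = "rdfxml", xml = "rdfxml",
         stop("cannot guess serialization from extension of ", path,
              "; pass format explicitly"))
}

# -- term <-> IRI -----------------------------------------------------------

expandTerm <- function(term, ns) {
  if (isLit(term)) return(term)
  if (startsWith(term, "<")) return(sub("^<(.*)>$", "\\1", term))
  i <- regexpr(":", term, fixed = TRUE)
  if (i < 0) stop("not a CURIE: ", term)
  prefix <- substr(term, 1L, i - 1L)
  if (!prefix %in% names(ns)) stop("undeclared prefix: ", prefix)
  paste0(ns[[prefix]], substring(term, i + 1L))
}

contractTerm <- function(iri, ns) {
  if (isLit(iri)) return(iri)
  hit <- which(startsWith(iri, unname(ns)))
  if (!length(hit)) return(paste0("<", iri, ">"))
  best <- hit[which.max(nchar(ns[hit]))]
  paste0(names(ns)[best], ":", substring(iri, nchar(ns[[best]]) + 1L))
}

escapeLit <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  gsub("\n", "\\n", x, fixed = TRUE)
}

unescapeLit <- function(x) {
  x <- gsub("\\n", "\n", x, fixed = TRUE)
  x <- gsub("\\\"", "\"", x, fixed = TRUE)
  gsub("\\\\", "\\", x, fixed = TRUE)
}

# -- writers ----------------------------------------------------------------

writeTurtle <- function(graph) {
  ns <- namespaces(graph)
  head <- sprintf("@prefix %s: <%s> .", names(ns), unname(ns))
  tr <- triples(graph)
  term <- function(x) {
    ifelse(isLit(x), paste0("\"", escapeLit(litValue(x)), "\""), x)
  }
  body <- if (nrow(tr))
    sprintf("%s %s %s .", tr$s, ifelse(tr$p == "rdf:type", "a", tr$p),
            term(tr$o))
  else character()
  paste(c(head, "", body, ""), collapse = "\n")
}

writeNTriples <- function(graph) {
  ns <- namespaces(graph)
  tr <- triples(graph)
  term <- function(x) {
    ifelse(isLit(x), paste0("\"", vapply(litValue(x), escapeLit, character(1)), "\""),
           paste0("<", vapply(x, expandTerm, character(1), ns = ns), ">"))
  }
  res <- function(x) paste0("<", vapply(x, expandTerm, character(1), ns = ns), ">")
  body <- if (nrow(tr)) sprintf("%s %s %s .", res(tr$s), res(tr$p), term(tr$o))
  else character()
  paste(c(body, ""), collapse = "\n")
}

writeRdfXml <- function(graph) {
  ns <- namespaces(graph)
  doc <- xml2::xml_new_root("rdf:RDF")
  for (p in names(ns))
    xml2::xml_set_attr(doc, paste0("xmlns:", p), ns[[p]])
  tr <- triples(graph)
  for (s in unique(tr$s)) {
    d <- xml2::xml_add_child(doc, "rdf:Description")
    xml2::xml_set_attr(d, "rdf:about", expandTerm(s, ns))
    rows <- tr[tr$s == s, , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      node <- xml2::xml_add_child(d, rows$p[i])
      if (isLit(rows$o[i])) xml2::xml_set_text(node, litValue(rows$o[i]))
      else xml2::xml_set_attr(node, "rdf:resource", expandTerm(rows$o[i], ns))
    }
  }
  as.character(doc)
}

#' Serialize an ontology graph
#'
#' @param graph an [OntologyGraph-class].
#' @param format one of `"turtle"`, `"ntriples"`, `"rdfxml"` (aliases
#'   `ttl`, `nt`, `rdf`, `xml` accepted). Guessed from `path` if missing.
#' @param path optional file to write; the serialized text is returned
#'   invisibly when writing, visibly otherwise.
#' @return character scalar of serialized text.
#' @examples
#' g <- addTriples(emptyGraph(), c("mcfe:left_kidney", "mcfe:part_of", "mcfe:embryo"))
#' cat(saveGraph(g, "turtle"))
#' @export
saveGraph <- function(graph, format = NULL, path = NULL) {
  stopifnot(is(graph, "OntologyGraph"))
  if (is.null(format)) {
    if (is.null(path)) stop("either format or path must be given")
    format <- formatFromPath(path)
  }
  format <- normalizeFormat(format)
  text <- switch(format,
                 turtle = writeTurtle(graph),
                 ntriples = writeNTriples(graph),
                 rdfxml = writeRdfXml(graph))
  if (!is.null(path)) {
    writeLines(text, path, sep = "")
    return(invisible(text))
  }
  text
}

# -- Turtle tokenizer / parser ----------------------------------------------

tokenizeTurtle <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  toks <- character(); kinds <- character()
  i <- 1L; line <- 1L
  push <- function(tok, kind) { toks[length(toks) + 1L] <<- tok
                                kinds[length(kinds) + 1L] <<- kind }
  while (i <= n) {
    c0 <- chars[i]
    if (c0 == "\n") { line <- line + 1L; i <- i + 1L; next }
    if (grepl("^[[:space:]]$", c0)) { i <- i + 1L; next }
    if (c0 == "#") { while (i <= n && chars[i] != "\n") i <- i + 1L; next }
    if (c0 == "\"") {
      j <- i + 1L; buf <- character()
      while (j <= n && chars[j] != "\"") {
        if (chars[j] == "\\") { buf <- c(buf, chars[j], chars[j + 1L]); j <- j + 2L }
        else { buf <- c(buf, chars[j]); j <- j + 1L }
      }
      if (j > n) stop("unterminated string literal at line ", line)
      push(paste(buf, collapse = ""), "lit")
      i <- j + 1L
      # skip optional datatype/lang tag
      if (i + 1L <= n && chars[i] == "^" && chars[i + 1L] == "^") {
        i <- i + 2L
        while (i <= n && !grepl("^[[:space:];,.]$", chars[i])) i <- i + 1L
      }
      next
    }
    if (c0 == "<") {
      j <- i + 1L
      while (j <= n && chars[j] != ">") j <- j + 1L
      if (j > n) stop("unterminated IRI at line ", line)
      push(paste(chars[i:j], collapse = ""), "iri")
      i <- j + 1L; next
    }
    if (c0 %in% c(".", ";", ",")) { push(c0, "punct"); i <- i + 1L; next }
    # bare token: prefixed name, keyword, or number
    j <- i
    while (j <= n && !grepl("^[[:space:];,<\"#]$", chars[j]) &&
           !(chars[j] == "." && (j == n || grepl("^[[:space:]]$", chars[j + 1L]))))
      j <- j + 1L
    push(paste(chars[i:(j - 1L)], collapse = ""), "name")
    i <- j
  }
  list(tokens = toks, kinds = kinds)
}

parseTurtle <- function(text) {
  tk <- tokenizeTurtle(text)
  toks <- tk$tokens; kinds <- tk$kinds
  ns <- defaultNamespaces()
  out <- list(); i <- 1L; n <- length(toks)
  term <- function(j) {
    kind <- kinds[j]; tok <- toks[j]
    if (kind == "lit") return(lit(unescapeLit(tok)))
    if (kind == "iri") return(contractTerm(sub("^<(.*)>$", "\\1", tok), ns))
    if (tok == "a") return("rdf:type")
    if (grepl("^[+-]?[0-9.]+$", tok)) return(lit(tok))
    if (tok == "true" || tok == "false") return(lit(tok))
    if (!grepl(":", tok, fixed = TRUE))
      stop("cannot parse term '", tok, "' (token ", j, ")")
    tok
  }
  while (i <= n) {
    tok <- toks[i]
    if (kinds[i] == "name" && tolower(tok) %in% c("@prefix", "prefix")) {
      prefix <- sub(":$", "", toks[i + 1L])
      iri <- sub("^<(.*)>$", "\\1", toks[i + 2L])
      ns[[prefix]] <- iri
      i <- i + 3L
      if (i <= n && toks[i] == "." && kinds[i] == "punct") i <- i + 1L
      next
    }
    s <- term(i); i <- i + 1L
    repeat {
      p <- term(i); i <- i + 1L
      repeat {
        o <- term(i); i <- i + 1L
        out[[length(out) + 1L]] <- c(s, p, o)
        if (i <= n && toks[i] == "," && kinds[i] == "punct") { i <- i + 1L; next }
        break
      }
      if (i <= n && toks[i] == ";" && kinds[i] == "punct") { i <- i + 1L
        if (i <= n && toks[i] == "." && kinds[i] == "punct") { i <- i + 1L; break }
        next }
      if (i <= n && toks[i] == "." && kinds[i] == "punct") { i <- i + 1L; break }
      if (i > n) break
      stop("expected '.', ';' or ',' near token ", i, " ('", toks[i], "')")
    }
  }
  list(triples = out, namespaces = ns)
}

parseNTriples <- function(text) {
  ns <- defaultNamespaces()
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  out <- list()
  for (k in seq_along(lines)) {
    ln <- trimws(lines[k])
    if (!nchar(ln) || startsWith(ln, "#")) next
    m <- regmatches(ln, regexec(
      "^<([^>]*)>\\s+<([^>]*)>\\s+(<[^>]*>|\"(\\\\.|[^\"\\\\])*\")\\s*\\.\\s*$", ln))[[1]]
    if (!length(m)) stop("N-Triples parse error at line ", k, ": ", ln)
    s <- contractTerm(m[2], ns); p <- contractTerm(m[3], ns)
    ot <- m[4]
    o <- if (startsWith(ot, "<"))
      contractTerm(sub("^<(.*)>$", "\\1", ot), ns)
    else lit(unescapeLit(sub("^\"(.*)\"$", "\\1", ot)))
    out[[length(out) + 1L]] <- c(s, p, o)
  }
  list(triples = out, namespaces = ns)
}

parseRdfXml <- function(text) {
  doc <- xml2::read_xml(text)
  nsdef <- xml2::xml_ns(doc)
  ns <- defaultNamespaces()
  for (p in names(nsdef)) if (!p %in% c("d1")) ns[[p]] <- nsdef[[p]]
  rdfIri <- defaultNamespaces()[["rdf"]]
  out <- list()
  for (d in xml2::xml_find_all(doc, ".//*[local-name()='Description']")) {
    s <- contractTerm(xml2::xml_attr(d, "about"), ns)
    for (child in xml2::xml_children(d)) {
      fullp <- paste0(xml2::xml_ns(doc)[[strsplit(xml2::xml_name(child, nsdef),
                                                  ":")[[1]][1]]],
                      strsplit(xml2::xml_name(child, nsdef), ":")[[1]][2])
      p <- contractTerm(fullp, ns)
      resAttr <- xml2::xml_attr(child, "resource")
      o <- if (!is.na(resAttr)) contractTerm(resAttr, ns)
      else lit(xml2::xml_text(child))
      out[[length(out) + 1L]] <- c(s, p, o)
    }
  }
  list(triples = out, namespaces = ns)
}

#' Load an ontology graph from a serialized document
#'
#' @param source a file path or a character scalar of serialized text.
#' @param format serialization name (`turtle`, `ntriples`, `rdfxml`);
#'   guessed from a path's extension when omitted.
#' @return an [OntologyGraph-class]; all triples are marked asserted.
#' @examples
#' g <- loadGraph("@prefix mcfe: <http://example.org/mycf-embryo#> .
#'   mcfe:left_kidney mcfe:part_of mcfe:embryo .", format = "turtle")
#' tripleCount(g)
#' @export
loadGraph <- function(source, format = NULL) {
  isPath <- length(source) == 1L && !grepl("[\n{<@]", source) &&
    file.exists(source)
  text <- if (isPath) paste(readLines(source, warn = FALSE), collapse = "\n")
  else paste(source, collapse = "\n")
  if (is.null(format)) {
    if (isPath) format <- formatFromPath(source)
    else if (grepl("^\\s*<\\?xml|^\\s*<rdf:RDF", text)) format <- "rdfxml"
    else format <- "turtle"
  }
  format <- normalizeFormat(format)
  parsed <- switch(format,
                   turtle = parseTurtle(text),
                   ntriples = parseNTriples(text),
                   rdfxml = parseRdfXml(text))
  g <- emptyGraph(unlist(parsed$namespaces))
  if (length(parsed$triples))
    g <- addTriples(g, do.call(rbind, parsed$triples))
  g
}
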