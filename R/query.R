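# SPARQL-subset querying plus the canned queries the scene builder uses.
#
# Dialect: SELECT [DISTINCT] over basic graph patterns with FILTER on
# literals. Variables may stand in any position, including the
# predicate, so the schema can be queried alongside the data. Property
# paths are not supported: closure comes from saturation, not paths.

parseSparql <- function(queryText, graphNs = defaultNamespaces()) {
  text <- paste(queryText, collapse = "\n")
  ns <- graphNs
  pm <- gregexpr("(?i)PREFIX\\s+([A-Za-z][A-Za-z0-9_]*)\\s*:\\s*<([^>]*)>",
                 text, perl = TRUE)[[1]]
  if (pm[1] != -1) {
    for (hit in regmatches(text, gregexpr(
      "(?i)PREFIX\\s+([A-Za-z][A-Za-z0-9_]*)\\s*:\\s*<([^>]*)>", text,
      perl = TRUE))[[1]]) {
      parts <- regmatches(hit, regexec(
        "(?i)PREFIX\\s+([A-Za-z][A-Za-z0-9_]*)\\s*:\\s*<([^>]*)>", hit))[[1]]
      ns[[parts[2]]] <- parts[3]
    }
  }
  m <- regmatches(text, regexec(
    "(?is)SELECT\\s+(DISTINCT\\s+)?(.*?)\\s*WHERE\\s*\\{(.*)\\}", text,
    perl = TRUE))[[1]]
  if (!length(m)) stop("query parse error: expected SELECT ... WHERE { ... }")
  selVars <- trimws(m[3])
  body <- m[4]

  filters <- character()
  fm <- gregexpr("(?i)FILTER\\s*\\(([^)]*)\\)", body, perl = TRUE)[[1]]
  if (fm[1] != -1) {
    for (hit in regmatches(body, gregexpr("(?i)FILTER\\s*\\(([^)]*)\\)", body,
                                          perl = TRUE))[[1]])
      filters <- c(filters,
                   regmatches(hit, regexec("(?i)FILTER\\s*\\((.*)\\)", hit))[[1]][2])
    body <- gsub("(?i)FILTER\\s*\\(([^)]*)\\)\\s*\\.?", "", body, perl = TRUE)
  }

  tk <- tokenizeTurtle(body)
  toks <- tk$tokens; kinds <- tk$kinds
  term <- function(j) {
    kind <- kinds[j]; tok <- toks[j]
    if (kind == "lit") return(lit(unescapeLit(tok)))
    if (kind == "iri")
      return(contractTerm(sub("^<(.*)>$", "\\1", tok), graphNs))
    if (isVar(tok)) return(tok)
    if (tok == "a") return("rdf:type")
    if (grepl("^[+-]?[0-9.]+$", tok)) return(lit(tok))
    if (!grepl(":", tok, fixed = TRUE))
      stop("query parse error near token ", j, ": '", tok, "'")
    # canonicalize prefixed names against the graph's namespace table so
    # query-local prefixes aliasing a known IRI match stored CURIEs
    contractTerm(expandTerm(tok, ns), graphNs)
  }
  patterns <- list(); i <- 1L; n <- length(toks)
  while (i <= n) {
    if (kinds[i] == "punct") { i <- i + 1L; next }
    s <- term(i); i <- i + 1L
    repeat {
      p <- term(i); i <- i + 1L
      repeat {
        o <- term(i); i <- i + 1L
        patterns[[length(patterns) + 1L]] <- c(s, p, o)
        if (i <= n && toks[i] == "," && kinds[i] == "punct") { i <- i + 1L; next }
        break
      }
      if (i <= n && toks[i] == ";" && kinds[i] == "punct") { i <- i + 1L; next }
      if (i <= n && toks[i] == "." && kinds[i] == "punct") { i <- i + 1L; break }
      break
    }
  }
  vars <- if (selVars == "*") {
    vv <- unlist(patterns); unique(substring(vv[isVar(vv)], 2L))
  } else {
    vv <- strsplit(selVars, "[[:space:]]+")[[1]]
    if (!all(isVar(vv))) stop("query parse error: SELECT expects variables or *")
    substring(vv, 2L)
  }
  list(vars = vars, patterns = patterns, filters = filters, ns = ns)
}

applyFilter <- function(bindings, filterText) {
  m <- regmatches(filterText, regexec(
    "^\\s*\\?([A-Za-z0-9_]+)\\s*(<=|>=|!=|=|<|>)\\s*(.*?)\\s*$", filterText))[[1]]
  if (!length(m)) stop("unsupported FILTER expression: ", filterText)
  var <- m[2]; op <- m[3]; rhs <- m[4]
  if (!var %in% names(bindings))
    stop("FILTER references unbound variable ?", var)
  vals <- bindings[[var]]
  lhs <- ifelse(isLit(vals), litValue(vals), vals)
  rhsStr <- if (grepl("^\".*\"$", rhs)) sub("^\"(.*)\"$", "\\1", rhs) else rhs
  lhsNum <- suppressWarnings(as.numeric(lhs))
  rhsNum <- suppressWarnings(as.numeric(rhsStr))
  keep <- if (!is.na(rhsNum) && !all(is.na(lhsNum))) {
    switch(op, "<" = lhsNum < rhsNum, "<=" = lhsNum <= rhsNum,
           ">" = lhsNum > rhsNum, ">=" = lhsNum >= rhsNum,
           "=" = lhsNum == rhsNum, "!=" = lhsNum != rhsNum)
  } else {
    switch(op, "=" = lhs == rhsStr, "!=" = lhs != rhsStr,
           "<" = lhs < rhsStr, "<=" = lhs <= rhsStr,
           ">" = lhs > rhsStr, ">=" = lhs >= rhsStr)
  }
  keep[is.na(keep)] <- FALSE
  bindings[keep, , drop = FALSE]
}

#' Run a SPARQL SELECT query over a graph
#'
#' Basic-graph-pattern semantics over data and schema triples alike;
#' variables may stand for classes and properties.
#'
#' @param graph an [OntologyGraph-class] (saturate first if inferred
#'   answers are wanted).
#' @param queryText SPARQL SELECT text (the supported dialect: PREFIX
#'   declarations, SELECT / SELECT DISTINCT / SELECT *, a `{}` block of
#'   triple patterns with `.` `;` `,` punctuation, and simple
#'   `FILTER(?v op constant)` comparisons).
#' @return bindings table: data.frame with one column per selected
#'   variable, one row per solution.
#' @examples
#' g <- addTriples(emptyGraph(), c("mcfe:left_kidney", "mcfe:part_of", "mcfe:embryo"))
#' runQuery(g, "SELECT ?x WHERE { ?x mcfe:part_of mcfe:embryo . }")
#' @export
runQuery <- function(graph, queryText) {
  stopifnot(is(graph, "OntologyGraph"))
  q <- parseSparql(queryText, namespaces(graph))
  bindings <- evalConditions(triples(graph), q$patterns)
  if (is.null(bindings))
    bindings <- data.frame(matrix(character(), 1, 0))  # no patterns: one empty row
  for (f in q$filters) if (nrow(bindings)) bindings <- applyFilter(bindings, f)
  missing <- setdiff(q$vars, names(bindings))
  for (v in missing) bindings[[v]] <- character(nrow(bindings))
  out <- bindings[, q$vars, drop = FALSE]
  out <- out[!duplicated(out), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# -- stage arithmetic helpers ----------------------------------------------

stageDays <- function(graph, stage) {
  fromD <- objectsOf(graph, stage, "mcfe:from_gestation_day")
  toD <- objectsOf(graph, stage, "mcfe:to_gestation_day")
  if (!length(fromD) || !length(toD))
    stop("unknown stage (no gestation-day bounds in graph): ", stage)
  c(from = litNum(fromD[1]), to = litNum(toD[1]))
}

stageLeq <- function(graph, a, b) {
  # a precedes-or-equals b in gestation time
  stageDays(graph, a)[["from"]] <= stageDays(graph, b)[["from"]]
}

#' Geometric representations of the descendants of an entity
#'
#' Finds every entity that `develops_from` the given ancestor (in the
#' saturated graph) and returns its geometric representations at the
#' start stage or any later stage.
#'
#' @param graph an [OntologyGraph-class].
#' @param ancestor entity id, e.g. `"mcfe:cloaca"`.
#' @param startStage stage id, e.g. `"mcfe:te14"`.
#' @param saturated set TRUE if `graph` is already saturated to skip
#'   re-saturation (saturation is idempotent either way).
#' @return data.frame with columns `ee` (entity), `g` (geometric
#'   instance), `stage`.
#' @export
representationsDevelopingFrom <- function(graph, ancestor, startStage,
                                          saturated = FALSE) {
  if (!saturated) graph <- saturate(graph)
  if (!ancestor %in% c(triples(graph)$s, triples(graph)$o)) {
    warning("unknown ancestor: ", ancestor)
    return(data.frame(ee = character(), g = character(), stage = character()))
  }
  b <- evalConditions(triples(graph), list(
    c("?ee", "mcfe:develops_from", ancestor),
    c("?i", "rdf:type", "?ee"),
    c("?s", "mcfe:describes", "?i"),
    c("?s", "mcfe:has_geometrical_representation", "?g"),
    c("?s", "mcfe:at_stage", "?t")))
  if (is.null(b) || !nrow(b))
    return(data.frame(ee = character(), g = character(), stage = character()))
  keep <- vapply(b$t, function(t)
    t == startStage || hasTriple(graph, t, "mcfe:following_stage", startStage),
    logical(1))
  out <- data.frame(ee = b$ee[keep], g = b$g[keep], stage = b$t[keep],
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(out), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# -- scene extraction -------------------------------------------------------

parsePropertyValue <- function(o) {
  if (!isLit(o)) return(o)
  parts <- strsplit(litValue(o), "[[:space:]]+")[[1]]
  nums <- suppressWarnings(as.numeric(parts))
  if (!anyNA(nums) && length(nums) %in% c(1L, 3L)) {
    if (length(nums) == 1L) nums else nums
  } else litValue(o)
}

literalPropertyMap <- function(graph, resource) {
  tr <- triples(graph)
  rows <- tr[tr$s == resource & tr$src == "asserted", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(rows))) {
    key <- sub("^mcfe:", "", rows$p[i])
    val <- parsePropertyValue(rows$o[i])
    if (!key %in% names(out)) out[[key]] <- val
  }
  out
}

organInstances <- function(graph, organ) {
  inst <- subjectsOf(graph, "rdf:type", organ)
  inst <- inst[grepl("^mcfe:e[0-9]+_", inst)]
  if (length(inst)) inst else organ
}

geometricKindOf <- function(graph, g) {
  kinds <- schemaVocabulary()$geometricKinds
  types <- objectsOf(graph, g, "rdf:type")
  hit <- kinds[paste0("mcfe:", kinds) %in% types]
  if (length(hit)) hit[1] else NA_character_
}

processKindOf <- function(graph, p) {
  kinds <- schemaVocabulary()$processKinds
  types <- objectsOf(graph, p, "rdf:type")
  hit <- kinds[paste0("mcfe:", kinds) %in% types]
  if (length(hit)) hit[1] else NA_character_
}

#' Extract the scene description for a set of organs over a period
#'
#' For each requested organ (class or instance id) collects every static
#' representation whose stage lies in the period and every process
#' representation whose stage interval intersects the period (equality
#' counts as intersection), with the full geometric / process property
#' maps. Organs with no representation in the period are listed with
#' empty records and a warning.
#'
#' @param graph an [OntologyGraph-class], saturated or not (saturated
#'   internally when needed for the stage order).
#' @param organs character vector of entity ids.
#' @param period character(2) of stage ids, start before end.
#' @return a [SceneDescription-class].
#' @export
extractScene <- function(graph, organs, period) {
  stopifnot(is(graph, "OntologyGraph"), length(period) == 2L)
  p0 <- stageDays(graph, period[1]); p1 <- stageDays(graph, period[2])
  if (p0[["from"]] > p1[["from"]])
    stop("invalid period: ", period[1], " does not precede ", period[2])
  tr <- triples(graph)
  res <- list()
  for (organ in organs) {
    for (inst in organInstances(graph, organ)) {
      statics <- list(); procs <- list()
      strs <- subjectsOf(graph, "mcfe:describes", inst)
      for (s in strs) {
        atStage <- objectsOf(graph, s, "mcfe:at_stage")
        geoms <- objectsOf(graph, s, "mcfe:has_geometrical_representation")
        if (length(atStage) && length(geoms)) {
          d <- stageDays(graph, atStage[1])
          if (d[["from"]] >= p0[["from"]] && d[["from"]] <= p1[["from"]]) {
            for (g in geoms)
              statics[[length(statics) + 1L]] <- list(
                str = s, stage = atStage[1], shape = geometricKindOf(graph, g),
                geometry = g, properties = literalPropertyMap(graph, g))
          }
        }
        proc <- objectsOf(graph, s, "mcfe:has_process")
        fromS <- objectsOf(graph, s, "mcfe:from_stage")
        toS <- objectsOf(graph, s, "mcfe:to_stage")
        if (length(proc) && length(fromS) && length(toS)) {
          df_ <- stageDays(graph, fromS[1]); dt_ <- stageDays(graph, toS[1])
          if (df_[["from"]] > dt_[["from"]])
            stop("process interval reversed on ", s)
          if (df_[["from"]] <= p1[["from"]] && dt_[["from"]] >= p0[["from"]]) {
            for (pr in proc) {
              params <- literalPropertyMap(graph, pr)
              # multi-valued rotation axes
              ax <- tr$o[tr$s == pr & tr$p == "mcfe:rotation_axis"]
              if (length(ax)) params$rotation_axis <- litValue(ax)
              fixedTo <- list(
                rostral = objectsOf(graph, pr, "mcfe:rostral_end_fixed_to"),
                caudal = objectsOf(graph, pr, "mcfe:caudal_end_fixed_to"),
                whole = objectsOf(graph, pr, "mcfe:fixed_to"))
              procs[[length(procs) + 1L]] <- list(
                str = s, process = pr, kind = processKindOf(graph, pr),
                from = fromS[1], to = toS[1], parameters = params,
                fixedTo = fixedTo,
                dependsOn = objectsOf(graph, pr, "mcfe:depends_on"),
                active = TRUE)
            }
          }
        }
      }
      if (!length(statics) && !length(procs))
        warning("organ ", inst, " has no representation in period ",
                period[1], "..", period[2])
      res[[inst]] <- list(instance = inst, organ = organ,
                          statics = statics, processes = procs)
    }
  }
  new("SceneDescription", organs = res, period = as.character(period))
}
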