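# Safe-rule (Datalog) representation and forward-chaining saturation.

#' Is a rule safe?
#'
#' A rule is safe when every variable of its conclusions also occurs in
#' its conditions, which bounds every derivable fact by the constants of
#' the graph and guarantees termination of saturation.
#'
#' @param rule a [Rule-class].
#' @export
ruleIsSafe <- function(rule) {
  vars <- function(pats) {
    v <- unlist(pats, use.names = FALSE)
    v[isVar(v)]
  }
  all(vars(rule@conclusions) %in% vars(rule@conditions))
}

#' Construct an inference rule
#'
#' @param id rule identifier.
#' @param conditions list of triple patterns (character(3); variables
#'   start with `?`).
#' @param conclusions list of triple patterns.
#' @return a validated [Rule-class].
#' @examples
#' rule("R2",
#'   list(c("?x", "mcfe:develops_from", "?y"),
#'        c("?y", "mcfe:develops_from", "?z")),
#'   list(c("?x", "mcfe:develops_from", "?z")))
#' @export
rule <- function(id, conditions, conclusions) {
  new("Rule", id = id, conditions = conditions, conclusions = conclusions)
}

# -- declarative rules file -------------------------------------------------

parsePatternText <- function(text) {
  toks <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  if (length(toks) != 3L)
    stop("triple pattern must have 3 terms: ", text)
  toks
}

#' Parse a declarative rules file
#'
#' One rule per line: `ID: pattern & pattern ... => pattern & ...`,
#' each pattern three whitespace-separated terms; `#` starts a comment.
#'
#' @param path file path, or `text` given directly.
#' @param text character vector of lines (overrides `path`).
#' @return list of [Rule-class] objects.
#' @export
parseRules <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*:\\s*(.*)=>(.*)$", ln))[[1]]
    if (!length(m)) stop("cannot parse rule line: ", ln)
    conds <- lapply(strsplit(m[3], "&", fixed = TRUE)[[1]], parsePatternText)
    concl <- lapply(strsplit(m[4], "&", fixed = TRUE)[[1]], parsePatternText)
    rule(m[2], conds, concl)
  })
}

#' The default ruleset of fifteen safe rules
#'
#' R1 makes every direct lineage link a `develops_from` link; R2 closes
#' `develops_from` transitively; R3/R4 propagate lineage through
#' `part_of` and `subClassOf` of the precursor. R5-R7 form the generic
#' RDFS/mereology core: `subClassOf` transitivity, `part_of`
#' transitivity and `subPropertyOf` entailment. R8/R9 tie geometric
#' models to the organ instances and stages they represent. R10 closes
#' the `following_stage` order, R11 the `depends_on` relation between
#' processes; R12 propagates a disease's impact down process
#' dependencies; R13-R15 relate processes to the entities they impact
#' and the stage interval over which they run.
#'
#' The ruleset is shipped as a declarative rules file
#' (`system.file("extdata", "rules_default.rules", package = "embryofab")`)
#' parsed at load.
#'
#' @return list of 15 [Rule-class] objects, ids R1..R15.
#' @examples
#' length(defaultRuleset())
#' @export
defaultRuleset <- function() {
  path <- system.file("extdata", "rules_default.rules", package = "embryofab")
  if (!nzchar(path)) stop("rules file not found in installed package")
  parseRules(path)
}

# -- pattern matching -------------------------------------------------------

# bindings for a single pattern against a triple frame
matchPattern <- function(tf, pattern) {
  fields <- c("s", "p", "o")
  sel <- rep(TRUE, nrow(tf))
  varOf <- character(0)
  for (k in 1:3) {
    t <- pattern[k]
    if (isVar(t)) varOf[fields[k]] <- substring(t, 2L)
    else sel <- sel & tf[[fields[k]]] == t
  }
  rows <- tf[sel, , drop = FALSE]
  # repeated variable inside one pattern enforces equality
  if (anyDuplicated(varOf)) {
    for (v in unique(varOf[duplicated(varOf)])) {
      fs <- names(varOf)[varOf == v]
      for (k in seq_along(fs)[-1])
        rows <- rows[rows[[fs[1]]] == rows[[fs[k]]], , drop = FALSE]
    }
  }
  out <- data.frame(matrix(character(), nrow = nrow(rows), ncol = 0),
                    stringsAsFactors = FALSE)
  for (f in names(varOf)) out[[varOf[[f]]]] <- rows[[f]]
  out[!duplicated(out), , drop = FALSE]
}

joinBindings <- function(a, b) {
  shared <- intersect(names(a), names(b))
  if (length(shared)) merge(a, b, by = shared, stringsAsFactors = FALSE)
  else merge(a, b, by = NULL)
}

# evaluate a conjunction of patterns; optionally restrict one condition
# to a delta frame (semi-naive evaluation)
evalConditions <- function(tf, patterns, deltaPos = NULL, delta = NULL) {
  acc <- NULL
  for (i in seq_along(patterns)) {
    frame <- if (!is.null(deltaPos) && i == deltaPos) delta else tf
    b <- matchPattern(frame, patterns[[i]])
    acc <- if (is.null(acc)) b else {
      if (nrow(acc) == 0L || nrow(b) == 0L) return(acc[0, , drop = FALSE])
      joinBindings(acc, b)
    }
  }
  acc
}

instantiate <- function(pattern, bindings) {
  cols <- lapply(pattern, function(t) {
    if (isVar(t)) bindings[[substring(t, 2L)]]
    else rep(t, nrow(bindings))
  })
  data.frame(s = cols[[1]], p = cols[[2]], o = cols[[3]],
             stringsAsFactors = FALSE)
}

#' Apply one rule to a graph
#'
#' Computes the instantiated conclusions of every variable binding that
#' satisfies all the rule's conditions. The graph is not modified.
#'
#' @param graph an [OntologyGraph-class].
#' @param rule a safe [Rule-class].
#' @return data.frame of conclusion triples (columns `s`, `p`, `o`),
#'   duplicates collapsed.
#' @export
applyRule <- function(graph, rule) {
  stopifnot(is(graph, "OntologyGraph"), is(rule, "Rule"))
  if (!ruleIsSafe(rule)) stop("unsafe rule: ", rule@id)
  tf <- triples(graph)
  bindings <- evalConditions(tf, rule@conditions)
  if (is.null(bindings) || nrow(bindings) == 0L)
    return(data.frame(s = character(), p = character(), o = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(rule@conclusions, instantiate, bindings = bindings))
  out <- out[!startsWith(out$s, "\""), , drop = FALSE]  # literals cannot be subjects
  out[!duplicated(paste(out$s, out$p, out$o, sep = "\r")), , drop = FALSE]
}

# one semi-naive round for one rule: each condition in turn restricted
# to the delta, the others over the full frame
ruleDeltaConclusions <- function(tf, delta, r) {
  pieces <- lapply(seq_along(r@conditions), function(i) {
    b <- evalConditions(tf, r@conditions, deltaPos = i, delta = delta)
    if (is.null(b) || nrow(b) == 0L) return(NULL)
    do.call(rbind, lapply(r@conclusions, instantiate, bindings = b))
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (!length(pieces))
    return(data.frame(s = character(), p = character(), o = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, pieces)
  out <- out[!startsWith(out$s, "\""), , drop = FALSE]
  out[!duplicated(paste(out$s, out$p, out$o, sep = "\r")), , drop = FALSE]
}

#' Saturate a graph under a ruleset
#'
#' Forward-chains the rules until no new fact can be produced, yielding
#' the least fixpoint: the returned graph is closed under every rule and
#' a superset of the input. Every inferred triple records the id of the
#' rule that first produced it; a derivable triple that was already
#' asserted keeps its asserted provenance. Termination is guaranteed by
#' rule safety over the finite constant domain.
#'
#' @param graph an [OntologyGraph-class].
#' @param rules list of [Rule-class]; defaults to [defaultRuleset()].
#' @param method `"seminaive"` (delta-driven, the default) or `"naive"`
#'   (full re-evaluation each round; kept as an independent oracle).
#' @return the saturated [OntologyGraph-class].
#' @examples
#' g <- addTriples(emptyGraph(), rbind(
#'   c("mcfe:kidney", "mcfe:directly_develops_from", "mcfe:metanephric_blastema"),
#'   c("mcfe:metanephric_blastema", "mcfe:directly_develops_from", "mcfe:metanephros")))
#' gs <- saturate(g)
#' hasTriple(gs, "mcfe:kidney", "mcfe:develops_from", "mcfe:metanephros")
#' @export
saturate <- function(graph, rules = defaultRuleset(),
                     method = c("seminaive", "naive")) {
  stopifnot(is(graph, "OntologyGraph"))
  method <- match.arg(method)
  for (r in rules) if (!ruleIsSafe(r)) stop("unsafe rule: ", r@id)

  if (method == "naive") {
    repeat {
      added <- FALSE
      for (r in rules) {
        concl <- applyRule(graph, r)
        if (!nrow(concl)) next
        new <- !(paste(concl$s, concl$p, concl$o, sep = "\r") %in%
                   tripleKey(triples(graph)))
        if (any(new)) {
          graph <- addTriples(graph, concl[new, , drop = FALSE], src = r@id)
          added <- TRUE
        }
      }
      if (!added) break
    }
    return(graph)
  }

  delta <- triples(graph)[c("s", "p", "o")]
  while (nrow(delta)) {
    tf <- triples(graph)
    newDelta <- NULL
    for (r in rules) {
      concl <- ruleDeltaConclusions(tf, delta, r)
      if (!nrow(concl)) next
      keys <- paste(concl$s, concl$p, concl$o, sep = "\r")
      fresh <- !(keys %in% tripleKey(triples(graph)))
      if (!is.null(newDelta))
        fresh <- fresh & !(keys %in% paste(newDelta$s, newDelta$p, newDelta$o,
                                           sep = "\r"))
      if (any(fresh)) {
        add <- concl[fresh, , drop = FALSE]
        graph <- addTriples(graph, add, src = r@id)
        newDelta <- rbind(newDelta, add)
      }
    }
    delta <- if (is.null(newDelta))
      data.frame(s = character(), p = character(), o = character(),
                 stringsAsFactors = FALSE)
    else newDelta
  }
  graph
}
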