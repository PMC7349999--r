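# Fisher's-exact GO-term enrichment over the upper ontology levels.
# The ontology is read from OBO 1.2 using is_a edges only; a term's level
# is the length of the shortest is_a path to its namespace root (roots at
# level 0, so "the first 4 levels" means levels 1-4).

.NAMESPACE_CODE <- c(molecular_function = "MF", biological_process = "BP",
                     cellular_component = "CC")

#' Load a GO-style ontology from OBO text
#'
#' Parses \code{[Term]} stanzas (id, name, namespace, is_a), drops obsolete
#' terms, builds the directed child-to-parent is_a graph and computes each
#' term's level as the shortest is_a path from its namespace root.
#'
#' @param obo_text OBO 1.2 content (string, lines, or a file path).
#' @return List of class \code{ontology_graph} with \code{terms} (data.frame
#'   \code{id}, \code{name}, \code{namespace}, \code{level}),
#'   \code{parents} (named list), \code{roots} (named by namespace code) and
#'   the \code{igraph} object \code{graph}.
#' @export
load_ontology <- function(obo_text) {
  lines <- .as_lines(obo_text)
  stanza_starts <- grep("^\\[", lines)
  term_starts <- grep("^\\[Term\\]$", lines)
  bounds <- c(stanza_starts, length(lines) + 1L)

  terms <- list()
  for (s in term_starts) {
    e <- min(bounds[bounds > s]) - 1L
    block <- lines[s:e]
    get1 <- function(key) {
      v <- sub(paste0("^", key, ":\\s*"), "",
               grep(paste0("^", key, ":"), block, value = TRUE))
      if (length(v)) v[1L] else NA_character_
    }
    if (identical(get1("is_obsolete"), "true")) next
    id <- get1("id")
    if (is.na(id)) next
    isa <- sub("\\s*!.*$", "",
               sub("^is_a:\\s*", "", grep("^is_a:", block, value = TRUE)))
    terms[[id]] <- list(id = id, name = get1("name"),
                        namespace = get1("namespace"),
                        parents = trimws(isa))
  }
  if (length(terms) == 0L) stop("no non-obsolete [Term] stanzas found")

  ids <- names(terms)
  parents <- lapply(terms, function(t) intersect(t$parents, ids))
  edges <- do.call(rbind, lapply(ids, function(id) {
    if (length(parents[[id]]) == 0L) return(NULL)
    cbind(id, parents[[id]])
  }))
  g <- igraph::graph_from_data_frame(
    d = if (is.null(edges)) {
      data.frame(from = character(0), to = character(0))
    } else {
      data.frame(from = edges[, 1L], to = edges[, 2L],
                 stringsAsFactors = FALSE)
    },
    directed = TRUE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE)
  )
  if (!igraph::is_dag(g)) stop("is_a cycle detected: ontology must be acyclic")

  ns_raw <- vapply(terms, function(t) t$namespace, character(1))
  ns <- ifelse(ns_raw %in% names(.NAMESPACE_CODE),
               .NAMESPACE_CODE[ns_raw], ns_raw)
  is_root <- lengths(parents) == 0L
  roots <- character(0)
  for (code in unique(ns)) {
    r <- ids[is_root & ns == code]
    if (length(r) != 1L) {
      stop("namespace '", code, "' must have exactly one root, found ",
           length(r))
    }
    roots[code] <- r
  }

  level <- rep(NA_real_, length(ids))
  names(level) <- ids
  for (code in names(roots)) {
    members <- ids[ns == code]
    d <- igraph::distances(g, v = members, to = roots[code], mode = "out")
    level[members] <- as.numeric(d[, 1L])
  }
  if (any(!is.finite(level))) {
    stop("term(s) cannot reach their namespace root: ",
         paste(ids[!is.finite(level)], collapse = ", "))
  }

  structure(
    list(terms = data.frame(
           id = ids,
           name = vapply(terms, function(t) t$name, character(1)),
           namespace = unname(ns),
           level = as.integer(unname(level)),
           stringsAsFactors = FALSE, row.names = NULL),
         parents = parents,
         roots = roots,
         graph = g),
    class = "ontology_graph"
  )
}

#' Read protein annotations from a GAF file
#'
#' Uses columns 2 (object id) and 5 (GO id) of GAF 2.x; rows whose
#' qualifier (column 4) contains \code{NOT} are dropped, as are comment
#' lines starting with \code{!}.
#'
#' @param path GAF file path (or text).
#' @return Data.frame \code{protein_id}, \code{term_id}.
#' @export
read_gaf <- function(path) {
  lines <- .as_lines(path)
  lines <- lines[!grepl("^!", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 5L
  if (any(short)) stop("GAF rows with fewer than 5 columns")
  qualifier <- vapply(fields, `[[`, character(1), 4L)
  keep <- !grepl("(^|\\|)NOT($|\\|)", qualifier)
  data.frame(
    protein_id = vapply(fields[keep], `[[`, character(1), 2L),
    term_id = vapply(fields[keep], `[[`, character(1), 5L),
    stringsAsFactors = FALSE
  )
}

#' Close annotations under is_a propagation
#'
#' Annotating a term implies annotation of all of its ancestors up to the
#' namespace root.
#'
#' @param annotations Data.frame \code{protein_id}, \code{term_id} (e.g.
#'   from \code{\link{read_gaf}}), or a named list protein -> terms.
#' @param ontology An \code{\link{load_ontology}} result. Annotations to
#'   unknown terms are dropped with a warning.
#' @return Named list: protein id -> character vector of term ids, closed
#'   under propagation.
#' @export
propagate_annotations <- function(annotations, ontology) {
  if (is.data.frame(annotations)) {
    annotations <- split(annotations$term_id, annotations$protein_id)
  }
  known <- ontology$terms$id
  anc_cache <- new.env(parent = emptyenv())
  ancestors <- function(term) {
    if (!is.null(anc_cache[[term]])) return(anc_cache[[term]])
    out <- names(igraph::subcomponent(ontology$graph, term, mode = "out"))
    anc_cache[[term]] <- out
    out
  }
  lapply(annotations, function(terms) {
    terms <- unique(terms)
    unknown <- setdiff(terms, known)
    if (length(unknown)) {
      warning("dropping annotation(s) to unknown term(s): ",
              paste(unknown, collapse = ", "))
      terms <- intersect(terms, known)
    }
    unique(unlist(lapply(terms, ancestors), use.names = FALSE))
  })
}

#' One-sided Fisher exact p-value for a 2x2 enrichment table
#'
#' \code{P(X >= a)} under the hypergeometric null with fixed margins, i.e.
#' the one-sided (greater) Fisher exact test for over-representation of a
#' term among \code{a + b} target proteins drawn from a background
#' containing \code{a + c} term carriers.
#'
#' @param a Target proteins carrying the term.
#' @param b Target proteins without the term.
#' @param c Background-only proteins carrying the term.
#' @param d Background-only proteins without the term.
#' @return p-value in \code{(0, 1]}.
#' @export
fisher_term <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("counts must be non-negative")
  stats::phyper(a - 1, m = a + c, n = b + d, k = a + b, lower.tail = FALSE)
}

#' GO-term enrichment of a target set against a background
#'
#' Tests every ontology term of level 1 to \code{max_level} annotating at
#' least one target protein, using the one-sided Fisher exact test, with a
#' Bonferroni correction whose multiplicity \code{m} is the number of terms
#' tested within the term's namespace.
#'
#' @param target_ids Character vector of target protein ids.
#' @param background_ids Character vector of background protein ids; must
#'   contain the target.
#' @param annotations Propagation-closed annotations (see
#'   \code{\link{propagate_annotations}}). Proteins without an entry are
#'   treated as unannotated.
#' @param ontology An \code{\link{load_ontology}} result.
#' @param max_level Deepest ontology level tested (roots are level 0 and
#'   are never tested).
#' @param alpha Significance level applied to the Bonferroni-corrected p.
#' @return Data.frame, one row per tested term: \code{term_id},
#'   \code{name}, \code{namespace}, \code{level}, counts \code{a}--\code{d},
#'   \code{odds_ratio}, \code{fold}, \code{p}, \code{p_bonferroni},
#'   \code{m_tests}, \code{enriched}; sorted by namespace then p.
#' @export
enrich <- function(target_ids, background_ids, annotations, ontology,
                   max_level = 4L, alpha = 0.05) {
  target_ids <- unique(as.character(target_ids))
  background_ids <- unique(as.character(background_ids))
  if (length(target_ids) == 0L) stop("empty target set")
  if (!all(target_ids %in% background_ids)) {
    stop("target set must be a subset of the background")
  }
  n_target <- length(target_ids)
  n_background <- length(background_ids)

  has_term <- function(ids, term) {
    sum(vapply(ids, function(p) term %in% annotations[[p]], logical(1)))
  }
  candidates <- ontology$terms[
    ontology$terms$level >= 1L & ontology$terms$level <= max_level, ,
    drop = FALSE]

  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    term <- candidates$id[i]
    a <- has_term(target_ids, term)
    if (a == 0L) return(NULL)
    bg_with <- has_term(background_ids, term)
    b <- n_target - a
    c <- bg_with - a
    d <- (n_background - n_target) - c
    p <- fisher_term(a, b, c, d)
    odds <- if (b > 0 && c > 0) (a * d) / (b * c) else Inf
    data.frame(term_id = term, name = candidates$name[i],
               namespace = candidates$namespace[i],
               level = candidates$level[i],
               a = a, b = b, c = c, d = d,
               odds_ratio = odds,
               fold = (a / n_target) / (bg_with / n_background),
               p = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(term_id = character(0), name = character(0),
                      namespace = character(0), level = integer(0),
                      a = integer(0), b = integer(0), c = integer(0),
                      d = integer(0), odds_ratio = numeric(0),
                      fold = numeric(0), p = numeric(0),
                      p_bonferroni = numeric(0), m_tests = integer(0),
                      enriched = logical(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  m_by_ns <- table(out$namespace)
  out$m_tests <- as.integer(m_by_ns[out$namespace])
  out$p_bonferroni <- pmin(1, out$p * out$m_tests)
  out$enriched <- out$p_bonferroni < alpha
  out <- out[order(out$namespace, out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}
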