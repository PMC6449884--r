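#' Parse an OBO-format ontology
#'
#' Reads an OBO 1.2/1.4 flat file into a validated `pheno_ontology` object.
#' Only `is_a` relationships are kept; obsolete terms are dropped.  The root
#' is auto-detected as the unique term without parents unless `root` is
#' given, in which case the ontology is restricted to that term's subtree
#' (the usual clinical choice for HPO is the "Phenotypic abnormality"
#' subtree, HP:0000118).
#'
#' @param path Path to an OBO file.
#' @param root Optional term id.  When supplied, the graph is restricted to
#'   `root` and its descendants and `root` becomes the root; required when
#'   several parentless terms remain after parsing.
#' @return A `pheno_ontology`: a list with
#'   \describe{
#'     \item{terms}{tibble with columns `id`, `name`, `definition`,
#'       `synonyms` (list column of character vectors).}
#'     \item{edges}{tibble with columns `child`, `parent` (`is_a` pairs).}
#'     \item{root}{the root term id.}
#'     \item{alt_ids}{named character vector mapping alternative ids to
#'       primary ids.}
#'   }
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' write_obo(toy_fixture()$ontology, obo)
#' ont <- parse_obo(obo)
#' ont$root
#' @export
parse_obo <- function(path, root = NULL) {
  if (!file.exists(path)) stop("OBO file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  stanza_starts <- which(lines == "[Term]")
  if (length(stanza_starts) == 0L)
    stop("no [Term] stanza found in ", path, call. = FALSE)
  block_starts <- grep("^\\[.*\\]$", lines)
  bounds <- c(block_starts, length(lines) + 1L)

  terms <- list()
  edges_child <- character()
  edges_parent <- character()
  alt_map <- character()

  for (s in stanza_starts) {
    end <- min(bounds[bounds > s]) - 1L
    body <- lines[seq(s + 1L, length.out = max(0L, end - s))]
    body <- body[nzchar(body)]
    fld <- function(key) {
      hits <- body[startsWith(body, paste0(key, ":"))]
      trimws(sub(paste0("^", key, ":"), "", hits))
    }
    id <- fld("id")[1]
    if (is.na(id) || !nzchar(id)) next
    if (any(tolower(fld("is_obsolete")) == "true")) next
    name <- fld("name")[1]
    if (is.na(name)) name <- ""
    def_raw <- fld("def")[1]
    definition <- if (is.na(def_raw)) "" else extract_quoted(def_raw)
    synonyms <- vapply(fld("synonym"), extract_quoted, character(1),
                       USE.NAMES = FALSE)
    parents <- sub("\\s*!.*$", "", fld("is_a"))
    parents <- trimws(parents)
    parents <- parents[nzchar(parents)]
    alt <- fld("alt_id")
    if (length(alt)) alt_map[alt] <- id
    terms[[id]] <- list(id = id, name = name, definition = definition,
                        synonyms = synonyms)
    if (length(parents)) {
      edges_child <- c(edges_child, rep(id, length(parents)))
      edges_parent <- c(edges_parent, parents)
    }
  }
  if (!length(terms)) stop("no usable terms parsed from ", path, call. = FALSE)

  term_ids <- names(terms)
  keep <- edges_parent %in% term_ids & edges_child %in% term_ids &
    edges_child != edges_parent
  edges <- tibble::tibble(child = edges_child[keep],
                          parent = edges_parent[keep])
  edges <- dplyr::distinct(edges)

  new_ontology(
    terms = tibble::tibble(
      id = term_ids,
      name = unname(vapply(terms, `[[`, character(1), "name")),
      definition = unname(vapply(terms, `[[`, character(1), "definition")),
      synonyms = unname(lapply(terms, `[[`, "synonyms"))
    ),
    edges = edges, root = root, alt_ids = alt_map
  )
}

extract_quoted <- function(x) {
  m <- regmatches(x, regexpr('"(\\\\.|[^"\\\\])*"', x))
  if (length(m) == 0L) return(trimws(x))
  gsub('\\\\(.)', "\\1", substr(m, 2L, nchar(m) - 1L))
}

#' Construct a validated ontology from terms and edges
#'
#' Low-level constructor behind [parse_obo()] and the fixture generators.
#' Checks acyclicity, root uniqueness and reachability of the root.
#'
#' @param terms Tibble with columns `id`, `name`, `definition`, `synonyms`.
#' @param edges Tibble with columns `child`, `parent`.
#' @param root Optional root id (restricts to its subtree).
#' @param alt_ids Named character vector of alternative-id mappings.
#' @return A `pheno_ontology` object.
#' @export
new_ontology <- function(terms, edges, root = NULL, alt_ids = character()) {
  stopifnot(all(c("id", "name", "definition") %in% names(terms)))
  if (anyDuplicated(terms$id))
    stop("duplicate term ids: ",
         paste(unique(terms$id[duplicated(terms$id)]), collapse = ", "),
         call. = FALSE)
  if (!"synonyms" %in% names(terms))
    terms$synonyms <- rep(list(character()), nrow(terms))

  g <- igraph::graph_from_data_frame(
    edges[, c("child", "parent")], directed = TRUE,
    vertices = terms$id
  )
  if (!igraph::is_dag(g)) {
    cyc <- find_one_cycle(edges)
    stop("ontology graph contains a cycle: ",
         paste(cyc, collapse = " -> "), call. = FALSE)
  }

  apex <- setdiff(terms$id, edges$child)
  if (is.null(root)) {
    if (length(apex) != 1L)
      stop("cannot auto-detect root; parentless terms: ",
           paste(apex, collapse = ", "),
           ". Supply `root` explicitly.", call. = FALSE)
    root <- apex
  } else {
    if (!root %in% terms$id)
      stop("requested root ", root, " not in ontology", call. = FALSE)
    sub_ids <- c(root, descendants_of(edges, root))
    terms <- terms[terms$id %in% sub_ids, , drop = FALSE]
    edges <- edges[edges$child %in% sub_ids & edges$parent %in% sub_ids, ,
                   drop = FALSE]
    g <- igraph::graph_from_data_frame(
      edges[, c("child", "parent")], directed = TRUE, vertices = terms$id)
  }

  ont <- structure(
    list(terms = tibble::as_tibble(terms),
         edges = tibble::as_tibble(edges),
         root = root,
         alt_ids = alt_ids,
         graph = g),
    class = "pheno_ontology"
  )
  # every non-root term must reach the root
  anc <- ancestor_lists(ont)
  bad <- setdiff(names(anc)[!vapply(anc, function(a) root %in% a, logical(1))],
                 root)
  if (length(bad))
    stop("terms not connected to root ", root, ": ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  ont$ancestors <- anc
  ont
}

# one directed cycle, for the error message (edges known to be cyclic)
find_one_cycle <- function(edges) {
  g <- igraph::graph_from_data_frame(edges[, c("child", "parent")],
                                     directed = TRUE)
  for (e in seq_len(nrow(edges))) {
    # a cycle exists iff some edge (c,p) has a path p ->* c
    p <- edges$parent[e]; ch <- edges$child[e]
    sp <- suppressWarnings(
      igraph::shortest_paths(g, from = p, to = ch, mode = "out")$vpath[[1]])
    if (length(sp)) return(c(names(sp), names(sp)[1]))
  }
  c("<cycle>", "<cycle>")
}

descendants_of <- function(edges, id) {
  kids <- split(edges$child, edges$parent)
  out <- character(); frontier <- id
  while (length(frontier)) {
    nxt <- unique(unlist(kids[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, out)
    out <- c(out, nxt)
    frontier <- nxt
  }
  out
}

# named list id -> character vector of all proper ancestors
ancestor_lists <- function(ont) {
  ids <- ont$terms$id
  parents <- split(ont$edges$parent, factor(ont$edges$child, levels = ids))
  anc <- stats::setNames(vector("list", length(ids)), ids)
  order_ids <- topo_order(ont) # parents before children
  for (id in order_ids) {
    ps <- parents[[id]]
    anc[[id]] <- if (is.null(ps) || !length(ps)) character() else
      unique(c(ps, unlist(anc[ps], use.names = FALSE)))
  }
  anc
}

# topological order with ancestors first (root first)
topo_order <- function(ont) {
  names(igraph::topo_sort(ont$graph, mode = "in"))
}

#' @export
print.pheno_ontology <- function(x, ...) {
  cat("<pheno_ontology> ", nrow(x$terms), " terms, ", nrow(x$edges),
      " is_a edges, root ", x$root,
      ", max depth ", most_depth(x), "\n", sep = "")
  invisible(x)
}

#' Ancestors of a term
#'
#' Transitive closure over `is_a` parent edges, excluding the term itself.
#' The root is an ancestor of every non-root term.
#'
#' @param ontology A `pheno_ontology`.
#' @param id A term id (vectorised: a character vector).
#' @return For a single id, a character vector; for several, a named list.
#' @export
term_ancestors <- function(ontology, id) {
  check_terms(ontology, id)
  res <- ontology$ancestors[id]
  if (length(id) == 1L) res[[1]] else res
}

#' Descendants of a term
#'
#' @inheritParams term_ancestors
#' @return Character vector of all terms having `id` among their ancestors.
#' @export
term_descendants <- function(ontology, id) {
  check_terms(ontology, id)
  stopifnot(length(id) == 1L)
  descendants_of(ontology$edges, id)
}

check_terms <- function(ontology, ids) {
  bad <- setdiff(ids, ontology$terms$id)
  if (length(bad))
    stop("unknown term id(s): ", paste(bad, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Longest leaf-to-root path length
#'
#' The maximum number of edges on a directed path from any term to the root,
#' computed by longest-path dynamic programming over a topological order.
#' A single-term ontology has depth 0.
#'
#' @param ontology A `pheno_ontology`.
#' @return Non-negative integer.
#' @export
most_depth <- function(ontology) {
  ids <- ontology$terms$id
  if (nrow(ontology$edges) == 0L) return(0L)
  depth <- stats::setNames(integer(length(ids)), ids)
  parents <- split(ontology$edges$parent,
                   factor(ontology$edges$child, levels = ids))
  for (id in topo_order(ontology)) {
    ps <- parents[[id]]
    if (!is.null(ps) && length(ps)) depth[id] <- max(depth[ps]) + 1L
  }
  max(depth)
}

#' Write an ontology to an OBO file
#'
#' Emits OBO 1.2 stanzas (`id`, `name`, `def`, `synonym`, `is_a`) that
#' round-trip through [parse_obo()].
#'
#' @param ontology A `pheno_ontology`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(ontology, path) {
  parents <- split(ontology$edges$parent, ontology$edges$child)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(ontology$terms))) {
    id <- ontology$terms$id[i]
    out <- c("[Term]",
             paste0("id: ", id),
             paste0("name: ", ontology$terms$name[i]))
    d <- ontology$terms$definition[i]
    if (nzchar(d))
      out <- c(out, paste0("def: \"", gsub('"', '\\\\"', d), "\" []"))
    for (s in ontology$terms$synonyms[[i]])
      out <- c(out, paste0("synonym: \"", gsub('"', '\\\\"', s),
                           "\" EXACT []"))
    for (p in sort(parents[[id]]))
      out <- c(out, paste0("is_a: ", p))
    writeLines(c(out, ""), con)
  }
  invisible(path)
}
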