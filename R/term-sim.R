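#' Is one term an ancestor or descendant of the other?
#'
#' Two terms are "reachable" when a directed path links them in the is_a
#' DAG, i.e. one is an ancestor of the other (or they are identical).
#' Sibling terms sharing only a common ancestor are unreachable and score 0
#' in [term_sim()]: in a phenotype hierarchy, sibling leaves need share
#' neither causative genes nor disease symptoms.
#'
#' @param ontology A `pheno_ontology`.
#' @param t_i,t_j Term ids.
#' @return Logical flag.
#' @export
reachable <- function(ontology, t_i, t_j) {
  check_terms(ontology, c(t_i, t_j))
  t_i == t_j || t_i %in% ontology$ancestors[[t_j]] ||
    t_j %in% ontology$ancestors[[t_i]]
}

#' Shortest directed distance and best weight product between two terms
#'
#' For a reachable pair, the distance is the minimum number of edges on a
#' directed path between the terms, and the path weight is the maximum, over
#' all minimum-length paths, of the product of edge weights along the path.
#' The identity pair has distance 0 and weight 1 (empty product).
#'
#' @param wdag A `pheno_wdag` from [build_wdag()].
#' @param t_i,t_j Term ids; must be reachable.
#' @return Named list with `dist` (integer) and `path_weight` (in \[0,1\]).
#' @export
path_metrics <- function(wdag, t_i, t_j) {
  ont <- wdag$base
  check_terms(ont, c(t_i, t_j))
  if (t_i == t_j) return(list(dist = 0L, path_weight = 1.0))
  if (t_j %in% ont$ancestors[[t_i]]) {
    lo <- t_i; hi <- t_j
  } else if (t_i %in% ont$ancestors[[t_j]]) {
    lo <- t_j; hi <- t_i
  } else {
    stop("terms ", t_i, " and ", t_j, " are not reachable", call. = FALSE)
  }
  tab <- upward_table(ont, wdag$edge_weight, lo)
  list(dist = tab$dist[[hi]], path_weight = tab$weight[[hi]])
}

# Level-order (BFS) dynamic programme from `from` up its ancestor cone:
# dist = shortest #edges to each ancestor; weight = max product of edge
# weights among shortest paths.  Parents-of-level-k nodes form level k+1;
# processing whole levels before moving on makes the max-product recurrence
# well-defined.
upward_table <- function(ontology, edge_weight, from) {
  pw <- split(
    stats::setNames(edge_weight$weight, edge_weight$parent),
    edge_weight$child
  )
  dist <- stats::setNames(0L, from)
  wprod <- stats::setNames(1.0, from)
  frontier <- from
  k <- 0L
  while (length(frontier)) {
    k <- k + 1L
    nxt <- new.env(parent = emptyenv())
    for (v in frontier) {
      ps <- pw[[v]]
      for (j in seq_along(ps)) {
        p <- names(ps)[j]
        if (!is.na(dist[p])) next    # already reached at a shorter level
        cand <- wprod[[v]] * ps[[j]]
        prev <- get0(p, envir = nxt, ifnotfound = -1)
        if (cand > prev) assign(p, cand, envir = nxt)
      }
    }
    new_nodes <- ls(nxt)
    if (!length(new_nodes)) break
    dist[new_nodes] <- k
    wprod[new_nodes] <- vapply(new_nodes, get, numeric(1), envir = nxt)
    frontier <- new_nodes
  }
  list(dist = as.list(dist), weight = as.list(wprod))
}

#' Path-constrained term similarity
#'
#' For a reachable pair the similarity is
#' `min(IC(t_i), IC(t_j)) * W(t_i, t_j) * (1 - dist(t_i, t_j) / mostDepth)`,
#' where `W` is the best weight product along a shortest directed path
#' ([path_metrics()]) and `mostDepth` the ontology's longest leaf-to-root
#' path ([most_depth()]).  Unreachable pairs score 0.  `sim(t, t) = IC(t)`.
#'
#' @param ic An `ic_table` from [compute_ic()].
#' @param wdag A `pheno_wdag` built on the same ontology.
#' @param depth The `most_depth` value of the ontology; a depth of 0
#'   (single-node ontology) disables the distance factor.
#' @param t_i,t_j Term ids.
#' @param use_weight,use_depth Ablation toggles: unit edge weights / no
#'   distance penalty.
#' @return Non-negative similarity; symmetric in its term arguments and
#'   bounded by `min(IC(t_i), IC(t_j))`.
#' @examples
#' fx <- toy_fixture()
#' ic <- compute_ic(fx$ontology, fx$corpus, w = 1)
#' wd <- build_wdag(fx$ontology)
#' term_sim(ic, wd, most_depth(fx$ontology), "T:0000003", "T:0000001")
#' @export
term_sim <- function(ic, wdag, depth, t_i, t_j,
                     use_weight = TRUE, use_depth = TRUE) {
  ont <- wdag$base
  check_terms(ont, c(t_i, t_j))
  if (!reachable(ont, t_i, t_j)) return(0)
  pm <- path_metrics(wdag, t_i, t_j)
  icv <- stats::setNames(ic$ic, ic$term_id)
  mic <- min(icv[[t_i]], icv[[t_j]])
  w <- if (use_weight) pm$path_weight else 1.0
  d <- if (use_depth && depth > 0) 1 - pm$dist / depth else 1.0
  mic * w * max(0, d)
}
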