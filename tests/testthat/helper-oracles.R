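# Independent brute-force oracles used by the tests.  These deliberately
# share no code with the package internals: closures by repeated edge
# chasing, exhaustive path enumeration, two-pass tf-idf, naive double loops.

# transitive closure of parent edges by iterated expansion
brute_ancestors <- function(edges, t) {
  anc <- character()
  frontier <- t
  repeat {
    nxt <- unique(edges$parent[edges$child %in% frontier])
    nxt <- setdiff(nxt, anc)
    if (!length(nxt)) break
    anc <- c(anc, nxt)
    frontier <- nxt
  }
  sort(anc)
}

# all directed paths (sequences of nodes) from `from` up to `to`
enumerate_paths <- function(edges, from, to) {
  paths <- list()
  walk <- function(node, acc) {
    if (node == to) {
      paths[[length(paths) + 1L]] <<- acc
      return(invisible())
    }
    for (p in edges$parent[edges$child == node]) walk(p, c(acc, p))
  }
  walk(from, from)
  paths
}

# exhaustive dist / max-product-over-shortest-paths between a reachable pair
brute_path_metrics <- function(edges, weights, t_i, t_j) {
  key <- paste(edges$child, edges$parent)
  wmap <- stats::setNames(weights, key)
  paths <- enumerate_paths(edges, t_i, t_j)
  if (!length(paths)) paths <- enumerate_paths(edges, t_j, t_i)
  stopifnot(length(paths) > 0)
  lens <- vapply(paths, length, integer(1)) - 1L
  d <- min(lens)
  best <- max(vapply(paths[lens == d], function(p) {
    if (length(p) == 1L) return(1)
    prod(wmap[paste(p[-length(p)], p[-1])])
  }, numeric(1)))
  list(dist = d, path_weight = best)
}

# exhaustive longest path to the root, any start node
brute_most_depth <- function(edges, ids, root) {
  if (!nrow(edges)) return(0L)
  longest <- 0L
  for (t in setdiff(ids, root)) {
    for (p in enumerate_paths(edges, t, root))
      longest <- max(longest, length(p) - 1L)
  }
  longest
}

# per-unit closure-union counting
brute_propagated_counts <- function(edges, ids, unit_to_terms) {
  counts <- stats::setNames(integer(length(ids)), ids)
  for (terms in unit_to_terms) {
    closed <- unique(c(terms,
                       unlist(lapply(terms, brute_ancestors, edges = edges))))
    counts[closed] <- counts[closed] + 1L
  }
  counts
}

# two-pass tf / df recomputation over token lists
brute_tfidf <- function(docs) {
  n <- length(docs)
  df <- table(unlist(lapply(docs, unique)))
  lapply(docs, function(toks) {
    if (!length(toks)) return(stats::setNames(numeric(), character()))
    out <- vapply(unique(toks), function(word) {
      (sum(toks == word) / length(toks)) * log(n / df[[word]])
    }, numeric(1))
    out
  })
}

# naive double loop over the set-similarity definition
brute_directed_set_sim <- function(T_from, T_to, sim_fun, pmi_fun = NULL) {
  total <- 0
  for (ti in T_from) {
    best <- -Inf
    for (tj in T_to) {
      v <- sim_fun(ti, tj)
      if (!is.null(pmi_fun)) v <- v * pmi_fun(ti, tj)
      if (v > best) best <- v
    }
    total <- total + best
  }
  total / length(T_from)
}

# random rooted DAG (node 1 is the root; every later node gets 1-2 parents
# among earlier nodes), with random definitions and random edge weights
random_dag_fixture <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("R:%07d", seq_len(n))
  child <- character(); parent <- character()
  if (n > 1) {
    for (i in 2:n) {
      k <- sample(1:min(2, i - 1), 1)
      ps <- sample(ids[seq_len(i - 1)], k)
      child <- c(child, rep(ids[i], k))
      parent <- c(parent, ps)
    }
  }
  words <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta", "eta")
  ont <- phenorank::new_ontology(
    terms = tibble::tibble(
      id = ids,
      name = paste("node", seq_len(n)),
      definition = vapply(seq_len(n), function(i)
        paste(sample(words, sample(2:4, 1), replace = TRUE),
              collapse = " "), character(1)),
      synonyms = rep(list(character()), n)
    ),
    edges = tibble::tibble(child = child, parent = parent)
  )
  wdag <- structure(
    list(base = ont,
         edge_weight = tibble::tibble(
           child = ont$edges$child, parent = ont$edges$parent,
           weight = stats::runif(nrow(ont$edges))
         )),
    class = "pheno_wdag")
  list(ontology = ont, wdag = wdag)
}

# random annotation corpus over an ontology's non-root terms
random_corpus <- function(ontology, n_genes, n_diseases, seed) {
  set.seed(seed)
  pool <- setdiff(ontology$terms$id, ontology$root)
  draw <- function(n, prefix) {
    stats::setNames(
      lapply(seq_len(n), function(i)
        sample(pool, sample(1:min(4, length(pool)), 1))),
      paste0(prefix, seq_len(n)))
  }
  phenorank::new_corpus(draw(n_genes, "g"), draw(n_diseases, "DB:"))
}

toy_ids <- sprintf("T:%07d", 0:5)
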