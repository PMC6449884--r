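#' Similarity configuration
#'
#' Bundles the tunable parameters of the similarity measure.  The four
#' ablation toggles mirror the measure's components: dual-source annotation
#' (`ic_source`), the depth/distance penalty (`use_depth`), the
#' definition-weighted DAG (`use_weight`) and PMI set weighting
#' (`pmi_mode`).
#'
#' @param w Gene/disease IC blending weight in \[0,1\] (default 0.5; used
#'   when `ic_source = "both"`).
#' @param ic_source `"both"` (blend with `w`), `"gene"` or `"disease"`.
#' @param pmi_mode `"positive"` (clamp negatives, default), `"raw"`, or
#'   `"off"` (plain symmetric best-match average).
#' @param pmi_source Which corpus the PMI probabilities come from; pick the
#'   candidate type being ranked (default `"disease"`), or `"union"`.
#' @param use_depth Apply the `(1 - dist / mostDepth)` factor.
#' @param use_weight Use TF-IDF cosine edge weights (else unit weights).
#' @param tie_policy Rank assigned within score ties: `"pessimistic"`
#'   (maximal rank, default) or `"mean"`.
#' @return A `sim_config` list.
#' @export
sim_config <- function(w = 0.5,
                       ic_source = c("both", "gene", "disease"),
                       pmi_mode = c("positive", "raw", "off"),
                       pmi_source = c("disease", "gene", "union"),
                       use_depth = TRUE,
                       use_weight = TRUE,
                       tie_policy = c("pessimistic", "mean")) {
  if (!is.numeric(w) || length(w) != 1L || is.na(w) || w < 0 || w > 1)
    stop("`w` must be a single number in [0, 1]", call. = FALSE)
  structure(list(
    w = w,
    ic_source = match.arg(ic_source),
    pmi_mode = match.arg(pmi_mode),
    pmi_source = match.arg(pmi_source),
    use_depth = isTRUE(use_depth),
    use_weight = isTRUE(use_weight),
    tie_policy = match.arg(tie_policy)
  ), class = "sim_config")
}

#' Precompute everything the similarity measure needs
#'
#' Builds, once per (ontology, corpus): the TF-IDF-weighted DAG, the
#' per-source propagated annotation counts, the ontology depth, PMI
#' co-annotation counts for both sources, and per-term ancestor tables
#' holding the shortest directed distance and the best edge-weight product
#' along shortest paths.  All configuration-dependent quantities (the `w`
#' blend, ablation toggles, PMI mode) are applied at query time, so one
#' index serves every [sim_config()].
#'
#' @param ontology A `pheno_ontology`.
#' @param corpus A `pheno_corpus`.
#' @param stopwords Passed to the definition tokenizer.
#' @return A `pheno_index`.
#' @examples
#' fx <- toy_fixture()
#' idx <- pheno_index(fx$ontology, fx$corpus)
#' glance(idx)
#' @export
pheno_index <- function(ontology, corpus, stopwords = TRUE) {
  wdag <- build_wdag(ontology, stopwords = stopwords)
  ids <- ontology$terms$id
  up <- lapply(stats::setNames(ids, ids), function(t)
    upward_table(ontology, wdag$edge_weight, t))
  structure(list(
    ontology = ontology,
    corpus = corpus,
    wdag = wdag,
    depth = most_depth(ontology),
    counts_gene = propagated_counts(ontology, corpus$gene_to_terms),
    counts_disease = propagated_counts(ontology, corpus$disease_to_terms),
    pmi = list(gene = build_pmi(corpus, ontology, "gene"),
               disease = build_pmi(corpus, ontology, "disease"),
               union = build_pmi(corpus, ontology, "union")),
    up_tables = up
  ), class = "pheno_index")
}

#' @export
print.pheno_index <- function(x, ...) {
  cat("<pheno_index> ", nrow(x$ontology$terms), " terms, depth ", x$depth,
      "; ", length(x$corpus$gene_to_terms), " genes, ",
      length(x$corpus$disease_to_terms), " diseases\n", sep = "")
  invisible(x)
}

# combined per-term IC vector under a config (named over all terms)
index_ic <- function(index, config) {
  mk <- function(counts) {
    total <- counts[[index$ontology$root]]
    ic <- ifelse(counts > 0, log(total / counts), NA_real_)
    mx <- suppressWarnings(max(ic, na.rm = TRUE))
    ic[is.na(ic)] <- if (is.finite(mx)) mx else 0
    ic
  }
  icg <- mk(index$counts_gene)
  icd <- mk(index$counts_disease)
  switch(config$ic_source,
         both = config$w * icg + (1 - config$w) * icd,
         gene = icg,
         disease = icd)
}

#' Pairwise term-similarity matrix
#'
#' Vectorised version of [term_sim()] over two term vectors, driven by the
#' precomputed ancestor tables of a [pheno_index()].
#'
#' @param index A `pheno_index`.
#' @param terms_a,terms_b Character vectors of term ids (default: all
#'   ontology terms).
#' @param config A [sim_config()].
#' @return Numeric matrix with dimnames `terms_a` x `terms_b`.
#' @export
term_sim_matrix <- function(index, terms_a = NULL, terms_b = NULL,
                            config = sim_config()) {
  ont <- index$ontology
  if (is.null(terms_a)) terms_a <- ont$terms$id
  if (is.null(terms_b)) terms_b <- ont$terms$id
  check_terms(ont, c(terms_a, terms_b))
  ic <- index_ic(index, config)
  out <- matrix(0, length(terms_a), length(terms_b),
                dimnames = list(terms_a, terms_b))
  bset <- stats::setNames(seq_along(terms_b), terms_b)
  depth <- index$depth
  for (i in seq_along(terms_a)) {
    ta <- terms_a[i]
    # pairs where ta is the descendant
    tab <- index$up_tables[[ta]]
    reach_up <- intersect(names(tab$dist), terms_b)
    # pairs where ta is the ancestor: consult the other side's table
    reach_dn <- terms_b[vapply(terms_b, function(tb)
      !is.na(match(ta, names(index$up_tables[[tb]]$dist))) && tb != ta,
      logical(1))]
    for (tb in reach_up) {
      d <- tab$dist[[tb]]; pw <- tab$weight[[tb]]
      out[i, bset[[tb]]] <- pair_sim(ic[[ta]], ic[[tb]], d, pw, depth,
                                     config)
    }
    for (tb in reach_dn) {
      tb_tab <- index$up_tables[[tb]]
      d <- tb_tab$dist[[ta]]; pw <- tb_tab$weight[[ta]]
      out[i, bset[[tb]]] <- pair_sim(ic[[ta]], ic[[tb]], d, pw, depth,
                                     config)
    }
  }
  out
}

pair_sim <- function(ic_a, ic_b, d, pw, depth, config) {
  w <- if (config$use_weight) pw else 1.0
  f <- if (config$use_depth && depth > 0) 1 - d / depth else 1.0
  min(ic_a, ic_b) * w * max(0, f)
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' @rdname pheno_index
#' @param x A `pheno_index`.
#' @param ... Unused.
#' @method glance pheno_index
#' @export
glance.pheno_index <- function(x, ...) {
  tibble::tibble(
    n_terms = nrow(x$ontology$terms),
    n_edges = nrow(x$ontology$edges),
    depth = x$depth,
    n_genes = length(x$corpus$gene_to_terms),
    n_diseases = length(x$corpus$disease_to_terms),
    mean_edge_weight = mean(x$wdag$edge_weight$weight)
  )
}

#' @rdname pheno_index
#' @method tidy pheno_index
#' @export
tidy.pheno_index <- function(x, ...) {
  ic05 <- compute_ic(x$ontology, x$corpus, w = 0.5)
  tibble::as_tibble(ic05)
}
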