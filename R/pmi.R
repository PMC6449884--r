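#' Build a pointwise mutual information model of term co-annotation
#'
#' Two phenotype terms are associated when they appear in the same unit's
#' (gene's or disease's) annotation set.  With propagated term sets,
#' `p(t)` is the fraction of units whose closed set contains `t`, `p(a, b)`
#' the fraction containing both, and `PMI(a, b) = ln(p(a,b) / (p(a) p(b)))`.
#'
#' Conventions: never-co-annotated pairs (including any term never
#' annotated) get PMI 0 — "no evidence of association" — rather than
#' negative infinity; `PMI(t, t) = -ln p(t) >= 0`.  In `positive` mode
#' (the default downstream) negative values are clamped to 0, so the
#' best-match weighting never prefers a weaker match.
#'
#' @param corpus A `pheno_corpus`.
#' @param ontology The `pheno_ontology` used for upward propagation.
#' @param source `"gene"`, `"disease"`, or `"union"` (pool both unit sets).
#' @return A `pheno_pmi`: list with `source`, `n_units`, `term_count`
#'   (named integer), and `pair_count` (sparse symmetric matrix of joint
#'   unit counts over annotated terms).
#' @export
build_pmi <- function(corpus, ontology,
                      source = c("disease", "gene", "union")) {
  source <- match.arg(source)
  units <- switch(source,
    gene = corpus$gene_to_terms,
    disease = corpus$disease_to_terms,
    union = c(corpus$gene_to_terms, corpus$disease_to_terms)
  )
  if (!length(units))
    stop("annotation corpus for source '", source, "' is empty",
         call. = FALSE)
  closed <- lapply(units, function(ts) propagate_terms(ontology, ts))
  vocab <- sort(unique(unlist(closed, use.names = FALSE)))
  inc <- Matrix::sparseMatrix(
    i = rep(seq_along(closed), lengths(closed)),
    j = match(unlist(closed, use.names = FALSE), vocab),
    x = 1,
    dims = c(length(closed), length(vocab)),
    dimnames = list(NULL, vocab)
  )
  pair <- Matrix::crossprod(inc) # joint unit counts; diagonal = marginals
  structure(
    list(source = source,
         n_units = length(closed),
         term_count = stats::setNames(as.integer(Matrix::diag(pair)), vocab),
         pair_count = pair),
    class = "pheno_pmi"
  )
}

#' @export
print.pheno_pmi <- function(x, ...) {
  cat("<pheno_pmi> source ", x$source, ", ", x$n_units, " units, ",
      length(x$term_count), " annotated terms\n", sep = "")
  invisible(x)
}

#' PMI values for term pairs
#'
#' @param pmi A `pheno_pmi`.
#' @param terms_a,terms_b Character vectors of term ids.
#' @param mode `"positive"` clamps negative PMI to 0; `"raw"` keeps it;
#'   `"off"` returns 1 everywhere (PMI weighting disabled).
#' @return A `length(terms_a) x length(terms_b)` numeric matrix with
#'   dimnames.
#' @export
pmi_matrix <- function(pmi, terms_a, terms_b,
                       mode = c("positive", "raw", "off")) {
  mode <- match.arg(mode)
  out <- matrix(0, length(terms_a), length(terms_b),
                dimnames = list(terms_a, terms_b))
  if (mode == "off") return(out + 1)
  ia <- match(terms_a, colnames(pmi$pair_count))
  ib <- match(terms_b, colnames(pmi$pair_count))
  ok_a <- which(!is.na(ia)); ok_b <- which(!is.na(ib))
  if (length(ok_a) && length(ok_b)) {
    joint <- as.matrix(pmi$pair_count[ia[ok_a], ib[ok_b], drop = FALSE])
    pa <- pmi$term_count[terms_a[ok_a]] / pmi$n_units
    pb <- pmi$term_count[terms_b[ok_b]] / pmi$n_units
    pj <- joint / pmi$n_units
    val <- log(pj / outer(pa, pb))
    val[joint == 0] <- 0
    out[ok_a, ok_b] <- val
  }
  if (mode == "positive") out[out < 0] <- 0
  out
}

#' @rdname pmi_matrix
#' @param t_i,t_j Single term ids.
#' @export
pmi_value <- function(pmi, t_i, t_j, mode = c("positive", "raw", "off")) {
  pmi_matrix(pmi, t_i, t_j, mode = mode)[1, 1]
}
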