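stopword_list <- c(
  "a", "an", "and", "are", "as", "at", "be", "but", "by", "for", "from",
  "has", "have", "in", "into", "is", "it", "its", "may", "no", "not", "of",
  "on", "or", "such", "than", "that", "the", "their", "there", "these",
  "this", "to", "usually", "was", "were", "which", "will", "with"
)

#' Tokenize a phenotype term definition
#'
#' Lowercases, strips punctuation, splits on whitespace and removes a small
#' fixed English stop-word list.  When the definition is empty the term's
#' name and synonyms are used instead.  May return an empty vector.
#'
#' @param definition Definition text (may be empty or `NA`).
#' @param name,synonyms Fallback text used when `definition` is empty.
#' @param stopwords Logical; remove stop-words (default `TRUE`).
#' @return Character vector of tokens.
#' @examples
#' tokenize_definition("Split hand.")
#' tokenize_definition("", name = "Areflexia of upper limbs")
#' @export
tokenize_definition <- function(definition, name = "",
                                synonyms = character(),
                                stopwords = TRUE) {
  text <- if (!is.na(definition) && nzchar(trimws(definition))) definition
          else paste(c(name, synonyms), collapse = " ")
  toks <- strsplit(gsub("[^a-z0-9]+", " ", tolower(text)), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  if (stopwords) toks <- toks[!toks %in% stopword_list]
  toks
}

#' TF-IDF vectors for every term definition
#'
#' Each term's token list (see [tokenize_definition()]) is one document; the
#' corpus is the whole ontology.  The component for word `p` in document `t`
#' is `tf(p, t) * idf(p)` with `tf = n_p / |t|` (count over document length)
#' and `idf = ln(|T| / df(p))` (natural log of the corpus size over the
#' number of documents containing `p`).  Words present in every document get
#' weight 0; terms with no tokens get an empty vector.
#'
#' @param ontology A `pheno_ontology`.
#' @param stopwords Passed to [tokenize_definition()].
#' @return Named list (by term id) of named numeric vectors.
#' @export
tfidf_vectors <- function(ontology, stopwords = TRUE) {
  docs <- purrr::pmap(
    list(ontology$terms$definition, ontology$terms$name,
         ontology$terms$synonyms),
    function(d, n, s) tokenize_definition(d, n, s, stopwords = stopwords)
  )
  names(docs) <- ontology$terms$id
  n_docs <- length(docs)
  df_counts <- table(unlist(lapply(docs, unique), use.names = FALSE))
  idf <- log(n_docs / as.numeric(df_counts))
  names(idf) <- names(df_counts)
  lapply(docs, function(toks) {
    if (!length(toks)) return(stats::setNames(numeric(), character()))
    tf <- table(toks) / length(toks)
    stats::setNames(as.numeric(tf) * idf[names(tf)], names(tf))
  })
}

cosine_sparse <- function(a, b) {
  if (!length(a) || !length(b)) return(NA_real_)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  shared <- intersect(names(a), names(b))
  if (!length(shared)) return(0)
  sum(a[shared] * b[shared]) / (na * nb)
}

#' Build the definition-weighted DAG
#'
#' Weights every `is_a` edge with the cosine similarity of the TF-IDF
#' vectors of the child and parent definitions, clamped to \[0,1\].  Edges
#' where either endpoint has an empty/zero vector get the neutral weight 1:
#' a zero there would annihilate every path through the term in the
#' path-product used by [term_sim()].
#'
#' @param ontology A `pheno_ontology`.
#' @param stopwords Passed to [tokenize_definition()].
#' @return A `pheno_wdag`: list with `base` (the ontology) and `edge_weight`
#'   (tibble `child`, `parent`, `weight`).
#' @export
build_wdag <- function(ontology, stopwords = TRUE) {
  vecs <- tfidf_vectors(ontology, stopwords = stopwords)
  w <- purrr::map2_dbl(ontology$edges$child, ontology$edges$parent,
                       function(c_, p_) {
    cs <- cosine_sparse(vecs[[c_]], vecs[[p_]])
    if (is.na(cs)) 1.0 else min(1, max(0, cs))
  })
  structure(
    list(base = ontology,
         edge_weight = tibble::tibble(child = ontology$edges$child,
                                      parent = ontology$edges$parent,
                                      weight = w)),
    class = "pheno_wdag"
  )
}

#' @export
print.pheno_wdag <- function(x, ...) {
  cat("<pheno_wdag> ", nrow(x$edge_weight), " weighted is_a edges, ",
      "mean weight ", round(mean(x$edge_weight$weight), 3), "\n", sep = "")
  invisible(x)
}

#' Write / read an edge-weight cache
#'
#' @param wdag A `pheno_wdag`.
#' @param path File path.
#' @param ontology Ontology to reattach when reading.
#' @return `path` / the re-read `pheno_wdag`.
#' @export
write_wdag_cache <- function(wdag, path) {
  utils::write.table(as.data.frame(wdag$edge_weight), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_wdag_cache
#' @export
read_wdag_cache <- function(path, ontology) {
  df <- tibble::as_tibble(utils::read.delim(path,
                                            colClasses = c("character",
                                                           "character",
                                                           "numeric")))
  structure(list(base = ontology, edge_weight = df), class = "pheno_wdag")
}
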