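#' Generate a synthetic ontology + annotation corpus fixture
#'
#' Builds a random layered is_a DAG with textual definitions and a matching
#' gene/disease annotation corpus, emulating the structure of a phenotype
#' ontology with its two annotation files: a single root, terms arranged in
#' depth layers with occasional extra (diamond-forming) parents, definitions
#' drawn from a Zipf-weighted vocabulary with controllable parent/child
#' vocabulary overlap, leaf-biased annotation sets, per-(disease, term)
#' penetrance values on the standard frequency-modifier midpoints, and a
#' coupling knob that makes genes co-annotated with diseases (coupling 0
#' gives fully independent gene annotation, i.e. no co-annotation structure
#' beyond chance).
#'
#' Deterministic given `seed`; the result always passes parse-time
#' validation (acyclic, rooted) and round-trips through [write_obo()],
#' [write_gene_annotations()] and [write_disease_annotations()].
#'
#' @param n_terms Total number of terms (>= 2), root included.
#' @param n_genes,n_diseases Number of annotation units per source.
#' @param depth Number of layers below the root (the realized
#'   [most_depth()] equals `depth` when every layer is populated).
#' @param vocab_size Vocabulary size for definitions.
#' @param seed Integer seed.
#' @param def_overlap Probability a child definition keeps each token of its
#'   primary parent's definition.
#' @param extra_parent_prob Probability a term gets a second parent.
#' @param mean_terms_per_disease,mean_terms_per_gene Poisson means for
#'   annotation set sizes (floored at 2).
#' @param coupling Probability a gene copies (most of) a random disease's
#'   annotation set instead of drawing independently.
#' @param common_pool_size,common_frac Co-annotation structure across
#'   diseases: a pool of `common_pool_size` recurring phenotypes (think
#'   seizures, short stature) from which each disease draws about
#'   `common_frac` of its terms, the rest being disease-specific leaf-biased
#'   draws.  Set `common_frac = 0` for independent disease annotation.
#' @param freq_levels,freq_weights Penetrance values sampled per
#'   (disease, term) and their sampling weights.
#' @return List with `ontology` (a `pheno_ontology`) and `corpus`
#'   (a `pheno_corpus`).
#' @export
make_fixture <- function(n_terms = 200, n_genes = 40, n_diseases = 30,
                         depth = 6, vocab_size = 150, seed = 1L,
                         def_overlap = 0.5, extra_parent_prob = 0.3,
                         mean_terms_per_disease = 8,
                         mean_terms_per_gene = 6,
                         coupling = 0.6,
                         common_pool_size = 20, common_frac = 0.35,
                         freq_levels = c(1.0, 0.895, 0.545, 0.17),
                         freq_weights = c(0.05, 0.3, 0.4, 0.25)) {
  if (n_terms < 2) stop("n_terms must be >= 2", call. = FALSE)
  if (depth < 1) stop("depth must be >= 1", call. = FALSE)
  if (n_terms - 1 < depth)
    stop("need at least one term per layer: n_terms-1 >= depth",
         call. = FALSE)
  withr::with_seed(as_seed(seed), {
    ids <- sprintf("T:%07d", seq_len(n_terms) - 1L)
    root <- ids[1]
    # geometric-ish layer sizes, every layer populated
    raw <- 1.6^seq_len(depth)
    sizes <- pmax(1L, as.integer(round((n_terms - 1L) * raw / sum(raw))))
    while (sum(sizes) > n_terms - 1L) {
      j <- which.max(sizes); sizes[j] <- sizes[j] - 1L
    }
    while (sum(sizes) < n_terms - 1L) {
      j <- which.min(sizes); sizes[j] <- sizes[j] + 1L
    }
    layer <- c(0L, rep(seq_len(depth), times = sizes))
    stopifnot(length(layer) == n_terms)

    vocab <- sprintf("word%04d", seq_len(vocab_size))
    zipf <- (1 / seq_len(vocab_size))
    draw_words <- function(k) sample(vocab, k, replace = TRUE, prob = zipf)

    defs <- character(n_terms)
    defs[1] <- paste(draw_words(6L), collapse = " ")
    child <- character(); parent <- character()
    for (i in 2:n_terms) {
      prev <- which(layer == layer[i] - 1L)
      prim <- if (length(prev) == 1L) prev else sample(prev, 1L)
      ps <- ids[prim]
      shallower <- which(layer < layer[i])
      shallower <- setdiff(shallower, prim)
      if (length(shallower) && stats::runif(1) < extra_parent_prob) {
        extra <- if (length(shallower) == 1L) shallower else
          sample(shallower, 1L)
        ps <- c(ps, ids[extra])
      }
      child <- c(child, rep(ids[i], length(ps)))
      parent <- c(parent, ps)
      inherited <- strsplit(defs[prim], " ")[[1]]
      inherited <- inherited[stats::runif(length(inherited)) < def_overlap]
      len <- sample(3:12, 1L)
      fresh <- if (len > length(inherited)) draw_words(len -
                                                       length(inherited))
               else character()
      defs[i] <- paste(c(inherited, fresh), collapse = " ")
    }

    ontology <- new_ontology(
      terms = tibble::tibble(
        id = ids,
        name = paste("synthetic term", seq_len(n_terms) - 1L),
        definition = defs,
        synonyms = rep(list(character()), n_terms)
      ),
      edges = tibble::tibble(child = child, parent = parent)
    )

    # deeper terms are more likely to be annotated (leaf bias)
    ann_prob <- (layer + 0.25)^2
    ann_prob[1] <- 0
    draw_terms <- function(mean_size) {
      k <- max(2L, stats::rpois(1L, mean_size))
      k <- min(k, n_terms - 1L)
      sample(ids, k, prob = ann_prob)
    }

    pool_size <- min(common_pool_size, n_terms - 1L)
    common_pool <- sample(ids, pool_size, prob = ann_prob)
    disease_ids <- sprintf("DB:%06d", 100000L + seq_len(n_diseases))
    disease_to_terms <- stats::setNames(
      purrr::map(seq_len(n_diseases), function(d) {
        specific <- draw_terms(mean_terms_per_disease)
        n_common <- stats::rbinom(1L, length(specific), common_frac)
        if (n_common > 0L)
          specific[seq_len(n_common)] <- sample(common_pool,
                                                min(n_common, pool_size))
        unique(specific)
      }),
      disease_ids)

    gene_ids <- sprintf("GENE%03d", seq_len(n_genes))
    gene_to_terms <- stats::setNames(purrr::map(seq_len(n_genes), function(g) {
      if (stats::runif(1) < coupling) {
        d <- disease_to_terms[[sample(n_diseases, 1L)]]
        kept <- d[stats::runif(length(d)) < 0.7]
        if (!length(kept)) kept <- d[sample(length(d), 1L)]
        unique(c(kept, draw_terms(2)))
      } else {
        draw_terms(mean_terms_per_gene)
      }
    }), gene_ids)

    freq <- tibble::tibble(
      disease_id = rep(disease_ids, lengths(disease_to_terms)),
      term_id = unlist(disease_to_terms, use.names = FALSE)
    )
    freq$frequency <- sample(freq_levels, nrow(freq), replace = TRUE,
                             prob = freq_weights)

    list(ontology = ontology,
         corpus = new_corpus(gene_to_terms, disease_to_terms, freq))
  })
}

#' The documented six-term toy fixture
#'
#' A pinned miniature: six terms `T:0000000` (root) ... `T:0000005` with
#' edges T1->T0, T2->T0, T3->T1, T4->T1, T5->T2; three genes annotated to
#' the three leaves (g1->T3, g2->T4, g3->T5) and two diseases
#' (D1 -> \{T3, T4\}, D2 -> \{T5\}).  Propagated gene counts are therefore
#' root 3, T1 2, each leaf 1, so e.g. the gene IC of T1 is `ln(3/2)` and the
#' disease IC of T5 is `ln 2`.  All frequencies default to 1.
#'
#' @param definitions Optional named character vector overriding the two-word
#'   definitions of any of T0..T5.
#' @return List with `ontology` and `corpus`.
#' @examples
#' fx <- toy_fixture()
#' most_depth(fx$ontology)
#' @export
toy_fixture <- function(definitions = NULL) {
  ids <- sprintf("T:%07d", 0:5)
  defs <- c("phenotypic abnormality group", "limb abnormality",
            "nervous abnormality", "split hand", "absent limb reflex",
            "nervous tissue atrophy")
  names(defs) <- ids
  if (!is.null(definitions)) defs[names(definitions)] <- definitions
  ontology <- new_ontology(
    terms = tibble::tibble(
      id = ids,
      name = c("root", "limb", "nervous", "split hand", "areflexia",
               "atrophy"),
      definition = unname(defs),
      synonyms = rep(list(character()), 6)
    ),
    edges = tibble::tibble(
      child = ids[c(2, 3, 4, 5, 6)],
      parent = ids[c(1, 1, 2, 2, 3)]
    )
  )
  corpus <- new_corpus(
    gene_to_terms = list(g1 = ids[4], g2 = ids[5], g3 = ids[6]),
    disease_to_terms = list("DB:000001" = ids[c(4, 5)],
                            "DB:000002" = ids[6])
  )
  list(ontology = ontology, corpus = corpus)
}
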