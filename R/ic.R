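#' Propagated annotation counts
#'
#' Counts, for every ontology term, the number of annotation units (genes or
#' diseases) whose term set — closed upward under the true-path rule —
#' contains the term.  The root therefore counts every annotated unit, and a
#' unit annotated to several descendants of a term still counts once.
#'
#' @param ontology A `pheno_ontology`.
#' @param unit_to_terms Named list: unit -> character vector of term ids.
#' @return Named integer vector over all ontology terms.
#' @export
propagated_counts <- function(ontology, unit_to_terms) {
  if (!length(unit_to_terms)) stop("empty annotation corpus", call. = FALSE)
  ids <- ontology$terms$id
  counts <- stats::setNames(integer(length(ids)), ids)
  for (terms in unit_to_terms) {
    closed <- propagate_terms(ontology, terms)
    counts[closed] <- counts[closed] + 1L
  }
  counts
}

# upward closure of a term set (terms plus all their ancestors)
propagate_terms <- function(ontology, terms) {
  terms <- intersect(unique(terms), ontology$terms$id)
  unique(c(terms, unlist(ontology$ancestors[terms], use.names = FALSE)))
}

#' Compute blended gene/disease information content
#'
#' Per-term information content from each annotation source,
#' `IC_source(t) = ln(N / n_t)` where `N` is the number of units annotated to
#' the root (all units, after upward propagation) and `n_t` the number
#' annotated to `t`; the two sources are blended as
#' `IC(t) = w * IC_gene(t) + (1 - w) * IC_disease(t)`.
#'
#' Terms with zero propagated count in a source (no unit annotates them or
#' any descendant) are treated as maximally specific and receive that
#' source's maximum observed finite IC, keeping downstream products finite.
#'
#' @param ontology A `pheno_ontology`.
#' @param corpus A `pheno_corpus`.
#' @param w Weight on the gene source, in \[0,1\]; `w = 1` is gene-only IC,
#'   `w = 0` disease-only.
#' @return An `ic_table`: tibble with columns `term_id`, `ic_gene`,
#'   `ic_disease`, `ic` (natural-log units), with `w` stored as an
#'   attribute.
#' @examples
#' fx <- toy_fixture()
#' compute_ic(fx$ontology, fx$corpus, w = 1)
#' @export
compute_ic <- function(ontology, corpus, w = 0.5) {
  if (!is.numeric(w) || length(w) != 1L || is.na(w) || w < 0 || w > 1)
    stop("`w` must be a single number in [0, 1]", call. = FALSE)
  ic_g <- source_ic(ontology, corpus$gene_to_terms)
  ic_d <- source_ic(ontology, corpus$disease_to_terms)
  out <- tibble::tibble(
    term_id = ontology$terms$id,
    ic_gene = unname(ic_g),
    ic_disease = unname(ic_d),
    ic = w * unname(ic_g) + (1 - w) * unname(ic_d)
  )
  structure(out, w = w, class = c("ic_table", class(out)))
}

source_ic <- function(ontology, unit_to_terms) {
  counts <- propagated_counts(ontology, unit_to_terms)
  total <- counts[[ontology$root]]
  if (total == 0L) stop("no units annotated in this source", call. = FALSE)
  ic <- ifelse(counts > 0, log(total / counts), NA_real_)
  mx <- suppressWarnings(max(ic, na.rm = TRUE))
  if (!is.finite(mx)) mx <- 0
  ic[is.na(ic)] <- mx
  stats::setNames(ic, names(counts))
}

#' Write / read an IC table cache
#'
#' Plain TSV with columns `term_id`, `ic_gene`, `ic_disease`, `ic`; `w` is
#' stored in a comment header line.
#'
#' @param ic An `ic_table`.
#' @param path File path.
#' @return `path` / the re-read `ic_table`.
#' @export
write_ic_cache <- function(ic, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("# w=", format(attr(ic, "w"), digits = 17)), con)
  utils::write.table(as.data.frame(ic), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_ic_cache
#' @export
read_ic_cache <- function(path) {
  first <- readLines(path, n = 1L)
  w <- as.numeric(sub("^# w=", "", first))
  df <- utils::read.delim(path, skip = 1L)
  structure(tibble::as_tibble(df), w = w,
            class = c("ic_table", class(tibble::tibble())))
}
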