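#' Directed PMI-weighted best-match set similarity
#'
#' `Sim_set(T_from -> T_to) = (1/|T_from|) * sum over t_i in T_from of
#' max over t_j in T_to of sim(t_i, t_j) * PMI(t_i, t_j)`: each query term
#' is matched to its best PMI-weighted counterpart and matches are averaged
#' over the query set.
#'
#' @param T_from,T_to Non-empty character vectors of term ids.
#' @param sims Pairwise term-similarity provider: either a numeric matrix
#'   with term ids as dimnames covering both sets, or a function
#'   `f(t_i, t_j)`.
#' @param pmi Pairwise PMI provider in the same two forms; `NULL` disables
#'   PMI weighting (all weights 1).
#' @return A single non-negative number (non-negative in positive PMI mode).
#' @export
directed_set_sim <- function(T_from, T_to, sims, pmi = NULL) {
  if (!length(T_from)) stop("T_from is empty", call. = FALSE)
  if (!length(T_to)) stop("T_to is empty", call. = FALSE)
  s <- provider_matrix(sims, T_from, T_to)
  p <- if (is.null(pmi)) 1 else provider_matrix(pmi, T_from, T_to)
  weighted <- s * p
  mean(apply(weighted, 1L, max))
}

provider_matrix <- function(x, rows, cols) {
  if (is.function(x)) {
    outer(rows, cols, Vectorize(x))
  } else {
    missing_r <- setdiff(rows, rownames(x))
    missing_c <- setdiff(cols, colnames(x))
    if (length(missing_r) || length(missing_c))
      stop("similarity/PMI table lacks term(s): ",
           paste(c(missing_r, missing_c), collapse = ", "), call. = FALSE)
    x[rows, cols, drop = FALSE]
  }
}

#' Symmetric set similarity
#'
#' Averages the two directed scores to remove the dependence on argument
#' order: `Sim_sym(T_p, T_c) = (Sim_set(T_p -> T_c) +
#' Sim_set(T_c -> T_p)) / 2`.
#'
#' @inheritParams directed_set_sim
#' @param T_p,T_c Non-empty term-id sets.
#' @return Tibble with one row: `sim_forward` (`T_p -> T_c`),
#'   `sim_backward`, `sim_sym`.
#' @export
symmetric_set_sim <- function(T_p, T_c, sims, pmi = NULL) {
  fwd <- directed_set_sim(T_p, T_c, sims, pmi)
  bwd <- directed_set_sim(T_c, T_p, sims, pmi)
  tibble::tibble(sim_forward = fwd, sim_backward = bwd,
                 sim_sym = (fwd + bwd) / 2)
}

#' Set similarity through a precomputed index
#'
#' High-level entry point: computes the symmetric PMI-weighted best-match
#' similarity between two phenotype-term sets under a [sim_config()].
#'
#' @param index A [pheno_index()].
#' @param T_p,T_c Non-empty term-id sets.
#' @param config A [sim_config()].
#' @return One-row tibble: `sim_forward`, `sim_backward`, `sim_sym`.
#' @examples
#' fx <- toy_fixture()
#' idx <- pheno_index(fx$ontology, fx$corpus)
#' set_similarity(idx, c("T:0000003", "T:0000004"), c("T:0000001"),
#'                sim_config(pmi_source = "gene"))
#' @export
set_similarity <- function(index, T_p, T_c, config = sim_config()) {
  terms <- unique(c(T_p, T_c))
  check_terms(index$ontology, terms)
  s <- term_sim_matrix(index, terms, terms, config)
  p <- if (config$pmi_mode == "off") NULL else
    pmi_matrix(index$pmi[[config$pmi_source]], terms, terms,
               mode = config$pmi_mode)
  symmetric_set_sim(T_p, T_c, s, p)
}
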