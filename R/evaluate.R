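#' Rank candidate diseases (or genes) for one patient
#'
#' Scores the patient's phenotype set against every candidate's annotation
#' set with the symmetric PMI-weighted best-match similarity and sorts the
#' candidates by descending score.  The true target's rank within ties
#' follows the configured tie policy: pessimistic (maximal rank among the
#' tied block, the default) or mean rank.
#'
#' @param index A [pheno_index()].
#' @param patient_terms Character vector of the patient's term ids.
#' @param candidates Named list: candidate id -> term-id set.  Defaults to
#'   the corpus's disease annotation sets.
#' @param true_target Candidate id of the patient's true disease/gene; must
#'   be among the candidates.
#' @param config A [sim_config()].
#' @param sim_mat,pmi_mat Optional precomputed matrices over all involved
#'   terms (used by [rank_cohort()] to avoid recomputation).
#' @return A `pheno_ranking` tibble: `candidate_id`, `score`, `rank`, with
#'   attributes `true_target` and `true_rank`.
#' @export
rank_candidates <- function(index, patient_terms, true_target,
                            candidates = NULL, config = sim_config(),
                            sim_mat = NULL, pmi_mat = NULL) {
  if (is.null(candidates)) candidates <- index$corpus$disease_to_terms
  if (!true_target %in% names(candidates))
    stop("true target ", true_target, " is not among the candidates",
         call. = FALSE)
  terms <- unique(c(patient_terms, unlist(candidates, use.names = FALSE)))
  check_terms(index$ontology, terms)
  if (is.null(sim_mat))
    sim_mat <- term_sim_matrix(index, terms, terms, config)
  if (is.null(pmi_mat) && config$pmi_mode != "off")
    pmi_mat <- pmi_matrix(index$pmi[[config$pmi_source]], terms, terms,
                          mode = config$pmi_mode)
  scores <- vapply(candidates, function(ct) {
    symmetric_set_sim(patient_terms, ct, sim_mat, pmi_mat)$sim_sym
  }, numeric(1))
  ranks <- score_ranks(scores, config$tie_policy)
  out <- tibble::tibble(candidate_id = names(candidates),
                        score = unname(scores),
                        rank = unname(ranks))
  out <- dplyr::arrange(out, .data$rank, .data$candidate_id)
  structure(out,
            true_target = true_target,
            true_rank = unname(ranks[true_target]),
            tie_policy = config$tie_policy,
            class = c("pheno_ranking", class(out)))
}

score_ranks <- function(scores, tie_policy) {
  method <- switch(tie_policy, pessimistic = "max", mean = "average")
  rank(-scores, ties.method = method)
}

#' @export
print.pheno_ranking <- function(x, ...) {
  cat("<pheno_ranking> true target ", attr(x, "true_target"),
      " at rank ", attr(x, "true_rank"), " of ", nrow(x),
      " (", attr(x, "tie_policy"), " ties)\n", sep = "")
  NextMethod()
}

#' @rdname rank_candidates
#' @param x A `pheno_ranking`.
#' @param ... Unused.
#' @method glance pheno_ranking
#' @export
glance.pheno_ranking <- function(x, ...) {
  tibble::tibble(true_target = attr(x, "true_target"),
                 true_rank = attr(x, "true_rank"),
                 n_candidates = nrow(x),
                 top_candidate = x$candidate_id[1],
                 top_score = x$score[1])
}

#' Rank a whole patient cohort
#'
#' Applies [rank_candidates()] to each row of a patients tibble, sharing one
#' precomputed term-similarity matrix across patients.
#'
#' @param index A [pheno_index()].
#' @param patients Patients tibble ([simulate_optimal()] and friends).
#' @param candidates Named list of candidate term sets (default: disease
#'   annotations of the corpus).
#' @param config A [sim_config()].
#' @return Tibble: `patient_id`, `true_target`, `true_rank`,
#'   `n_candidates`, `top_candidate`, `top_score` (one row per patient).
#' @export
rank_cohort <- function(index, patients, candidates = NULL,
                        config = sim_config()) {
  if (is.null(candidates)) candidates <- index$corpus$disease_to_terms
  terms <- unique(c(unlist(patients$terms, use.names = FALSE),
                    unlist(candidates, use.names = FALSE)))
  check_terms(index$ontology, terms)
  sim_mat <- term_sim_matrix(index, terms, terms, config)
  pmi_mat <- if (config$pmi_mode == "off") NULL else
    pmi_matrix(index$pmi[[config$pmi_source]], terms, terms,
               mode = config$pmi_mode)
  res <- purrr::map2(patients$terms, patients$true_target, function(tt, tgt) {
    r <- rank_candidates(index, tt, tgt, candidates, config,
                         sim_mat = sim_mat, pmi_mat = pmi_mat)
    glance(r)
  })
  out <- dplyr::bind_cols(
    tibble::tibble(patient_id = patients$patient_id),
    dplyr::bind_rows(res)
  )
  if ("type" %in% names(patients)) out$type <- patients$type
  out
}

#' Cumulative rank distribution
#'
#' The fraction of patients whose true target ranks at or above each
#' threshold `k` — the standard curve for phenotype-driven disease
#' prioritisation benchmarks.  Non-decreasing in `k` and equal to 1 at the
#' maximum possible rank.
#'
#' @param results Data frame with a `true_rank` column ([rank_cohort()]).
#' @param ks Integer thresholds.
#' @return A `cumulative_rank` tibble: `k`, `fraction`.
#' @export
cumulative_rank <- function(results, ks = c(1, 3, 5, 10)) {
  if (!nrow(results)) stop("no ranking results", call. = FALSE)
  out <- tibble::tibble(
    k = as.integer(ks),
    fraction = vapply(ks, function(k) mean(results$true_rank <= k),
                      numeric(1))
  )
  structure(out, class = c("cumulative_rank", class(out)))
}

#' Overlap of top-k pairs across similarity tables
#'
#' Given several named pairwise-similarity tables over the same entities
#' (columns `id_a`, `id_b`, and a score column), extracts each table's top-k
#' unordered pairs and reports the cardinality of every subset intersection
#' — the numeric content of a Venn diagram.
#'
#' @param tables Named list of data frames with columns `id_a`, `id_b` and
#'   `score` (or `sim_sym`).
#' @param k Number of top pairs per table; must not exceed any table size.
#' @return List with `top` (named list of pair-key character vectors) and
#'   `intersections` (tibble `tables`, `n_tables`, `size`).
#' @export
top_pairs_overlap <- function(tables, k) {
  stopifnot(is.list(tables), !is.null(names(tables)), length(tables) >= 2)
  top <- purrr::map(tables, function(df) {
    score_col <- if ("score" %in% names(df)) "score" else "sim_sym"
    key <- purrr::map2_chr(df$id_a, df$id_b,
                           ~paste(sort(c(.x, .y)), collapse = "|"))
    df <- tibble::tibble(key = key, score = df[[score_col]])
    df <- df[!duplicated(df$key), , drop = FALSE]
    if (k > nrow(df))
      stop("k = ", k, " exceeds table size ", nrow(df), call. = FALSE)
    df <- df[order(-df$score, df$key), , drop = FALSE]
    df$key[seq_len(k)]
  })
  nm <- names(tables)
  combos <- unlist(lapply(seq_along(nm), function(m)
    utils::combn(nm, m, simplify = FALSE)), recursive = FALSE)
  inter <- purrr::map(combos, function(cc)
    tibble::tibble(tables = paste(cc, collapse = "&"),
                   n_tables = length(cc),
                   size = length(Reduce(intersect, top[cc]))))
  list(top = top, intersections = dplyr::bind_rows(inter))
}

#' Sweep the gene/disease IC blending weight
#'
#' Re-ranks a cohort at each value of `w`, returning per-patient candidate
#' scores so downstream code can study how rankings move with the blend
#' (e.g. rank correlation between adjacent `w` values) plus the cumulative
#' rank curve per `w`.  At `w = 1` the measure uses gene-only IC, at `w = 0`
#' disease-only.
#'
#' @param index A [pheno_index()].
#' @param patients Patients tibble.
#' @param ws Weight grid in \[0,1\].
#' @param config Base [sim_config()]; its `w` is overridden.
#' @param ks Thresholds for the per-w cumulative curve.
#' @return A `w_sweep` list: `scores` (tibble `w`, `patient_id`,
#'   `candidate_id`, `score`, `true_rank`) and `curves` (tibble `w`, `k`,
#'   `fraction`).
#' @export
sweep_w <- function(index, patients, ws = seq(0, 1, by = 0.1),
                    config = sim_config(), ks = c(1, 3, 5, 10)) {
  candidates <- index$corpus$disease_to_terms
  terms <- unique(c(unlist(patients$terms, use.names = FALSE),
                    unlist(candidates, use.names = FALSE)))
  pmi_mat <- if (config$pmi_mode == "off") NULL else
    pmi_matrix(index$pmi[[config$pmi_source]], terms, terms,
               mode = config$pmi_mode)
  all_scores <- list(); all_curves <- list()
  for (w in ws) {
    cfg <- config; cfg$w <- w
    sim_mat <- term_sim_matrix(index, terms, terms, cfg)
    rows <- purrr::map2(patients$terms, patients$true_target,
                        function(tt, tgt) {
      r <- rank_candidates(index, tt, tgt, candidates, cfg,
                           sim_mat = sim_mat, pmi_mat = pmi_mat)
      tibble::tibble(candidate_id = r$candidate_id, score = r$score,
                     true_rank = attr(r, "true_rank"))
    })
    sc <- dplyr::bind_rows(rows, .id = "row")
    sc$patient_id <- patients$patient_id[as.integer(sc$row)]
    sc$row <- NULL
    sc$w <- w
    all_scores[[length(all_scores) + 1L]] <- sc
    tr <- dplyr::distinct(sc[, c("patient_id", "true_rank", "w")])
    cv <- cumulative_rank(tr, ks)
    cv$w <- w
    all_curves[[length(all_curves) + 1L]] <- cv
  }
  structure(list(scores = dplyr::bind_rows(all_scores),
                 curves = tibble::as_tibble(dplyr::bind_rows(all_curves))),
            class = "w_sweep")
}
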