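#' Simulate optimal patients from a disease's annotations
#'
#' Each simulated patient carries each phenotype annotated to the disease
#' independently with probability equal to the phenotype's frequency
#' (penetrance); pairs absent from the frequency table count as 1.  Patients
#' drawn with zero phenotypes are redrawn (up to `max_retries`, then an
#' error).  Deterministic given `seed`.
#'
#' @param corpus A `pheno_corpus`.
#' @param disease A disease id present in the corpus.
#' @param n Number of patients.
#' @param seed Integer seed.
#' @param max_retries Redraw budget per patient for empty draws.
#' @return A patients tibble: `patient_id`, `true_target`, `terms` (list
#'   column), `provenance` (list column, parallel to `terms`), `seed`.
#' @export
simulate_optimal <- function(corpus, disease, n, seed, max_retries = 100L) {
  freqs <- disease_frequencies(corpus, disease) # errors on unknown disease
  withr::with_seed(as_seed(seed), {
    rows <- purrr::map(seq_len(n), function(k) {
      for (try in seq_len(max_retries)) {
        keep <- stats::runif(length(freqs)) <= freqs
        if (any(keep)) {
          terms <- names(freqs)[keep]
          return(list(terms = terms,
                      provenance = rep("optimal", length(terms))))
        }
      }
      stop("could not draw a non-empty phenotype set for ", disease,
           " after ", max_retries, " attempts (all frequencies ~0?)",
           call. = FALSE)
    })
    tibble::tibble(
      patient_id = sprintf("%s_opt_%03d", disease, seq_len(n)),
      true_target = disease,
      terms = purrr::map(rows, "terms"),
      provenance = purrr::map(rows, "provenance"),
      seed = seed
    )
  })
}

#' Add noise phenotypes to simulated patients
#'
#' Adds, per patient, `n_noise` distinct terms drawn uniformly from the
#' ontology terms NOT in the propagated annotation set of the patient's true
#' target (so a noise term is never an annotated phenotype of the disease,
#' nor an ancestor of one).  By default `n_noise` is half the number of
#' non-noise terms the patient carries, rounded up.
#'
#' @param patients A patients tibble (see [simulate_optimal()]).
#' @param ontology A `pheno_ontology`.
#' @param corpus A `pheno_corpus` (provides the true target's annotations).
#' @param seed Integer seed.
#' @param n_noise Optional fixed noise count per patient.
#' @return The patients tibble with noise terms appended and tagged.
#' @export
add_noise <- function(patients, ontology, corpus, seed, n_noise = NULL) {
  withr::with_seed(as_seed(seed), {
    patients$terms <- as.list(patients$terms)
    patients$provenance <- as.list(patients$provenance)
    for (i in seq_len(nrow(patients))) {
      target <- patients$true_target[i]
      assoc <- propagate_terms(ontology, corpus$disease_to_terms[[target]])
      pool <- setdiff(ontology$terms$id, c(assoc, patients$terms[[i]]))
      k <- if (is.null(n_noise))
        ceiling(sum(patients$provenance[[i]] != "noise") / 2)
      else n_noise
      if (length(pool) < k)
        stop("only ", length(pool), " non-associated terms available, ",
             k, " noise terms requested", call. = FALSE)
      noise <- sample(pool, k)
      patients$terms[[i]] <- c(patients$terms[[i]], noise)
      patients$provenance[[i]] <- c(patients$provenance[[i]],
                                    rep("noise", k))
    }
    patients
  })
}

#' Replace half of the optimal phenotypes by ancestors, then add noise
#'
#' Models imprecise clinical coding: half of each patient's optimal terms
#' (rounded down) are replaced by a uniformly drawn proper ancestor (the
#' root excluded — it carries no information).  A term whose only ancestor
#' is the root is resampled from the remaining optimal terms; if no eligible
#' term remains the replacement is skipped.  Afterwards, noise terms are
#' added, half the size of the post-replacement set (rounded up), drawn as
#' in [add_noise()].
#'
#' @inheritParams add_noise
#' @param add_noise_terms Set `FALSE` to skip the noise step.
#' @return The patients tibble with `imprecise` (and `noise`) tags.
#' @export
add_imprecision <- function(patients, ontology, corpus, seed,
                            add_noise_terms = TRUE) {
  seed <- as_seed(seed)
  patients <- withr::with_seed(seed, {
    patients$terms <- as.list(patients$terms)
    patients$provenance <- as.list(patients$provenance)
    for (i in seq_len(nrow(patients))) {
      terms <- patients$terms[[i]]
      prov <- patients$provenance[[i]]
      opt_idx <- which(prov == "optimal")
      n_replace <- floor(length(opt_idx) / 2)
      if (n_replace == 0L) next
      candidates <- sample(opt_idx)
      replaced <- 0L
      for (j in candidates) {
        if (replaced >= n_replace) break
        anc <- setdiff(ontology$ancestors[[terms[j]]],
                       c(ontology$root, terms))
        if (!length(anc)) next # only the root above it; try another term
        terms[j] <- if (length(anc) == 1L) anc else sample(anc, 1L)
        prov[j] <- "imprecise"
        replaced <- replaced + 1L
      }
      if (replaced < n_replace)
        message("patient ", patients$patient_id[i], ": only ", replaced,
                " of ", n_replace, " imprecision replacements possible")
      patients$terms[[i]] <- terms
      patients$provenance[[i]] <- prov
    }
    patients
  })
  if (add_noise_terms)
    patients <- add_noise(patients, ontology, corpus, seed = seed + 1L)
  patients
}

#' Simulate a mixed patient cohort
#'
#' Draws `n` patients whose true diseases cycle through `diseases`, split
#' between profile types.  The default composition gives optimal, noisy and
#' noisy-and-imprecise patients one third each.
#'
#' @param corpus,ontology Corpus and ontology.
#' @param n Total number of patients.
#' @param diseases Disease ids to simulate from (default: all in corpus).
#' @param composition Named numeric proportions over
#'   `c("optimal", "noisy", "noisy_imprecise")`; needs not sum to 1.
#' @param seed Integer seed.
#' @return Patients tibble with an extra `type` column.
#' @export
simulate_cohort <- function(corpus, ontology, n,
                            diseases = NULL,
                            composition = c(optimal = 1, noisy = 1,
                                            noisy_imprecise = 1),
                            seed = 1L) {
  seed <- as_seed(seed)
  if (is.null(diseases)) diseases <- names(corpus$disease_to_terms)
  comp <- composition / sum(composition)
  n_type <- stats::setNames(floor(n * comp), names(comp))
  rem <- n - sum(n_type)
  if (rem > 0) n_type[seq_len(rem)] <- n_type[seq_len(rem)] + 1L
  out <- list()
  offset <- 0L
  for (type in names(n_type)) {
    nt <- n_type[[type]]
    if (nt == 0L) next
    ds <- diseases[((offset + seq_len(nt) - 1L) %% length(diseases)) + 1L]
    per <- table(ds)
    batch <- purrr::imap(as.list(per), function(cnt, d) {
      p <- simulate_optimal(corpus, d, cnt,
                            seed = seed + offset + match(d, diseases))
      if (type == "noisy")
        p <- add_noise(p, ontology, corpus,
                       seed = seed + offset + match(d, diseases) + 7919L)
      if (type == "noisy_imprecise")
        p <- add_imprecision(p, ontology, corpus,
                             seed = seed + offset + match(d, diseases) +
                               15013L)
      p
    })
    batch <- dplyr::bind_rows(batch)
    batch$type <- type
    batch$patient_id <- sprintf("P%04d_%s", offset + seq_len(nrow(batch)),
                                type)
    out[[type]] <- batch
    offset <- offset + nt
  }
  dplyr::bind_rows(out)
}

# seeds passed around must stay valid 32-bit integers
as_seed <- function(seed) {
  s <- as.integer(seed %% .Machine$integer.max)
  if (is.na(s)) stop("invalid seed", call. = FALSE)
  s
}

#' Write / read a patients file
#'
#' One row per patient: `patient_id`, `true_target`, comma-separated term
#' ids.  Provenance tags go to a sidecar TSV (`<path>.provenance.tsv`) with
#' one row per (patient, term).
#'
#' @param patients Patients tibble.
#' @param path Output TSV path.
#' @return `path` / the re-read patients tibble.
#' @export
write_patients <- function(patients, path) {
  df <- tibble::tibble(
    patient_id = patients$patient_id,
    true_target = patients$true_target,
    terms = vapply(patients$terms, paste, character(1), collapse = ",")
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- tibble::tibble(
    patient_id = rep(patients$patient_id, lengths(patients$terms)),
    term_id = unlist(patients$terms, use.names = FALSE),
    provenance = unlist(patients$provenance, use.names = FALSE)
  )
  utils::write.table(side, paste0(path, ".provenance.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_patients
#' @export
read_patients <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  out <- tibble::tibble(
    patient_id = df$patient_id,
    true_target = df$true_target,
    terms = strsplit(df$terms, ",", fixed = TRUE)
  )
  side_path <- paste0(path, ".provenance.tsv")
  if (file.exists(side_path)) {
    side <- utils::read.delim(side_path, colClasses = "character")
    prov <- split(side$provenance, factor(side$patient_id,
                                          levels = out$patient_id))
    out$provenance <- unname(prov)
  } else {
    out$provenance <- purrr::map(out$terms, ~rep("optimal", length(.x)))
  }
  out
}
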