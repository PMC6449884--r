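freq_corpus <- function(terms, freqs, ontology) {
  new_corpus(
    gene_to_terms = list(g1 = terms[1]),
    disease_to_terms = list(D1 = terms),
    frequency = tibble::tibble(disease_id = "D1", term_id = terms,
                               frequency = freqs))
}

test_that("penetrance 1 gives the full annotation set; 0 errors out", {
  fx <- toy_fixture()
  p <- simulate_optimal(fx$corpus, "DB:000001", n = 5, seed = 1)
  expect_equal(nrow(p), 5L)
  for (i in 1:5) expect_setequal(p$terms[[i]], toy_ids[4:5])
  expect_true(all(unlist(p$provenance) == "optimal"))

  zero <- freq_corpus(toy_ids[4:5], c(0, 0), fx$ontology)
  expect_error(simulate_optimal(zero, "D1", n = 1, seed = 1), "attempts")
  expect_error(simulate_optimal(fx$corpus, "NOPE", 1, 1), "unknown disease")
})

test_that("optimal draws follow the per-term penetrance (binomial check)", {
  fx <- make_fixture(n_terms = 30, n_genes = 5, n_diseases = 3, depth = 3,
                     vocab_size = 20, seed = 51)
  terms <- fx$corpus$disease_to_terms[[1]][1:6]
  stopifnot(length(terms) == 6)
  corpus <- freq_corpus(terms, rep(0.5, 6), fx$ontology)
  n <- 2000
  p <- simulate_optimal(corpus, "D1", n = n, seed = 99)
  sizes <- lengths(p$terms)
  # zero-truncated Binomial(6, 0.5): mean = 3 / (1 - 0.5^6)
  mu <- 3 / (1 - 0.5^6)
  v <- (3 * 0.5 + 9) / (1 - 0.5^6) - mu^2 # E[X^2|X>0] - mu^2
  se <- sqrt(v / n)
  expect_lt(abs(mean(sizes) - mu), 3 * se)
  expect_true(all(sizes >= 1))
})

test_that("simulation is a pure function of its seed", {
  fx <- make_fixture(n_terms = 60, n_genes = 10, n_diseases = 6, depth = 4,
                     vocab_size = 40, seed = 53)
  d <- names(fx$corpus$disease_to_terms)[1]
  a <- simulate_optimal(fx$corpus, d, 10, seed = 7)
  b <- simulate_optimal(fx$corpus, d, 10, seed = 7)
  expect_identical(a, b)
  na <- add_noise(a, fx$ontology, fx$corpus, seed = 8)
  nb <- add_noise(b, fx$ontology, fx$corpus, seed = 8)
  expect_identical(na, nb)
  ia <- add_imprecision(a, fx$ontology, fx$corpus, seed = 9)
  ib <- add_imprecision(b, fx$ontology, fx$corpus, seed = 9)
  expect_identical(ia, ib)
  expect_false(identical(na, add_noise(a, fx$ontology, fx$corpus, seed = 10)))
})

test_that("noise adds ceil(n/2) terms never associated with the disease", {
  fx <- make_fixture(n_terms = 80, n_genes = 10, n_diseases = 8, depth = 5,
                     vocab_size = 40, seed = 57)
  d <- names(fx$corpus$disease_to_terms)[2]
  assoc <- unique(c(
    fx$corpus$disease_to_terms[[d]],
    unlist(term_ancestors(fx$ontology, fx$corpus$disease_to_terms[[d]]))))
  for (seed in 1:25) {
    p <- simulate_optimal(fx$corpus, d, 1, seed = seed)
    n_opt <- length(p$terms[[1]])
    noisy <- add_noise(p, fx$ontology, fx$corpus, seed = seed + 1000)
    noise_terms <- noisy$terms[[1]][noisy$provenance[[1]] == "noise"]
    expect_length(noise_terms, ceiling(n_opt / 2))
    expect_length(noisy$terms[[1]], n_opt + ceiling(n_opt / 2))
    expect_length(intersect(noise_terms, assoc), 0L)
    expect_false(anyDuplicated(noisy$terms[[1]]) > 0)
  }
})

test_that("4 optimal terms gain exactly 2 noise terms", {
  fx <- toy_fixture()
  ont4 <- make_fixture(n_terms = 20, n_genes = 3, n_diseases = 2, depth = 3,
                       vocab_size = 15, seed = 61)
  d <- names(ont4$corpus$disease_to_terms)[1]
  terms4 <- ont4$corpus$disease_to_terms[[d]][1:4]
  corpus <- new_corpus(list(g1 = terms4[1]), stats::setNames(list(terms4), d))
  p <- simulate_optimal(corpus, d, 1, seed = 3)
  expect_length(p$terms[[1]], 4L)
  noisy <- add_noise(p, ont4$ontology, corpus, seed = 4)
  expect_length(noisy$terms[[1]], 6L)
})

test_that("imprecision replaces floor(n/2) terms by proper ancestors", {
  fx <- make_fixture(n_terms = 80, n_genes = 10, n_diseases = 8, depth = 5,
                     vocab_size = 40, seed = 63)
  d <- names(fx$corpus$disease_to_terms)[3]
  for (seed in 1:15) {
    p <- simulate_optimal(fx$corpus, d, 1, seed = seed)
    opt_terms <- p$terms[[1]]
    imp <- add_imprecision(p, fx$ontology, fx$corpus, seed = seed + 500,
                           add_noise_terms = FALSE)
    prov <- imp$provenance[[1]]
    replaced <- which(prov == "imprecise")
    # every imprecise term is a proper non-root ancestor of the optimal
    # term it replaced (positions are preserved)
    for (j in replaced) {
      anc <- term_ancestors(fx$ontology, opt_terms[j])
      expect_true(imp$terms[[1]][j] %in% setdiff(anc, fx$ontology$root))
    }
    # replacement count: floor(n/2) unless blocked by root-only ancestors
    only_root <- vapply(opt_terms, function(t)
      length(setdiff(term_ancestors(fx$ontology, t),
                     fx$ontology$root)) == 0, logical(1))
    expect_lte(length(replaced), floor(length(opt_terms) / 2))
    if (!any(only_root))
      expect_length(replaced, floor(length(opt_terms) / 2))
  }
})

test_that("noisy-and-imprecise patients get half-of-set noise terms", {
  fx <- make_fixture(n_terms = 100, n_genes = 10, n_diseases = 8, depth = 5,
                     vocab_size = 40, seed = 67)
  d <- names(fx$corpus$disease_to_terms)[1]
  p <- simulate_optimal(fx$corpus, d, 4, seed = 11)
  imp <- add_imprecision(p, fx$ontology, fx$corpus, seed = 12)
  for (i in seq_len(nrow(imp))) {
    prov <- imp$provenance[[i]]
    n_core <- sum(prov != "noise")
    expect_equal(sum(prov == "noise"), ceiling(n_core / 2))
    expect_equal(n_core, length(p$terms[[i]])) # replacement preserves size
    # provenance partitions the term set
    expect_length(prov, length(imp$terms[[i]]))
    expect_true(all(prov %in% c("optimal", "imprecise", "noise")))
  }
})

test_that("the forced toy replacement picks the only non-root ancestor", {
  fx <- toy_fixture()
  p <- tibble::tibble(patient_id = "p1", true_target = "DB:000001",
                      terms = list(toy_ids[4:5]),
                      provenance = list(rep("optimal", 2)), seed = 1L)
  imp <- add_imprecision(p, fx$ontology, fx$corpus, seed = 2,
                         add_noise_terms = FALSE)
  j <- which(imp$provenance[[1]] == "imprecise")
  expect_length(j, 1L)
  expect_equal(imp$terms[[1]][j], toy_ids[2]) # T1, the only choice
})

test_that("cohorts mix types in the requested composition", {
  fx <- make_fixture(n_terms = 80, n_genes = 12, n_diseases = 6, depth = 4,
                     vocab_size = 40, seed = 71)
  cohort <- simulate_cohort(fx$corpus, fx$ontology, n = 30, seed = 5)
  expect_equal(nrow(cohort), 30L)
  expect_equal(as.integer(table(cohort$type)[c("optimal", "noisy",
                                               "noisy_imprecise")]),
               c(10L, 10L, 10L))
  expect_identical(cohort,
                   simulate_cohort(fx$corpus, fx$ontology, n = 30, seed = 5))
})

test_that("patients round-trip through the TSV files", {
  fx <- make_fixture(n_terms = 60, n_genes = 10, n_diseases = 5, depth = 4,
                     vocab_size = 30, seed = 73)
  cohort <- simulate_cohort(fx$corpus, fx$ontology, n = 9, seed = 6)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_patients(cohort, path)
  re <- read_patients(path)
  expect_equal(re$patient_id, cohort$patient_id)
  expect_equal(re$terms, unname(cohort$terms))
  expect_equal(re$provenance, unname(as.list(cohort$provenance)))
})
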