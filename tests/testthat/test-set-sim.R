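# flat (unstructured) ontology over given leaf terms plus a root, so PMI
# probabilities reduce to the raw containment fractions of the unit sets
flat_ontology <- function(leaves) {
  ids <- c("F:0000000", leaves)
  new_ontology(
    terms = tibble::tibble(id = ids, name = ids, definition = "",
                           synonyms = rep(list(character()), length(ids))),
    edges = tibble::tibble(child = leaves, parent = "F:0000000"))
}

test_that("PMI is 0 under exact independence and at saturation", {
  ont <- flat_ontology(c("F:0000001", "F:0000002"))
  a <- "F:0000001"; b <- "F:0000002"
  # p(a) = p(b) = 1/2, p(a,b) = 1/4 -> PMI = ln 1 = 0
  corpus <- new_corpus(
    gene_to_terms = list(g1 = c(a, b), g2 = a, g3 = b, g4 = character()),
    disease_to_terms = list(d1 = a))
  pmi <- build_pmi(corpus, ont, source = "gene")
  expect_equal(pmi_value(pmi, a, b, mode = "raw"), 0, tolerance = 1e-12)
  # saturated co-occurrence: PMI(a,b) = ln(1/(1*1)) = 0, PMI(a,a) = -ln 1 = 0
  corpus2 <- new_corpus(gene_to_terms = list(g1 = c(a, b), g2 = c(a, b)),
                        disease_to_terms = list(d1 = a))
  pmi2 <- build_pmi(corpus2, ont, source = "gene")
  expect_equal(pmi_value(pmi2, a, b, mode = "raw"), 0)
  expect_equal(pmi_value(pmi2, a, a, mode = "raw"), 0)
})

test_that("the printed four-unit example gives raw PMI ln(8/9)", {
  ont <- flat_ontology(c("F:0000001", "F:0000002"))
  a <- "F:0000001"; b <- "F:0000002"
  corpus <- new_corpus(
    gene_to_terms = list(g1 = c(a, b), g2 = c(a, b), g3 = a, g4 = b),
    disease_to_terms = list(d1 = a))
  pmi <- build_pmi(corpus, ont, source = "gene")
  expect_equal(pmi_value(pmi, a, b, mode = "raw"), log(8 / 9),
               tolerance = 1e-12)
  expect_equal(pmi_value(pmi, a, b, mode = "positive"), 0)
  # PMI(t,t) = -ln p(t) with p(a) = 3/4
  expect_equal(pmi_value(pmi, a, a, mode = "raw"), -log(3 / 4),
               tolerance = 1e-12)
})

test_that("never-co-annotated pairs get PMI 0, not -Inf", {
  ont <- flat_ontology(c("F:0000001", "F:0000002", "F:0000003"))
  corpus <- new_corpus(
    gene_to_terms = list(g1 = "F:0000001", g2 = "F:0000002"),
    disease_to_terms = list(d1 = "F:0000001"))
  pmi <- build_pmi(corpus, ont, source = "gene")
  expect_equal(pmi_value(pmi, "F:0000001", "F:0000002", "raw"), 0)
  # a term absent from the corpus entirely is also 0
  expect_equal(pmi_value(pmi, "F:0000001", "F:0000003", "raw"), 0)
  expect_error(build_pmi(new_corpus(list(), list(d1 = "F:0000001")),
                         ont, source = "gene"), "empty")
})

test_that("PMI uses propagated term sets and symmetric pair counts", {
  fx <- toy_fixture()
  pmi <- build_pmi(fx$corpus, fx$ontology, source = "gene")
  # g1 -> T3 propagates to T1: joint(T3, T1) = 1 of 3 units
  m <- pmi_matrix(pmi, toy_ids, toy_ids, mode = "raw")
  expect_equal(m, t(m), tolerance = 1e-12)
  # p(T3,T1) = 1/3, p(T3) = 1/3, p(T1) = 2/3 -> PMI = ln(3/2)
  expect_equal(m[toy_ids[4], toy_ids[2]], log(3 / 2), tolerance = 1e-12)
})

test_that("pair probability never exceeds either marginal", {
  fx <- make_fixture(n_terms = 60, n_genes = 15, n_diseases = 10, depth = 4,
                     vocab_size = 40, seed = 23)
  for (src in c("gene", "disease", "union")) {
    pmi <- build_pmi(fx$corpus, fx$ontology, source = src)
    pc <- as.matrix(pmi$pair_count)
    marg <- pmi$term_count[colnames(pc)]
    expect_true(all(pc <= pmin(outer(marg, marg, pmin)) + 1e-12))
    expect_equal(pc, t(pc))
  }
})

test_that("directed set similarity is the best-match average", {
  fx <- toy_fixture()
  idx <- pheno_index(fx$ontology, fx$corpus)
  cfg <- sim_config(pmi_source = "gene")
  s <- term_sim_matrix(idx, config = cfg)
  p <- pmi_matrix(idx$pmi$gene, rownames(s), colnames(s), "positive")
  # single-element identity: sim(t,t) * PMI(t,t) = IC(t) * (-ln p(t))
  t3 <- toy_ids[4]
  ic <- index_ic(idx, cfg)
  expect_equal(directed_set_sim(t3, t3, s, p),
               ic[[t3]] * (-log(1 / 3)), tolerance = 1e-12)
  # all cross-pairs unreachable -> 0
  expect_equal(directed_set_sim(toy_ids[4], toy_ids[5], s, p), 0)
  # empty sets are named errors
  expect_error(directed_set_sim(character(), t3, s, p), "T_from")
  expect_error(directed_set_sim(t3, character(), s, p), "T_to")
})

test_that("directed set similarity matches the naive double loop", {
  fx <- make_fixture(n_terms = 50, n_genes = 12, n_diseases = 8, depth = 4,
                     vocab_size = 40, seed = 29)
  idx <- pheno_index(fx$ontology, fx$corpus)
  cfg <- sim_config(pmi_source = "disease")
  ids <- fx$ontology$terms$id
  s <- term_sim_matrix(idx, config = cfg)
  p <- pmi_matrix(idx$pmi$disease, ids, ids, "positive")
  set.seed(31)
  for (rep in 1:10) {
    A <- sample(ids, sample(2:5, 1))
    B <- sample(ids, sample(2:5, 1))
    expect_equal(
      directed_set_sim(A, B, s, p),
      brute_directed_set_sim(A, B, function(a, b) s[a, b],
                             function(a, b) p[a, b]),
      tolerance = 1e-12)
  }
})

test_that("symmetric similarity averages both directions and is symmetric", {
  fx <- make_fixture(n_terms = 50, n_genes = 12, n_diseases = 8, depth = 4,
                     vocab_size = 40, seed = 37)
  idx <- pheno_index(fx$ontology, fx$corpus)
  ids <- fx$ontology$terms$id
  cfg <- sim_config()
  set.seed(41)
  for (rep in 1:8) {
    A <- sample(ids, sample(1:5, 1))
    B <- sample(ids, sample(1:5, 1))
    ab <- set_similarity(idx, A, B, cfg)
    ba <- set_similarity(idx, B, A, cfg)
    expect_equal(ab$sim_sym, (ab$sim_forward + ab$sim_backward) / 2,
                 tolerance = 1e-12)
    expect_equal(ab$sim_forward, ba$sim_backward, tolerance = 1e-12)
    expect_equal(ab$sim_sym, ba$sim_sym, tolerance = 1e-12)
  }
  # T_p = T_c: both directions coincide
  self <- set_similarity(idx, ids[2:4], ids[2:4], cfg)
  expect_equal(self$sim_forward, self$sim_backward, tolerance = 1e-12)
})

test_that("PMI off reduces to a plain symmetric best-match average", {
  fx <- make_fixture(n_terms = 40, n_genes = 10, n_diseases = 6, depth = 4,
                     vocab_size = 30, seed = 43)
  idx <- pheno_index(fx$ontology, fx$corpus)
  cfg <- sim_config(pmi_mode = "off")
  ids <- fx$ontology$terms$id
  s <- term_sim_matrix(idx, config = cfg)
  set.seed(47)
  A <- sample(ids, 4); B <- sample(ids, 3)
  got <- set_similarity(idx, A, B, cfg)
  fwd <- mean(apply(s[A, B, drop = FALSE], 1, max))
  bwd <- mean(apply(s[B, A, drop = FALSE], 1, max))
  expect_equal(got$sim_sym, (fwd + bwd) / 2, tolerance = 1e-12)
  # positive mode keeps all set scores non-negative
  cfg2 <- sim_config(pmi_mode = "positive")
  got2 <- set_similarity(idx, A, B, cfg2)
  expect_true(all(unlist(got2) >= 0))
})
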