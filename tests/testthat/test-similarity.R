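test_that("semantic profiles follow the decay recursion", {
  # chain root -> a -> d
  p <- semantic_profile(chain_dag(c("root", "a", "d")))
  expect_equal(p$contribution, c(root = 0.25, a = 0.5, d = 1))
  expect_equal(p$semantic_value, 1.75)

  # singleton
  p1 <- semantic_profile(disease_dag("d", "d", matrix(character(0), ncol = 2)))
  expect_equal(p1$contribution, c(d = 1))
  expect_equal(p1$semantic_value, 1)

  # diamond: two paths of equal length resolve by max to the same value
  dg <- disease_dag("d", c("root", "a", "b", "d"),
                    rbind(c("root", "a"), c("root", "b"),
                          c("a", "d"), c("b", "d")))
  pd <- semantic_profile(dg)
  expect_equal(pd$contribution[["root"]], 0.25)
  expect_equal(pd$semantic_value, 2.25)

  # multi-position union DAG: max over children picks the shorter path
  dm <- disease_dag("d", c("r", "x", "d"),
                    rbind(c("r", "x"), c("x", "d"), c("r", "d")))
  pm <- semantic_profile(dm)
  expect_equal(pm$contribution[["r"]], 0.5)

  # non-default decay
  p9 <- semantic_profile(chain_dag(c("root", "d")), decay = 0.9)
  expect_equal(p9$contribution[["root"]], 0.9)
})

test_that("malformed DAGs are rejected", {
  expect_error(disease_dag("d", c("a", "d"),
                           rbind(c("a", "d"), c("d", "a"))), "cycle")
  expect_error(disease_dag("d", "x", matrix(character(0), ncol = 2)),
               "not among the DAG nodes")
  # node with no path down to the disease
  orphan <- disease_dag("d", c("root", "stray", "d"), rbind(c("root", "d")))
  expect_error(semantic_profile(orphan), "no path")
})

test_that("pairwise disease similarity matches hand-derived values", {
  sib <- sibling_dags()
  pa <- semantic_profile(sib$A); pb <- semantic_profile(sib$B)
  expect_equal(disease_similarity(pa, pa), 1)
  expect_equal(disease_similarity(pa, pb), 1 / 3)
  # disjoint node sets
  pc <- semantic_profile(chain_dag(c("other", "C")))
  expect_equal(disease_similarity(pa, pc), 0)
})

test_that("similarity is bounded, reflexive, and grows with shared ancestry", {
  set.seed(11)
  for (rep in 1:20) {
    depth_i <- sample(1:4, 1); depth_j <- sample(1:4, 1)
    shared <- sprintf("S%d", seq_len(sample(0:3, 1)))
    di <- chain_dag(c(shared, sprintf("I%d", seq_len(depth_i)), "di"))
    dj <- chain_dag(c(shared, sprintf("J%d", seq_len(depth_j)), "dj"))
    s <- disease_similarity(semantic_profile(di), semantic_profile(dj))
    expect_gte(s, 0); expect_lte(s, 1)
    # prepending one more shared ancestor never decreases similarity
    di2 <- chain_dag(c("S0", shared, sprintf("I%d", seq_len(depth_i)), "di"))
    dj2 <- chain_dag(c("S0", shared, sprintf("J%d", seq_len(depth_j)), "dj"))
    s2 <- disease_similarity(semantic_profile(di2), semantic_profile(dj2))
    expect_gte(s2, s - 1e-12)
  }
})

test_that("group similarity is the best match over the group", {
  sib <- sibling_dags()
  iso <- disease_dag("C", "C", matrix(character(0), ncol = 2))
  W <- build_disease_similarity(c(sib, list(iso)))
  expect_equal(disease_group_similarity("A", c("A", "B"), W), 1)
  expect_equal(disease_group_similarity("A", "B", W), 1 / 3)
  expect_equal(disease_group_similarity("A", c("B", "C"), W), 1 / 3)
  expect_error(disease_group_similarity("A", character(0), W), "empty")
  expect_error(disease_group_similarity("A", "nope", W), "nope")
})

test_that("the disease similarity matrix is symmetric with unit diagonal", {
  sib <- sibling_dags()
  iso <- disease_dag("C", "C", matrix(character(0), ncol = 2))
  W <- build_disease_similarity(c(sib, list(iso)))
  expect_equal(dim(W), c(3L, 3L))
  expect_identical(W, t(W))
  expect_equal(unname(diag(W)), rep(1, 3))
  expect_equal(W["A", "B"], 1 / 3)
  expect_equal(W["A", "C"], 0)
  expect_equal(W["B", "C"], 0)
  expect_silent(check_similarity_matrix(W))

  one <- build_disease_similarity(list(iso))
  expect_equal(unname(one), matrix(1))
  expect_error(build_disease_similarity(c(sib, sib)), "duplicate")
})

test_that("miRNA functional similarity reproduces hand-derived values", {
  sib <- sibling_dags()
  W_d <- build_disease_similarity(sib)  # W[A,B] = 1/3

  A1 <- matrix(c(1, 1, 0, 0), 2, 2, dimnames = list(c("m1", "m2"), c("A", "B")))
  # DT1 = DT2 = {A}
  expect_equal(mirna_functional_similarity(A1, W_d)["m1", "m2"], 1)

  A2 <- matrix(c(1, 0, 0, 1), 2, 2, dimnames = list(c("m1", "m2"), c("A", "B")))
  # DT1 = {A}, DT2 = {B} -> (1/3 + 1/3) / 2
  expect_equal(mirna_functional_similarity(A2, W_d)["m1", "m2"], 1 / 3)

  A3 <- matrix(c(1, 1, 1, 0), 2, 2, dimnames = list(c("m1", "m2"), c("A", "B")))
  # DT1 = {A, B}, DT2 = {A} -> (1 + 1/3 + 1) / 3
  expect_equal(mirna_functional_similarity(A3, W_d)["m1", "m2"], 7 / 9)
})

test_that("miRNAs without associations get zero similarity, unit self-similarity", {
  sib <- sibling_dags()
  W_d <- build_disease_similarity(sib)
  A <- matrix(c(1, 0, 0, 0), 2, 2, dimnames = list(c("m1", "m2"), c("A", "B")))
  W <- mirna_functional_similarity(A, W_d)
  expect_equal(W["m1", "m2"], 0)
  expect_equal(W["m2", "m2"], 1)
})

test_that("with identity disease similarity, MISIM reduces to set overlap", {
  n_dis <- 6
  W_d <- toy_similarity(n_dis, sprintf("D%d", 1:n_dis))
  set.seed(5)
  for (rep in 1:15) {
    A <- matrix(rbinom(4 * n_dis, 1, 0.5), 4,
                dimnames = list(sprintf("m%d", 1:4), colnames(W_d)))
    W <- mirna_functional_similarity(A, W_d)
    expect_identical(W, t(W))
    for (i in 1:3) for (j in (i + 1):4) {
      dt1 <- colnames(A)[A[i, ] == 1]; dt2 <- colnames(A)[A[j, ] == 1]
      expected <- if (!length(dt1) || !length(dt2)) 0 else
        2 * length(intersect(dt1, dt2)) / (length(dt1) + length(dt2))
      expect_equal(W[i, j], expected)
    }
  }
})
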