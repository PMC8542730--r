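# Clustering backends, dispersion, gap statistic, model selection, profiles.

test_that("within-cluster dispersion equals the brute-force pairwise formula", {
  # two points at distance 1 in one cluster
  coords <- rbind(c(0, 0), c(1, 0))
  expect_equal(within_dispersion(make_emb(coords), c(1, 1)), 0.5)
  expect_equal(within_dispersion(make_emb(coords), c(1, 1)),
               wk_oracle(coords, c(1, 1)))
  # singletons have zero dispersion
  expect_equal(within_dispersion(make_emb(coords), c(1, 2)), 0)
  # random case against the oracle, invariant to label renaming
  set.seed(2)
  c2 <- matrix(rnorm(30), 10, 3)
  lab <- sample(3, 10, replace = TRUE)
  expect_equal(within_dispersion(make_emb(c2), lab), wk_oracle(c2, lab))
  relab <- c(7, 5, 9)[lab]
  expect_equal(within_dispersion(make_emb(c2), relab),
               within_dispersion(make_emb(c2), lab))
  expect_error(within_dispersion(make_emb(c2), lab[1:5]), "match")
})

test_that("Ward clustering groups separated structure and is exhaustively optimal on a toy", {
  # two well-separated pairs of identical points
  emb <- make_emb(rbind(c(0, 0), c(0, 0), c(10, 10), c(10, 10)))
  sol <- cluster_hierarchical(emb, 2)
  expect_equal(sol$labels[1], sol$labels[2])
  expect_equal(sol$labels[3], sol$labels[4])
  expect_false(sol$labels[1] == sol$labels[3])
  # k = n gives singletons with W = 0
  sol_n <- cluster_hierarchical(emb, 4)
  expect_equal(sol_n$W_k, 0)
  expect_equal(sol_n$k, 4L)
  expect_error(cluster_hierarchical(emb, 5), "exceeds")
  # 6-point planted 3-blob toy: matches the minimum-WSS 3-partition
  coords <- rbind(c(0, 0), c(0.3, 0), c(5, 5), c(5.2, 5), c(-4, 6), c(-4, 6.4))
  sol3 <- cluster_hierarchical(make_emb(coords), 3)
  parts <- Filter(function(p) length(unique(p)) == 3, gen_partitions(6))
  costs <- vapply(parts, function(p) wk_oracle(coords, p), numeric(1))
  best <- parts[[which.min(costs)]]
  expect_equal(adjusted_rand_index(sol3$labels, best), 1)
  expect_equal(sol3$W_k, min(costs))
})

test_that("k-means++ is deterministic, exact on duplicated points, and optimal at small n", {
  pts <- rbind(c(0, 0), c(6, 0), c(3, 5))
  emb <- make_emb(pts[rep(1:3, each = 3), ])
  sol <- cluster_kmeanspp(emb, 3, seed = 4)
  expect_equal(sol$W_k, 0)
  expect_equal(sol$k, 3L)
  expect_identical(sol$labels, cluster_kmeanspp(emb, 3, seed = 4)$labels)
  # exhaustive-search optimum on 9 jittered points
  set.seed(5)
  coords <- pts[rep(1:3, each = 3), ] + matrix(rnorm(18, sd = 0.4), 9, 2)
  sol9 <- cluster_kmeanspp(make_emb(coords), 3, seed = 6, n_init = 10)
  expect_equal(sol9$W_k, kmeans_oracle(coords, 3), tolerance = 1e-9)
})

test_that("k-means++ seeding beats random seeding almost always", {
  blob <- make_blobs(60, rbind(c(0, 0), c(8, 0), c(4, 7)), sd = 0.8, seed = 3)
  wins <- 0L
  for (s in 1:20) {
    pp <- cluster_kmeanspp(blob$emb, 3, seed = s, n_init = 1)
    set.seed(s + 1000)
    rnd <- suppressWarnings(stats::kmeans(blob$emb$coords, centers = 3,
                                          iter.max = 100, nstart = 1,
                                          algorithm = "Lloyd"))
    wins <- wins + (pp$W_k <= rnd$tot.withinss + 1e-9)
  }
  expect_gte(wins, 19L)
})

test_that("W_k is non-increasing along nested hierarchical cuts", {
  set.seed(7)
  emb <- make_emb(matrix(rnorm(80), 40, 2))
  w <- vapply(1:8, function(k) cluster_hierarchical(emb, k)$W_k, numeric(1))
  expect_true(all(diff(w) <= 1e-9))
})

test_that("the gap statistic is null on box-uniform data and stable in B", {
  set.seed(11)
  emb <- make_emb(cbind(runif(1500, 0, 4), runif(1500, 0, 2)))
  g <- gap_statistic(emb, 3, B = 40, seed = 12)
  expect_lt(abs(g$gap), 3 * g$gap_se)
  g2 <- gap_statistic(emb, 3, B = 80, seed = 13)
  expect_lt(abs(g$gap - g2$gap), 3 * g$gap_se)
  expect_error(gap_statistic(emb, 3, B = 5, seed = 1), "at least 10")
  flat <- make_emb(cbind(rep(1, 20), rep(2, 20)))
  expect_error(gap_curve(flat, 2, B = 10, seed = 1), "degenerate")
})

test_that("the gap statistic is invariant to rigid rotation of the coordinates", {
  blob <- make_blobs(200, rbind(c(0, 0), c(7, 0), c(3.5, 6)), sd = 1, seed = 14)
  th <- 0.83
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  g1 <- gap_statistic(blob$emb, 3, B = 40, seed = 15)
  g2 <- gap_statistic(make_emb(blob$emb$coords %*% R), 3, B = 40, seed = 16)
  expect_lt(abs(g1$gap - g2$gap), 3 * sqrt(g1$gap_se^2 + g2$gap_se^2))
})

test_that("model selection returns the single cell of a one-cell grid", {
  prep <- small_prepared(n_scale = 0.03, seed = 16)
  X <- prep$strata$SR$features
  sel <- select_model(X, d_grid = 2, k_grid = 3, method = "kmeanspp",
                      B = 10, seed = 17, embedder = "pca")
  expect_equal(unname(sel$gap$best), c(2, 3))
  expect_equal(dim(sel$gap$gap_matrix), c(1L, 1L))
  expect_equal(sel$solution$k, 3L)
  expect_length(sel$solution$internal_indices, 3L)
})

test_that("a single gaussian cloud is flagged as weak structure", {
  set.seed(18)
  X <- make_fm(matrix(rnorm(300 * 4), 300, 4))
  sel <- select_model(X, d_grid = 2, k_grid = 1:5, method = "hierarchical",
                      B = 20, seed = 19, embedder = "pca")
  expect_true(sel$gap$weak_structure)
})

test_that("selection reproduces bit-identically under a fixed master seed", {
  prep <- small_prepared(n_scale = 0.03, seed = 20)
  X <- prep$strata$SR$features
  a <- select_model(X, d_grid = 2, k_grid = 2:3, method = "hierarchical",
                    B = 10, seed = 21, embedder = "vae",
                    vae_args = list(epochs = 5, hidden = 8, batch_size = 128))
  b <- select_model(X, d_grid = 2, k_grid = 2:3, method = "hierarchical",
                    B = 10, seed = 21, embedder = "vae",
                    vae_args = list(epochs = 5, hidden = 8, batch_size = 128))
  expect_identical(a$solution$labels, b$solution$labels)
  expect_identical(a$gap$gap_matrix, b$gap$gap_matrix)
})

test_that("internal indices behave sensibly on separated blobs", {
  blob <- make_blobs(150, rbind(c(0, 0), c(10, 0), c(5, 9)), sd = 0.7,
                     seed = 22)
  idx <- bbcluster:::internal_indices(blob$emb$coords, blob$labels)
  expect_gt(idx["silhouette"], 0.5)
  expect_lt(idx["silhouette"], 1)
  expect_gt(idx["calinski_harabasz"], 0)
  expect_gt(idx["davies_bouldin"], 0)
  expect_lt(idx["davies_bouldin"], 1)  # compact, well separated
})

test_that("canonical labels ascend in mortality and profiles scale to the cohort", {
  labels <- c(rep("x", 4), rep("y", 4))
  death <- c(1, 1, 1, 0, 0, 0, 0, 1)
  canon <- canonicalise_labels(labels, death)
  expect_equal(canon, c(rep(2L, 4), rep(1L, 4)))
  tab <- make_toy_table(6)
  tab$age <- c(60, 70, 80, 50, 65, 66)   # cohort median 65.5
  prof <- cluster_profile(tab, c(1, 1, 1, 2, 2, 2))
  age1 <- prof[prof$cluster == 1 & prof$variable == "age", ]
  expect_equal(age1$scaled, 70 / median(tab$age))
  # cluster identical to cohort: all ratios 1, proportions equal
  prof_same <- cluster_profile(tab, rep(1, 6))
  expect_true(all(abs(prof_same$scaled[prof_same$type == "continuous"] - 1)
                  < 1e-12))
  expect_equal(prof_same$cluster_value[prof_same$type == "binary"],
               prof_same$cohort_value[prof_same$type == "binary"])
  # binary variable absent in a cluster has proportion 0
  tab$anticoagulant <- c(0, 0, 0, 1, 1, 0)
  prof2 <- cluster_profile(tab, c(1, 1, 1, 2, 2, 2))
  expect_equal(prof2$cluster_value[prof2$cluster == 1 &
                                     prof2$variable == "anticoagulant"], 0)
})
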