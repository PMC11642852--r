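test_that("mcc reproduces the closed form on worked confusion tables", {
  expect_identical(mcc(5, 5, 0, 0), 1)
  expect_identical(mcc(0, 0, 5, 5), -1)
  expect_equal(mcc(4, 3, 1, 2), 10 / sqrt(600))
  expect_identical(mcc(0, 10, 0, 0), 0)  # zero-denominator convention
})

test_that("mcc equals the Pearson correlation of binary label vectors", {
  # exhaustive oracle over every confusion table with at most 12 counts
  for (total in 1:12) {
    parts <- expand.grid(tp = 0:total, tn = 0:total, fp = 0:total)
    parts$fn <- total - parts$tp - parts$tn - parts$fp
    parts <- parts[parts$fn >= 0, ]
    for (r in seq_len(nrow(parts))) {
      tp <- parts$tp[r]; tn <- parts$tn[r]
      fp <- parts$fp[r]; fn <- parts$fn[r]
      pred <- c(rep(1, tp), rep(0, tn), rep(1, fp), rep(0, fn))
      truth <- c(rep(1, tp), rep(0, tn), rep(0, fp), rep(1, fn))
      rho <- suppressWarnings(stats::cor(pred, truth))
      got <- mcc(tp, tn, fp, fn)
      if (is.na(rho)) {
        expect_identical(got, 0)
      } else {
        expect_equal(got, rho)
      }
    }
  }
})

test_that("pair_to_graphs runs each sequence through the whole pipeline", {
  tk <- kmer_tokenizer(3)
  pr <- mock_attention_provider(seed = 4L, max_tokens = 64L)
  gs <- pair_to_graphs(rand_dna(60), rand_dna(60), tk, pr, graph_config())
  expect_equal(nrow(gs$a$nodes), 20L)
  expect_equal(nrow(gs$b$nodes), 20L)

  # theta = 1 with sub-unity attention: edgeless graphs, nodes intact
  gs1 <- pair_to_graphs(rand_dna(60), rand_dna(60), tk, pr,
                        graph_config(theta = 1))
  expect_equal(nrow(gs1$a$edges), 0L)
  expect_equal(nrow(gs1$a$nodes), 20L)

  s <- rand_dna(60)
  gs2 <- pair_to_graphs(s, s, tk, pr, graph_config())
  g_a <- gs2$a; g_a$reference <- g_a$nodes$reference <- "x"
  g_b <- gs2$b; g_b$reference <- g_b$nodes$reference <- "x"
  expect_identical(g_a, g_b)  # identical sequences give identical graphs
})

test_that("gcn_layer follows the symmetric-normalized propagation rule", {
  # edgeless: A + I = I, so H' = ReLU(H W) = H for identity W, H >= 0
  g0 <- graph_with_edges(3, data.frame(i = integer(0), j = integer(0),
                                       weight = numeric(0)))
  H <- matrix(stats::runif(6), 3, 2)
  expect_equal(gcn_layer(H, g0, diag(2)), H)

  # one unit edge: D = (2, 2), rows average
  g1 <- graph_with_edges(2, data.frame(i = 0L, j = 1L, weight = 1))
  H1 <- diag(2)
  expect_equal(gcn_layer(H1, g1, diag(2)),
               matrix(0.5, 2, 2))

  expect_equal(gcn_layer(H, g0, matrix(0, 2, 2)), matrix(0, 3, 2))
  expect_error(gcn_layer(H, g1, diag(2)), "shape mismatch")
})

test_that("graph embeddings are permutation- and duplication-invariant", {
  set.seed(19)
  params <- tokengraph:::.init_params(4096L, 8L)
  g <- rand_graph(6)
  e1 <- graph_embedding(g, params)
  expect_length(e1, 8L)

  # permute node order (relabel indices consistently)
  perm <- sample(6L)
  nodes <- g$nodes[perm, ]
  nodes$node_index <- 0:5
  remap <- match(g$edges$i, g$nodes$node_index[perm]) - 1L
  remap_j <- match(g$edges$j, g$nodes$node_index[perm]) - 1L
  edges <- data.frame(i = pmin(remap, remap_j), j = pmax(remap, remap_j),
                      weight = g$edges$weight)
  gp <- token_graph(g$reference, nodes, edges)
  expect_equal(sort(graph_embedding(gp, params)), sort(e1))
  expect_equal(graph_embedding(gp, params), e1)

  # duplicating every node (disjoint copy of the graph) leaves the mean
  n2 <- g$nodes; n2$node_index <- n2$node_index + 6L
  e2 <- g$edges; e2$i <- e2$i + 6L; e2$j <- e2$j + 6L
  gd <- token_graph(g$reference, rbind(g$nodes, n2), rbind(g$edges, e2))
  expect_equal(graph_embedding(gd, params), e1)

  # a one-node graph embeds as that node's propagated features
  g1 <- graph_with_edges(1, data.frame(i = integer(0), j = integer(0),
                                       weight = numeric(0)))
  f <- gcn_layer(gcn_layer(params$embedding[g1$nodes$token_id + 1L, ,
                                            drop = FALSE],
                           g1, params$W1), g1, params$W2)
  expect_equal(graph_embedding(g1, params), as.numeric(f))

  empty <- token_graph("e", rand_graph(0)$nodes)
  expect_error(graph_embedding(empty, params), "empty")
})

test_that("predict_pair is a sigmoid readout with the expected fixed points", {
  set.seed(29)
  params <- tokengraph:::.init_params(4096L, 8L)
  ga <- rand_graph(4); gb <- rand_graph(5)

  p0 <- params; p0$w <- rep(0, 16L); p0$b <- 0
  expect_identical(predict_pair(ga, gb, p0), 0.5)

  psat <- params; psat$b <- 1e4
  expect_equal(predict_pair(ga, gb, psat), 1)

  expect_identical(predict_pair(ga, gb, params),
                   predict_pair(ga, gb, params))
  expect_true(predict_pair(ga, gb, params) >= 0 &&
                predict_pair(ga, gb, params) <= 1)
})

test_that("analytic gradients match finite differences", {
  set.seed(37)
  ga <- rand_graph(4); gb <- rand_graph(3)
  pa <- list(ids = ga$nodes$token_id, ahat = tokengraph:::.gcn_ahat(ga))
  pb <- list(ids = gb$nodes$token_id, ahat = tokengraph:::.gcn_ahat(gb))
  params <- tokengraph:::.init_params(4096L, 6L)
  fg <- tokengraph:::.pair_grad(pa, pb, 1, params)
  loss <- function(pp) -log(predict_pair(ga, gb, pp) + 1e-12)
  eps <- 1e-6
  for (nm in c("embedding", "W1", "W2", "w", "b")) {
    idx <- sample(length(params[[nm]]), min(5L, length(params[[nm]])))
    for (i in idx) {
      up <- params; up[[nm]][i] <- up[[nm]][i] + eps
      dn <- params; dn[[nm]][i] <- dn[[nm]][i] - eps
      num <- (loss(up) - loss(dn)) / (2 * eps)
      expect_equal(fg$grads[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("training is seeded, reproducible, and degenerates sanely", {
  data <- synth_epi_dataset(n_pairs = 16L, seq_length = 120L, seed = 3L)
  tk <- kmer_tokenizer(6)
  pr <- mock_attention_provider(seed = 0L, max_tokens = 64L)

  f0 <- epi_gcn(data, tk, pr, epochs = 0L, seed = 2L)
  init <- tokengraph:::.with_seed(1, NULL)  # no-op, keeps RNG tidy
  expect_identical(f0$params, f0$final_params)
  expect_true(is.na(f0$best_val_mcc))

  f1 <- epi_gcn(data, tk, pr, epochs = 2L, seed = 5L)
  f2 <- epi_gcn(data, tk, pr, epochs = 2L, seed = 5L)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$history, f2$history)

  single <- data; single$label <- 1L
  expect_error(epi_gcn(single, tk, pr, epochs = 1L), "both classes")

  expect_output(print(f1), "GCN classifier")
  expect_output(summary(f1), "validation MCC")
  pr1 <- predict(f1, data[1:3, ])
  expect_length(pr1, 3L)
  expect_true(all(pr1 >= 0 & pr1 <= 1))
  expect_true(all(predict(f1, data[1:3, ], type = "class") %in% 0:1))
})
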