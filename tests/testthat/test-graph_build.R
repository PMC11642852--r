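attn_matrix <- function(m, vals) {
  structure(list(values = matrix(vals, m, m, byrow = TRUE), token_count = m),
            class = "attention_matrix")
}

toy_tokens <- function(m, reference = "chr_e") {
  data.frame(node_index = seq_len(m) - 1L, token_id = seq_len(m) - 1L,
             token_string = strrep("A", 3L), reference = reference,
             start = (seq_len(m) - 1L) * 3L, end = seq_len(m) * 3L,
             stringsAsFactors = FALSE)
}

test_that("only upper-triangular entries at or above theta become edges", {
  a <- attn_matrix(3, c(0.5, 0.3, 0.2,
                        0.1, 0.6, 0.3,
                        0.2, 0.2, 0.6))
  g <- build_chunk_graph(toy_tokens(3), a, graph_config(theta = 0.25))
  expect_equal(g$edges$i, c(0L, 1L))
  expect_equal(g$edges$j, c(1L, 2L))
  expect_equal(g$edges$weight, c(0.3, 0.3))
  # the threshold is inclusive
  g2 <- build_chunk_graph(toy_tokens(3), a, graph_config(theta = 0.3))
  expect_equal(nrow(g2$edges), 2L)
  # all nodes retained even when isolated
  expect_equal(nrow(g$nodes), 3L)
})

test_that("theta extremes give the complete and the empty edge set", {
  set.seed(5)
  m <- 6L
  a <- aggregate_attention(mock_attention(seq_len(m), seed = 1L))
  g0 <- build_chunk_graph(toy_tokens(m), a, graph_config(theta = 0))
  expect_equal(nrow(g0$edges), m * (m - 1L) / 2L)
  g1 <- build_chunk_graph(toy_tokens(m), a, graph_config(theta = 1))
  expect_equal(nrow(g1$edges), 0L)
  expect_error(graph_config(theta = 1.01), "theta")
  expect_error(build_chunk_graph(toy_tokens(4), a, graph_config()),
               "disagree in size")
})

test_that("edge rule matches a brute-force double loop for all m <= 12", {
  set.seed(31)
  for (m in 1:12) {
    a <- aggregate_attention(mock_attention(sample.int(100L, m, TRUE),
                                            seed = m))
    for (theta in c(0, 1, round(stats::runif(5), 3),
                    sample(a$values, min(3, length(a$values))))) {
      g <- build_chunk_graph(toy_tokens(m), a, graph_config(theta = theta))
      brute <- list()
      for (i in seq_len(m)) {
        for (j in seq_len(m)) {
          if (i < j && a$values[i, j] >= theta) {
            brute[[length(brute) + 1L]] <- c(i - 1L, j - 1L, a$values[i, j])
          }
        }
      }
      bd <- if (length(brute)) do.call(rbind, brute) else
        matrix(0, 0L, 3L)
      expect_equal(nrow(g$edges), nrow(bd))
      if (nrow(bd)) {
        expect_equal(g$edges$i, as.integer(bd[, 1L]))
        expect_equal(g$edges$j, as.integer(bd[, 2L]))
        expect_equal(g$edges$weight, bd[, 3L])
      }
    }
  }
})

test_that("degree filter removes low-degree nodes in a single pass", {
  # star: center 0 linked to leaves 1..4
  star <- graph_with_edges(5, data.frame(i = 0L, j = 1:4, weight = 0.9))
  f <- apply_degree_filter(star, 2L)
  expect_equal(f$nodes$node_index, 0L)   # center survives on input degree 4
  expect_equal(nrow(f$edges), 0L)        # now isolated, index preserved

  expect_identical(apply_degree_filter(star, 0L), star)

  tri <- graph_with_edges(3, data.frame(i = c(0L, 0L, 1L), j = c(1L, 2L, 2L),
                                        weight = 0.5))
  expect_identical(apply_degree_filter(tri, 2L), tri)
})

test_that("k-core peeling iterates where the single pass stops", {
  # path 0-1-2-3: single pass at min_degree 2 keeps {1,2}; k-core empties
  path <- graph_with_edges(4, data.frame(i = 0:2, j = 1:3, weight = 1))
  once <- apply_degree_filter(path, 2L)
  expect_equal(once$nodes$node_index, c(1L, 2L))
  core <- apply_degree_filter(path, 2L, kcore = TRUE)
  expect_equal(nrow(core$nodes), 0L)
})

test_that("edge sets shrink as theta grows and survivors shrink with min_degree", {
  set.seed(17)
  for (r in 1:50) {
    g <- rand_graph(sample(2:12, 1))
    th <- sort(stats::runif(2))
    e1 <- refilter_graph(g, th[1L])$edges
    e2 <- refilter_graph(g, th[2L])$edges
    expect_true(all(paste(e2$i, e2$j) %in% paste(e1$i, e1$j)))
    dd <- sort(sample(0:4, 2))
    s1 <- apply_degree_filter(g, dd[1L])$nodes$node_index
    s2 <- apply_degree_filter(g, dd[2L])$nodes$node_index
    expect_true(all(s2 %in% s1))
  }
})

test_that("merging chunk graphs is a disjoint union", {
  g1 <- graph_with_edges(3, data.frame(i = c(0L, 1L), j = c(1L, 2L),
                                       weight = c(0.4, 0.5)))
  n2 <- toy_tokens(2)
  n2$node_index <- n2$node_index + 3L
  g2 <- token_graph("chr_e", n2,
                    data.frame(i = 3L, j = 4L, weight = 0.7))
  m <- merge_reference_graph(list(g1, g2))
  expect_equal(nrow(m$nodes), 5L)
  expect_equal(nrow(m$edges), 3L)
  expect_identical(merge_reference_graph(list(g1)), g1)
  empty <- merge_reference_graph(list(), reference = "chr_e")
  expect_equal(nrow(empty$nodes), 0L)

  g3 <- g2; g3$reference <- "other"; g3$nodes$reference <- "other"
  expect_error(merge_reference_graph(list(g1, g3)), "mix references")
})

test_that("degree filtering after the union equals filtering per chunk", {
  # no cross-chunk edges exist, so the two orders must agree
  set.seed(23)
  for (r in 1:10) {
    g1 <- rand_graph(sample(2:8, 1), reference = "chr_m")
    n2 <- rand_graph(sample(2:8, 1), reference = "chr_m")
    n2$nodes$node_index <- n2$nodes$node_index + nrow(g1$nodes)
    n2$edges$i <- n2$edges$i + nrow(g1$nodes)
    n2$edges$j <- n2$edges$j + nrow(g1$nodes)
    g2 <- token_graph("chr_m", n2$nodes, n2$edges)
    md <- 2L
    after_union <- apply_degree_filter(merge_reference_graph(list(g1, g2)), md)
    per_chunk <- merge_reference_graph(
      list(apply_degree_filter(g1, md), apply_degree_filter(g2, md)))
    expect_identical(after_union, per_chunk)
  }
})

test_that("serialization round-trips losslessly in all three formats", {
  set.seed(41)
  graphs <- c(lapply(1:8, function(i) rand_graph(sample(1:12, 1))),
              list(token_graph("chr_empty",
                               rand_graph(0)$nodes)))
  for (g in graphs) {
    for (fmt in c("graphml", "json", "tsv")) {
      p <- tempfile()
      write_token_graph(g, p, fmt)
      expect_identical(read_token_graph(p, fmt), g, label = fmt)
    }
  }
})

test_that("serialized edge lists contain no duplicates and no lower-triangular pairs", {
  set.seed(43)
  g <- rand_graph(10)
  p <- tempfile()
  write_token_graph(g, p, "tsv")
  tab <- utils::read.table(p, sep = "\t", header = TRUE, comment.char = "#")
  expect_true(all(tab$i < tab$j))
  expect_false(anyDuplicated(tab[, c("i", "j")]) > 0)
})

test_that("the full pipeline produces one filtered graph per reference", {
  fa <- tempfile(fileext = ".fa")
  synth_genome(fa, lengths = c(120L, 45L), seed = 5L)
  tk <- kmer_tokenizer(3)
  pr <- mock_attention_provider(seed = 2L, max_tokens = 32L)
  gs <- build_token_graphs(fa, tk, pr, graph_config(theta = 0.02,
                                                    min_degree = 1L))
  expect_named(gs, c("synth_ref1", "synth_ref2"))
  for (g in gs) {
    expect_true(all(g$edges$weight >= 0.02))
    if (nrow(g$nodes)) expect_true(all(node_degrees(g) >= 1L))
  }
  # 120 nt in 30-nt chunks of 3-mers: 40 tokens before filtering
  gs0 <- build_token_graphs(fa, tk, pr, graph_config())
  expect_equal(nrow(gs0$synth_ref1$nodes), 40L)
})
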