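#' Matthews correlation coefficient from confusion counts
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, the balanced
#' binary-classification metric in `[-1, 1]` equal to the Pearson correlation
#' between predicted and true binary labels. When any factor under the root
#' is zero the value is 0 by the standard convention.
#'
#' @param tp,tn,fp,fn Non-negative confusion counts.
#' @return MCC in `[-1, 1]`.
#' @examples
#' mcc(4, 3, 1, 2)  # 10 / sqrt(600)
#' @export
mcc <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom2 == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom2)
}

.mcc_labels <- function(pred, truth) {
  mcc(sum(pred == 1 & truth == 1), sum(pred == 0 & truth == 0),
      sum(pred == 1 & truth == 0), sum(pred == 0 & truth == 1))
}

#' Token graph from a single in-memory sequence
#'
#' Runs one sequence through the full pipeline — chunking to the provider's
#' token budget, cleaning, tokenization, attention, softmax/average
#' aggregation, upper-triangular theta rule, chunk union, degree filter —
#' treating the string as a single-reference genome.
#'
#' @param sequence Nucleotide string.
#' @param tokenizer A `tokenizer_adapter`.
#' @param provider An `attention_provider`.
#' @param config A `graph_config`.
#' @param reference Name to record on the graph (default `"seq"`).
#' @return A `token_graph`.
#' @export
sequence_to_graph <- function(sequence, tokenizer, provider,
                              config = graph_config(), reference = "seq") {
  chunk_len <- compute_chunk_length(provider$max_tokens,
                                    tokenizer$n_special_tokens)
  L <- nchar(sequence)
  starts <- if (L > 0L) seq.int(0L, L - 1L, by = chunk_len) else integer(0)
  offset <- 0L
  cgs <- list()
  for (s in starts) {
    raw <- substring(sequence, s + 1L, min(L, s + chunk_len))
    cleaned <- clean_chunk(structure(
      list(reference = reference, start = as.integer(s), raw_sequence = raw),
      class = "sequence_chunk"))
    toks <- tokenize_chunk(cleaned, tokenizer)
    if (nrow(toks) == 0L) next
    nodes <- globalize_offsets(toks, cleaned, index_offset = offset)
    offset <- offset + nrow(nodes)
    attn <- aggregate_attention(raw_attention(provider, nodes$token_id))
    cgs[[length(cgs) + 1L]] <- build_chunk_graph(nodes, attn, config)
  }
  g <- merge_reference_graph(cgs, reference = reference)
  apply_degree_filter(g, config$min_degree, kcore = config$kcore)
}

#' Graph pair for one labeled enhancer-promoter example
#'
#' @param seq_a,seq_b The two interacting (or non-interacting) sequences,
#'   enhancer first.
#' @inheritParams sequence_to_graph
#' @return List of two `token_graph`s (`a`, `b`).
#' @export
pair_to_graphs <- function(seq_a, seq_b, tokenizer, provider,
                           config = graph_config()) {
  list(a = sequence_to_graph(seq_a, tokenizer, provider, config, "seq_a"),
       b = sequence_to_graph(seq_b, tokenizer, provider, config, "seq_b"))
}

# symmetric normalization with unit self-loops: D^-1/2 (A + I) D^-1/2,
# A the weighted adjacency in node order (indices compacted for the GCN)
.gcn_ahat <- function(graph) {
  m <- nrow(graph$nodes)
  A <- matrix(0, m, m)
  if (nrow(graph$edges)) {
    ii <- match(graph$edges$i, graph$nodes$node_index)
    jj <- match(graph$edges$j, graph$nodes$node_index)
    A[cbind(ii, jj)] <- graph$edges$weight
    A[cbind(jj, ii)] <- graph$edges$weight
  }
  diag(A) <- diag(A) + 1
  dinv <- 1 / sqrt(rowSums(A))
  A * outer(dinv, dinv)
}

#' One graph-convolution layer
#'
#' `H' = ReLU(D^-1/2 (A + I) D^-1/2 H W)` with `A` the attention-weighted
#' adjacency (edge weights are not binarized — they are the pipeline's core
#' signal) and unit self-loops. Isolated nodes reduce to `ReLU(H_i W)`.
#'
#' @param H m x d feature matrix, rows in graph node order.
#' @param graph A `token_graph` with m nodes.
#' @param W d x d' weight matrix.
#' @return m x d' propagated feature matrix.
#' @export
gcn_layer <- function(H, graph, W) {
  H <- as.matrix(H); W <- as.matrix(W)
  if (nrow(H) != nrow(graph$nodes) || ncol(H) != nrow(W)) {
    stop("shape mismatch: H is ", nrow(H), "x", ncol(H), ", graph has ",
         nrow(graph$nodes), " nodes, W is ", nrow(W), "x", ncol(W))
  }
  pmax(.gcn_ahat(graph) %*% H %*% W, 0)
}

.forward_graph <- function(ids, ahat, params) {
  H0 <- params$embedding[ids + 1L, , drop = FALSE]
  Z1 <- ahat %*% H0 %*% params$W1
  H1 <- pmax(Z1, 0)
  Z2 <- ahat %*% H1 %*% params$W2
  H2 <- pmax(Z2, 0)
  list(H0 = H0, Z1 = Z1, H1 = H1, Z2 = Z2, H2 = H2,
       g = colMeans(H2))
}

#' Whole-graph embedding
#'
#' Token-id embedding lookup, two graph-convolution layers, then mean pooling
#' over node rows — a permutation-invariant fixed-length representation.
#'
#' @param graph A non-empty `token_graph`.
#' @param params A `gcn_params` list (see [epi_gcn()]).
#' @return Numeric vector of length `d`.
#' @export
graph_embedding <- function(graph, params) {
  if (nrow(graph$nodes) == 0L) stop("cannot embed an empty graph")
  .forward_graph(graph$nodes$token_id, .gcn_ahat(graph), params)$g
}

#' Interaction probability for a graph pair
#'
#' Sigmoid of an affine readout over the concatenated embeddings of the two
#' graphs. Order matters (enhancer, promoter): the readout is not symmetric.
#'
#' @param graph_a,graph_b Non-empty `token_graph`s.
#' @param params A `gcn_params` list.
#' @return Probability in `[0, 1]`.
#' @export
predict_pair <- function(graph_a, graph_b, params) {
  s <- sum(c(graph_embedding(graph_a, params),
             graph_embedding(graph_b, params)) * params$w) + params$b
  1 / (1 + exp(-s))
}

.init_params <- function(vocab_size, d) {
  list(embedding = matrix(stats::rnorm(vocab_size * d, sd = 0.1),
                          vocab_size, d),
       W1 = matrix(stats::rnorm(d * d, sd = sqrt(2 / d)), d, d),
       W2 = matrix(stats::rnorm(d * d, sd = sqrt(2 / d)), d, d),
       w = stats::rnorm(2 * d, sd = 0.1),
       b = 0,
       d = d, vocab_size = vocab_size)
}

.adam_new <- function(params) {
  st <- list(t = 0)
  for (nm in c("embedding", "W1", "W2", "w", "b")) {
    st[[paste0("m_", nm)]] <- params[[nm]] * 0
    st[[paste0("v_", nm)]] <- params[[nm]] * 0
  }
  st
}

.adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  st$t <- st$t + 1
  for (nm in c("embedding", "W1", "W2", "w", "b")) {
    g <- grads[[nm]]
    st[[paste0("m_", nm)]] <- beta1 * st[[paste0("m_", nm)]] + (1 - beta1) * g
    st[[paste0("v_", nm)]] <- beta2 * st[[paste0("v_", nm)]] +
      (1 - beta2) * g * g
    mhat <- st[[paste0("m_", nm)]] / (1 - beta1^st$t)
    vhat <- st[[paste0("v_", nm)]] / (1 - beta2^st$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = st)
}

# forward + backward for one pair; returns loss, probability and gradients
.pair_grad <- function(pa, pb, y, params) {
  fa <- .forward_graph(pa$ids, pa$ahat, params)
  fb <- .forward_graph(pb$ids, pb$ahat, params)
  d <- params$d
  s <- sum(c(fa$g, fb$g) * params$w) + params$b
  p <- 1 / (1 + exp(-s))
  ds <- p - y                       # dL/ds for binary cross-entropy
  gE <- params$embedding * 0
  gW1 <- params$W1 * 0
  gW2 <- params$W2 * 0
  back <- function(f, pg, wpart) {
    dg <- ds * wpart                          # d-vector
    dH2 <- matrix(dg, nrow(f$H2), d, byrow = TRUE) / nrow(f$H2)
    dZ2 <- dH2 * (f$Z2 > 0)
    AH1 <- pg$ahat %*% f$H1
    gW2 <<- gW2 + crossprod(AH1, dZ2)
    dH1 <- (pg$ahat %*% dZ2) %*% t(params$W2)
    dZ1 <- dH1 * (f$Z1 > 0)
    AH0 <- pg$ahat %*% f$H0
    gW1 <<- gW1 + crossprod(AH0, dZ1)
    dH0 <- (pg$ahat %*% dZ1) %*% t(params$W1)
    acc <- rowsum(dH0, pg$ids)
    rows <- as.integer(rownames(acc)) + 1L
    gE[rows, ] <<- gE[rows, ] + acc
  }
  back(fa, pa, params$w[seq_len(d)])
  back(fb, pb, params$w[d + seq_len(d)])
  list(loss = -(y * log(p + 1e-12) + (1 - y) * log(1 - p + 1e-12)),
       p = p,
       grads = list(embedding = gE, W1 = gW1, W2 = gW2,
                    w = ds * c(fa$g, fb$g), b = ds))
}

.prep_pairs <- function(data, tokenizer, provider, config) {
  lapply(seq_len(nrow(data)), function(r) {
    gs <- pair_to_graphs(data$seq_a[r], data$seq_b[r], tokenizer, provider,
                         config)
    list(a = list(ids = gs$a$nodes$token_id, ahat = .gcn_ahat(gs$a)),
         b = list(ids = gs$b$nodes$token_id, ahat = .gcn_ahat(gs$b)),
         y = data$label[r])
  })
}

.eval_mcc <- function(prep, params) {
  pr <- vapply(prep, function(x) {
    fa <- .forward_graph(x$a$ids, x$a$ahat, params)
    fb <- .forward_graph(x$b$ids, x$b$ahat, params)
    s <- sum(c(fa$g, fb$g) * params$w) + params$b
    1 / (1 + exp(-s))
  }, 0)
  y <- vapply(prep, `[[`, 0, "y")
  .mcc_labels(as.integer(pr >= 0.5), y)
}

#' Fit a GCN classifier for enhancer-promoter interaction
#'
#' Trains a two-layer graph convolutional network over attention-derived
#' token graphs: each sequence of a pair is converted to a graph
#' ([pair_to_graphs()]), nodes carry learned token-id embeddings, two
#' symmetric-normalized convolution layers propagate them over the weighted
#' adjacency, mean pooling gives one embedding per graph, and an affine +
#' sigmoid readout over the concatenated pair scores the interaction.
#' Training minimizes binary cross-entropy with Adam, one pair per step; all
#' randomness (initialization, shuffling, validation split) derives from
#' `seed`. The parameters achieving the best validation MCC (decision
#' threshold 0.5) are retained.
#'
#' @param data Data frame with columns `seq_a`, `seq_b` (nucleotide strings)
#'   and `label` (0/1); both classes must be present.
#' @param tokenizer A `tokenizer_adapter` (default 6-mer).
#' @param provider An `attention_provider` (default deterministic mock).
#' @param config A `graph_config` (default theta 0, no degree filter).
#' @param d Embedding and hidden width (default 32).
#' @param lr Adam learning rate (default 5e-3).
#' @param epochs Training epochs (default 50); 0 returns the initialized
#'   parameters unchanged.
#' @param val_fraction Held-out fraction for validation MCC (default 0.2).
#' @param seed Integer seed for all randomness.
#' @return An object of class `epi_gcn`: list with `params` (best-validation
#'   `gcn_params`), `final_params`, `history` (per-epoch loss and validation
#'   MCC), `best_val_mcc`, `tokenizer`, `provider`, `config`, `call`.
#' @export
epi_gcn <- function(data, tokenizer = kmer_tokenizer(6),
                    provider = mock_attention_provider(seed = 0L),
                    config = graph_config(), d = 32L, lr = 5e-3,
                    epochs = 50L, val_fraction = 0.2, seed = 1L) {
  stopifnot(all(c("seq_a", "seq_b", "label") %in% names(data)))
  if (length(unique(data$label)) < 2L) {
    stop("dataset must contain both classes")
  }
  set.seed(seed)
  n <- nrow(data)
  n_val <- max(1L, round(val_fraction * n))
  val_idx <- sample.int(n, n_val)
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (length(unique(data$label[tr_idx])) < 2L) {
    stop("training split must contain both classes")
  }
  prep <- .prep_pairs(data, tokenizer, provider, config)
  tr <- prep[tr_idx]
  va <- prep[val_idx]
  params <- .init_params(tokenizer$vocab_size, as.integer(d))
  st <- .adam_new(params)
  best <- params
  best_mcc <- -Inf
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_mcc = numeric(0))
  for (ep in seq_len(epochs)) {
    tot <- 0
    for (r in sample(length(tr))) {
      x <- tr[[r]]
      fg <- .pair_grad(x$a, x$b, x$y, params)
      tot <- tot + fg$loss
      upd <- .adam_step(params, fg$grads, st, lr)
      params <- upd$params
      st <- upd$state
    }
    vm <- .eval_mcc(va, params)
    history <- rbind(history, data.frame(epoch = ep,
                                         train_loss = tot / length(tr),
                                         val_mcc = vm))
    if (vm > best_mcc) {
      best_mcc <- vm
      best <- params
    }
  }
  if (epochs == 0L) {
    best <- params
    best_mcc <- NA_real_
  }
  structure(list(params = best, final_params = params,
                 best_val_mcc = best_mcc, history = history,
                 n_train = length(tr), n_val = length(va),
                 tokenizer = tokenizer, provider = provider, config = config,
                 call = match.call()),
            class = "epi_gcn")
}

#' @export
print.epi_gcn <- function(x, ...) {
  cat("Enhancer-promoter GCN classifier\n")
  cat("  width d =", x$params$d, ", vocabulary =", x$params$vocab_size, "\n")
  cat("  trained on", x$n_train, "pairs,", x$n_val, "held out\n")
  cat("  best validation MCC:", format(x$best_val_mcc, digits = 4), "\n")
  invisible(x)
}

#' @export
summary.epi_gcn <- function(object, ...) {
  cat("Enhancer-promoter GCN classifier\n\n")
  cat("Tokenizer:", object$tokenizer$name,
      "| attention provider:", object$provider$name, "\n")
  cat("Graph config: theta =", object$config$theta,
      ", min_degree =", object$config$min_degree, "\n")
  h <- object$history
  if (nrow(h)) {
    cat("\nTraining history (", nrow(h), " epochs):\n", sep = "")
    show <- h[unique(c(1L, nrow(h) %/% 2L, nrow(h))), ]
    print(show, row.names = FALSE)
  }
  cat("\nBest validation MCC:", format(object$best_val_mcc, digits = 4), "\n")
  invisible(object)
}

#' Predict interaction probabilities for sequence pairs
#'
#' @param object A fitted `epi_gcn`.
#' @param newdata Data frame with columns `seq_a`, `seq_b`.
#' @param type `"response"` for probabilities, `"class"` for 0/1 labels at
#'   threshold 0.5.
#' @param ... Unused.
#' @return Numeric (or integer) vector, one value per row of `newdata`.
#' @export
predict.epi_gcn <- function(object, newdata, type = c("response", "class"),
                            ...) {
  type <- match.arg(type)
  pr <- vapply(seq_len(nrow(newdata)), function(r) {
    gs <- pair_to_graphs(newdata$seq_a[r], newdata$seq_b[r],
                         object$tokenizer, object$provider, object$config)
    predict_pair(gs$a, gs$b, object$params)
  }, 0)
  if (type == "class") as.integer(pr >= 0.5) else pr
}
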