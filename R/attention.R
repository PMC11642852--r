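# Multiplicative-congruential mixing step, exact in doubles:
# h, v < 2^32 and 69069 * 2^32 < 2^53, so no precision is lost.
.mix <- function(h, v) (h * 69069 + v) %% 4294967296

#' Deterministic mock attention tensor
#'
#' Offline stand-in for a pre-trained genomic language model's attention
#' output: a layers x heads x m x m tensor of pseudo-random raw scores in
#' [0, 1), computed by a stated hash so the same inputs always give
#' bit-identical output. Each score mixes `(seed, layer, head)` with both the
#' token identities and the positions of the (i, j) pair through a
#' multiplicative-congruential scheme (multiplier 69069, modulus 2^32,
#' carried exactly in doubles): the identity component dominates (weight
#' 0.75) so repeated tokens produce structured, non-uniform graphs, while the
#' positional component (weight 0.25) breaks exact ties.
#'
#' @param token_ids Integer vector of token ids (non-empty).
#' @param seed Integer seed.
#' @param L,H Number of layers and heads.
#' @return An `attention_tensor`: list with `values` (array `L x H x m x m`)
#'   and `token_count`.
#' @export
mock_attention <- function(token_ids, seed, L = 2L, H = 2L) {
  m <- length(token_ids)
  if (m == 0L) stop("token list must be non-empty")
  stopifnot(L >= 1, H >= 1)
  ids <- as.numeric(token_ids) %% 4294967296
  pos <- as.numeric(seq_len(m))
  idh <- .mix(1, ids)
  vals <- array(0, dim = c(L, H, m, m))
  for (l in seq_len(L)) {
    for (h in seq_len(H)) {
      base <- .mix(.mix(.mix(as.numeric(seed) %% 4294967296, 104729), l), h)
      ri <- .mix(base, idh)
      u <- outer(ri, idh, .mix) / 4294967296
      rp <- .mix(base, pos)
      p <- outer(rp, pos, .mix) / 4294967296
      vals[l, h, , ] <- 0.75 * u + 0.25 * p
    }
  }
  structure(list(values = vals, token_count = m), class = "attention_tensor")
}

#' Deterministic mock attention provider
#'
#' Packages [mock_attention()] behind the attention-provider contract used by
#' the pipeline: a provider is a list with fields `name`, `max_tokens`, `L`,
#' `H`, `emits_probabilities` and a function `attention(token_ids)` returning
#' an `attention_tensor`. A provider backed by a real transformer would slot
#' in here; the mock ships in-package so every stage runs offline.
#'
#' @param seed Integer seed driving all mock scores.
#' @param L,H Layers and heads of the simulated model.
#' @param max_tokens Capacity of the simulated model, in tokens.
#' @return An `attention_provider`.
#' @export
mock_attention_provider <- function(seed = 0L, L = 2L, H = 2L,
                                    max_tokens = 512L) {
  structure(list(
    name = sprintf("mock(seed=%d,L=%d,H=%d)", seed, L, H),
    max_tokens = as.integer(max_tokens), L = as.integer(L), H = as.integer(H),
    emits_probabilities = FALSE,
    attention = function(token_ids) mock_attention(token_ids, seed, L, H)
  ), class = "attention_provider")
}

#' Raw attention for a token list
#'
#' Runs the provider on the token ids and returns the layer/head attention
#' tensor aligned with token order. Special tokens never reach this point
#' (tokenizer adapters exclude them), so no rows or columns need stripping
#' for the built-in providers; a hub-model provider must return the tensor
#' with special-token rows/columns already removed.
#'
#' @param provider An `attention_provider`.
#' @param token_ids Integer vector, non-empty and within provider capacity.
#' @return An `attention_tensor`.
#' @export
raw_attention <- function(provider, token_ids) {
  if (length(token_ids) == 0L) stop("token list must be non-empty")
  if (length(token_ids) > provider$max_tokens) {
    stop("token list of length ", length(token_ids),
         " exceeds provider capacity ", provider$max_tokens)
  }
  tensor <- provider$attention(token_ids)
  d <- dim(tensor$values)
  stopifnot(length(d) == 4L, d[3L] == d[4L], d[3L] == length(token_ids))
  tensor
}

#' Row-wise softmax
#'
#' Normalizes each row of a score matrix into a probability distribution:
#' `out[i, j] = exp(x[i, j]) / sum_k exp(x[i, k])`. Implemented with row-max
#' subtraction for overflow safety; by softmax shift-invariance the result is
#' unchanged.
#'
#' @param x Numeric matrix with finite entries.
#' @return Matrix of the same shape; every row sums to 1.
#' @export
normalize_rows <- function(x) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("non-finite attention scores")
  e <- exp(x - apply(x, 1L, max))
  e / rowSums(e)
}

#' Aggregate an attention tensor into one normalized matrix
#'
#' Applies a row-wise softmax to every layer/head slice (converting raw
#' weights to probabilities) and averages the resulting row-stochastic
#' matrices over all layers and heads with equal weights. The mean of
#' row-stochastic matrices is row-stochastic, so each output row sums to 1
#' and entries lie in [0, 1]; entry `a[i, j]` is read as the attention-derived
#' probability from token i to token j.
#'
#' @param tensor An `attention_tensor`.
#' @param renormalize If `FALSE`, skip the softmax (for providers that
#'   already emit probabilities) and only average.
#' @return An `attention_matrix`: list with `values` (m x m) and
#'   `token_count`.
#' @export
aggregate_attention <- function(tensor, renormalize = TRUE) {
  d <- dim(tensor$values)
  m <- d[3L]
  acc <- matrix(0, m, m)
  for (l in seq_len(d[1L])) {
    for (h in seq_len(d[2L])) {
      slice <- matrix(tensor$values[l, h, , ], m, m)
      acc <- acc + (if (renormalize) normalize_rows(slice) else slice)
    }
  }
  structure(list(values = acc / (d[1L] * d[2L]), token_count = m),
            class = "attention_matrix")
}
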