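#' Graph construction configuration
#'
#' @param theta Edge-weight threshold in `[0, 1]`; an edge (i, j) with i < j
#'   is kept iff its aggregated attention weight is `>= theta` (inclusive).
#' @param min_degree Degree-connectivity threshold (>= 0): after edge
#'   thresholding, nodes with fewer neighbors are removed.
#' @param kcore If `TRUE`, degree filtering peels iteratively (k-core) instead
#'   of the default single pass.
#' @return A `graph_config`.
#' @export
graph_config <- function(theta = 0, min_degree = 0L, kcore = FALSE) {
  if (theta < 0 || theta > 1) stop("theta must lie in [0, 1]")
  if (min_degree < 0) stop("min_degree must be >= 0")
  structure(list(theta = theta, min_degree = as.integer(min_degree),
                 kcore = isTRUE(kcore)), class = "graph_config")
}

.empty_edges <- function() {
  data.frame(i = integer(0), j = integer(0), weight = numeric(0))
}

#' Construct a token graph
#'
#' Low-level constructor validating the invariants: undirected edges stored
#' once with `i < j` (node_index values), no self-loops, no duplicates; edges
#' canonically sorted by (i, j) so structurally equal graphs compare equal.
#'
#' @param reference Reference name the graph describes.
#' @param nodes Data frame of token nodes (see [globalize_offsets()]).
#' @param edges Data frame with columns `i`, `j`, `weight`.
#' @return A `token_graph`.
#' @export
token_graph <- function(reference, nodes, edges = .empty_edges()) {
  if (nrow(edges) > 0L) {
    stopifnot(all(edges$i < edges$j),
              all(edges$i %in% nodes$node_index),
              all(edges$j %in% nodes$node_index),
              !anyDuplicated(edges[, c("i", "j")]))
    edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  }
  nodes <- nodes[order(nodes$node_index), , drop = FALSE]
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(list(reference = reference, nodes = nodes, edges = edges),
            class = "token_graph")
}

#' @export
print.token_graph <- function(x, ...) {
  cat("<token_graph> reference ", x$reference, ": ", nrow(x$nodes),
      " nodes, ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Build the graph of one chunk from its attention matrix
#'
#' Nodes are the chunk's tokens; only the upper-triangular part of the
#' aggregated attention matrix is consulted, so each unordered pair gets at
#' most one edge and the graph is undirected with no duplicates. For every
#' i < j the edge `(i, j, a_ij)` is present iff `a_ij >= theta`; the mirror
#' entry `a_ji` is never read. All nodes are retained here, even isolated
#' ones; degree filtering is a separate, later step.
#'
#' @param tokens Token-node data frame for the chunk.
#' @param attn An `attention_matrix` aligned with `tokens`.
#' @param config A `graph_config` (only `theta` is used here).
#' @return A `token_graph`.
#' @export
build_chunk_graph <- function(tokens, attn, config = graph_config()) {
  m <- nrow(tokens)
  if (m != attn$token_count) {
    stop("token list (", m, ") and attention matrix (", attn$token_count,
         ") disagree in size")
  }
  a <- attn$values
  hit <- which(upper.tri(a) & a >= config$theta, arr.ind = TRUE)
  edges <- data.frame(i = tokens$node_index[hit[, 1L]],
                      j = tokens$node_index[hit[, 2L]],
                      weight = a[hit])
  token_graph(tokens$reference[1L] %||% NA_character_, tokens, edges)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' Node degrees of a token graph
#' @param graph A `token_graph`.
#' @return Named integer vector of degrees, one per node, in node order.
#' @export
node_degrees <- function(graph) {
  deg <- integer(nrow(graph$nodes))
  names(deg) <- as.character(graph$nodes$node_index)
  if (nrow(graph$edges) > 0L) {
    t1 <- table(factor(as.character(graph$edges$i), levels = names(deg)))
    t2 <- table(factor(as.character(graph$edges$j), levels = names(deg)))
    deg <- as.integer(t1 + t2)
    names(deg) <- as.character(graph$nodes$node_index)
  }
  deg
}

#' Degree-connectivity filter
#'
#' Removes, in a single pass, every node whose degree in the input graph is
#' below `min_degree`, together with its incident edges; surviving nodes keep
#' their `node_index` (no recompaction), and a survivor may end up isolated.
#' With `kcore = TRUE` the pass repeats until stable, yielding the k-core.
#'
#' @param graph A `token_graph`.
#' @param min_degree Minimum neighbor count to survive.
#' @param kcore Iterate to a fixed point instead of one pass.
#' @return The filtered `token_graph`.
#' @export
apply_degree_filter <- function(graph, min_degree, kcore = FALSE) {
  repeat {
    if (min_degree <= 0L) return(graph)
    deg <- node_degrees(graph)
    keep <- graph$nodes$node_index[deg >= min_degree]
    if (length(keep) == nrow(graph$nodes)) return(graph)
    nodes <- graph$nodes[graph$nodes$node_index %in% keep, , drop = FALSE]
    edges <- graph$edges[graph$edges$i %in% keep & graph$edges$j %in% keep, ,
                         drop = FALSE]
    graph <- token_graph(graph$reference, nodes, edges)
    if (!kcore) return(graph)
  }
}

#' Union of chunk graphs for one reference
#'
#' Each reference is represented as one graph; chunks contribute disjoint
#' node-index ranges (cross-chunk numbering is assigned at tokenization), so
#' the union is a plain disjoint union of node and edge sets. No cross-chunk
#' edges are created: the model never attends across chunk boundaries.
#'
#' @param chunk_graphs List of `token_graph`s sharing one reference.
#' @param reference Reference name to use when the list is empty.
#' @return The merged `token_graph`.
#' @export
merge_reference_graph <- function(chunk_graphs, reference = NA_character_) {
  if (length(chunk_graphs) == 0L) {
    return(token_graph(reference, .empty_nodes()))
  }
  refs <- unique(vapply(chunk_graphs, `[[`, "", "reference"))
  if (length(refs) > 1L) {
    stop("chunk graphs mix references: ", paste(refs, collapse = ", "))
  }
  nodes <- do.call(rbind, lapply(chunk_graphs, `[[`, "nodes"))
  if (anyDuplicated(nodes$node_index)) {
    stop("chunk graphs have overlapping node_index ranges")
  }
  edges <- do.call(rbind, lapply(chunk_graphs, `[[`, "edges"))
  token_graph(refs, nodes, edges)
}

.empty_nodes <- function() {
  data.frame(node_index = integer(0), token_id = integer(0),
             token_string = character(0), reference = character(0),
             start = integer(0), end = integer(0), stringsAsFactors = FALSE)
}

#' Re-apply an edge-weight threshold to a built graph
#'
#' Raising theta can only drop edges, so filtering a built graph at a higher
#' theta equals rebuilding at that theta (node set untouched).
#' @param graph A `token_graph`.
#' @param theta New threshold.
#' @return A `token_graph` with edges of weight `>= theta`.
#' @export
refilter_graph <- function(graph, theta) {
  token_graph(graph$reference, graph$nodes,
              graph$edges[graph$edges$weight >= theta, , drop = FALSE])
}

#' Run the full graph-construction pipeline over a FASTA file
#'
#' For each reference: tile into chunks sized to the provider's token budget,
#' clean each chunk (uppercase, drop non-ACGT while preserving coordinates),
#' tokenize, obtain attention, aggregate (softmax then layer/head average),
#' apply the upper-triangular theta rule per chunk, union the chunk graphs,
#' and finally apply the degree filter to the per-reference graph.
#'
#' @param fasta Path to a FASTA file.
#' @param tokenizer A `tokenizer_adapter`.
#' @param provider An `attention_provider`.
#' @param config A `graph_config`.
#' @param references Optional subset of reference names (default: all).
#' @param renormalize Passed to [aggregate_attention()].
#' @return Named list of `token_graph`, one per reference.
#' @export
build_token_graphs <- function(fasta, tokenizer, provider,
                               config = graph_config(), references = NULL,
                               renormalize = TRUE) {
  genome <- open_genome(fasta)
  refs <- references %||% genome$references$name
  chunk_len <- compute_chunk_length(provider$max_tokens,
                                    tokenizer$n_special_tokens)
  out <- lapply(refs, function(ref) {
    offset <- 0L
    cgs <- list()
    for (chunk in iter_chunks(genome, ref, chunk_len)) {
      cleaned <- clean_chunk(chunk)
      toks <- tokenize_chunk(cleaned, tokenizer)
      if (nrow(toks) == 0L) next
      nodes <- globalize_offsets(toks, cleaned, index_offset = offset)
      offset <- offset + nrow(nodes)
      attn <- aggregate_attention(raw_attention(provider, nodes$token_id),
                                  renormalize = renormalize)
      cgs[[length(cgs) + 1L]] <- build_chunk_graph(nodes, attn, config)
    }
    g <- merge_reference_graph(cgs, reference = ref)
    apply_degree_filter(g, config$min_degree, kcore = config$kcore)
  })
  names(out) <- refs
  out
}
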