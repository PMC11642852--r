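# Shared fixtures, all built in code at test time.

write_fasta <- function(records, path = tempfile(fileext = ".fa"),
                        wrap = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(records)) {
    writeLines(paste0(">", nm), con)
    s <- records[[nm]]
    if (nchar(s) > 0L) {
      starts <- seq.int(1L, nchar(s), by = wrap)
      writeLines(vapply(starts, function(i)
        substr(s, i, min(nchar(s), i + wrap - 1L)), ""), con)
    }
  }
  path
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

make_chunk <- function(raw, start = 0L, reference = "chr_t1") {
  structure(list(reference = reference, start = as.integer(start),
                 length = nchar(raw), raw_sequence = raw),
            class = "sequence_chunk")
}

# random token graph with m nodes and random edge density
rand_graph <- function(m, reference = "chr_r", density = 0.4,
                       allow_empty = TRUE) {
  nodes <- data.frame(
    node_index = seq_len(m) - 1L,
    token_id = sample.int(4096L, m, replace = TRUE) - 1L,
    token_string = vapply(seq_len(m), function(i) rand_dna(6L), ""),
    reference = rep(reference, m),
    start = (seq_len(m) - 1L) * 6L,
    end = seq_len(m) * 6L,
    stringsAsFactors = FALSE)
  pairs <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < density
  edges <- data.frame(i = pairs[keep, 1L] - 1L, j = pairs[keep, 2L] - 1L,
                      weight = stats::runif(sum(keep)))
  token_graph(reference, nodes, edges)
}

# graph with hand-picked edges over m consecutively indexed nodes
graph_with_edges <- function(m, edges_df, reference = "chr_e") {
  nodes <- data.frame(
    node_index = seq_len(m) - 1L,
    token_id = seq_len(m) - 1L,
    token_string = strrep("A", 6L),
    reference = reference,
    start = (seq_len(m) - 1L) * 6L,
    end = seq_len(m) * 6L,
    stringsAsFactors = FALSE)
  token_graph(reference, nodes, edges_df)
}
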