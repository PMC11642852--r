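#' Built-in non-overlapping k-mer tokenizer
#'
#' Deterministic offline tokenizer in the style of nucleotide-transformer
#' k-mer vocabularies: a sequence over ACGT is partitioned into consecutive
#' non-overlapping k-mers. A trailing remainder shorter than `k` is dropped
#' (this adapter's documented remainder rule). Token ids index the
#' lexicographically ordered 4^k vocabulary, 0-based, after `n_special`
#' reserved special-token ids.
#'
#' @param k k-mer size (>= 1).
#' @param n_special Number of special tokens the adapter accounts for when
#'   sizing chunks (they never appear in output; default 2, class + separator).
#' @return A `tokenizer_adapter`: list with `name`, `mode`, `k`, `vocab_size`,
#'   `n_special_tokens`, and a `tokenize(sequence)` function returning a data
#'   frame with columns `token_id`, `token_string`, `local_start`, `local_end`
#'   (0-based, half-open offsets into the tokenized string).
#' @examples
#' tk <- kmer_tokenizer(3)
#' tk$tokenize("ACGTAC")
#' @export
kmer_tokenizer <- function(k, n_special = 2L) {
  stopifnot(k >= 1)
  k <- as.integer(k)
  base_vals <- c(A = 0L, C = 1L, G = 2L, T = 3L)
  tokenize <- function(sequence) {
    n <- nchar(sequence)
    m <- n %/% k
    if (m == 0L) return(.empty_tokens())
    starts0 <- (seq_len(m) - 1L) * k
    strs <- substring(sequence, starts0 + 1L, starts0 + k)
    # lexicographic rank of each k-mer = base-4 value of its letters
    mat <- matrix(base_vals[unlist(strsplit(strs, "", fixed = TRUE))],
                  nrow = k)
    ids <- as.integer(colSums(mat * 4^((k - 1L):0L))) + n_special
    data.frame(token_id = ids, token_string = strs,
               local_start = starts0, local_end = starts0 + k,
               stringsAsFactors = FALSE)
  }
  structure(list(name = sprintf("kmer:%d", k), mode = "kmer", k = k,
                 vocab_size = as.integer(4L^k + n_special),
                 n_special_tokens = as.integer(n_special),
                 tokenize = tokenize),
            class = "tokenizer_adapter")
}

.empty_tokens <- function() {
  data.frame(token_id = integer(0), token_string = character(0),
             local_start = integer(0), local_end = integer(0),
             stringsAsFactors = FALSE)
}

# default toy merge table: each row merges (left, right) -> left+right,
# applied in order, as in byte-pair encoding
.default_bpe_merges <- rbind(
  c("A", "C"), c("G", "T"), c("T", "A"), c("AC", "GT"),
  c("C", "A"), c("G", "G"), c("TA", "C")
)

#' Built-in toy byte-pair-encoding tokenizer
#'
#' A small, fixed-merge-table BPE tokenizer in the style of DNABERT-2's BPE
#' vocabulary, for offline use. Starting from single nucleotides, each merge
#' rule is applied greedily left-to-right in table order, producing
#' variable-length tokens with exact offsets.
#'
#' @param merges Two-column character matrix of (left, right) merge rules;
#'   defaults to a built-in 7-rule table over ACGT.
#' @param n_special Reserved special-token ids (default 2).
#' @return A `tokenizer_adapter`; see [kmer_tokenizer()] for the contract.
#' @examples
#' bpe_tokenizer()$tokenize("ACGTACGG")
#' @export
bpe_tokenizer <- function(merges = .default_bpe_merges, n_special = 2L) {
  vocab <- c("A", "C", "G", "T", apply(merges, 1L, paste, collapse = ""))
  vocab <- vocab[!duplicated(vocab)]
  tokenize <- function(sequence) {
    if (nchar(sequence) == 0L) return(.empty_tokens())
    toks <- strsplit(sequence, "", fixed = TRUE)[[1L]]
    for (r in seq_len(nrow(merges))) {
      left <- merges[r, 1L]; right <- merges[r, 2L]
      i <- 1L
      while (i < length(toks)) {
        if (toks[i] == left && toks[i + 1L] == right) {
          toks <- c(toks[seq_len(i - 1L)], paste0(left, right),
                    if (i + 1L < length(toks)) toks[(i + 2L):length(toks)])
        } else i <- i + 1L
      }
    }
    ends <- cumsum(nchar(toks))
    data.frame(token_id = match(toks, vocab) - 1L + as.integer(n_special),
               token_string = toks,
               local_start = as.integer(ends - nchar(toks)),
               local_end = as.integer(ends),
               stringsAsFactors = FALSE)
  }
  structure(list(name = "bpe:toy", mode = "bpe", k = NA_integer_,
                 vocab_size = as.integer(length(vocab) + n_special),
                 n_special_tokens = as.integer(n_special),
                 tokenize = tokenize),
            class = "tokenizer_adapter")
}

#' Parse a tokenizer specification string
#'
#' `"kmer:K"` gives the k-mer adapter with that K; `"bpe"` the toy BPE
#' adapter. Used by the command-line interface.
#' @param spec Character scalar.
#' @return A `tokenizer_adapter`.
#' @export
tokenizer_from_spec <- function(spec) {
  if (grepl("^kmer:[0-9]+$", spec)) {
    kmer_tokenizer(as.integer(sub("^kmer:", "", spec)))
  } else if (identical(spec, "bpe")) {
    bpe_tokenizer()
  } else {
    stop("unknown tokenizer spec: '", spec, "' (use kmer:K or bpe)")
  }
}

#' Tokenize a cleaned chunk
#'
#' Runs the adapter on the cleaned sequence (cleaning precedes tokenization
#' in the pipeline) and returns tokens with offsets into the cleaned string.
#' Special tokens are never included: they occupy no genomic position, so
#' they cannot form graph nodes; attention providers drop their rows/columns
#' to match.
#'
#' @param chunk A `cleaned_chunk` from [clean_chunk()].
#' @param tokenizer A `tokenizer_adapter`.
#' @return Data frame with columns `token_id`, `token_string`, `local_start`,
#'   `local_end` (0-based half-open, indices into `cleaned_sequence`). Empty
#'   cleaned sequence yields zero rows.
#' @export
tokenize_chunk <- function(chunk, tokenizer) {
  if (nchar(chunk$cleaned_sequence) == 0L) return(.empty_tokens())
  out <- tokenizer$tokenize(chunk$cleaned_sequence)
  stopifnot(all(out$token_string ==
                  substring(chunk$cleaned_sequence,
                            out$local_start + 1L, out$local_end)))
  out
}

#' Lift chunk-local token offsets to genome-wide coordinates
#'
#' Translates each token's cleaned-sequence offsets to genomic coordinates
#' through the chunk's `coord_map`, so positions account for characters that
#' were removed during cleaning: `start = coord_map[local_start]` and
#' `end = coord_map[local_end - 1] + 1`. A token whose bases straddle removed
#' characters therefore spans the gap. Node indices continue across chunks of
#' one reference via `index_offset`.
#'
#' @param tokens Data frame from [tokenize_chunk()].
#' @param chunk The `cleaned_chunk` the tokens came from.
#' @param index_offset First `node_index` to assign (0-based; default 0).
#' @return Data frame of token nodes: `node_index`, `token_id`,
#'   `token_string`, `reference`, `start`, `end` (0-based half-open genomic).
#' @export
globalize_offsets <- function(tokens, chunk, index_offset = 0L) {
  n_clean <- length(chunk$coord_map)
  if (nrow(tokens) > 0L &&
      (max(tokens$local_end) > n_clean || min(tokens$local_start) < 0L)) {
    stop("token offsets exceed cleaned chunk length (internal inconsistency)")
  }
  data.frame(
    node_index = index_offset + seq_len(nrow(tokens)) - 1L,
    token_id = tokens$token_id,
    token_string = tokens$token_string,
    reference = rep(chunk$reference, nrow(tokens)),
    start = chunk$coord_map[tokens$local_start + 1L],
    end = chunk$coord_map[tokens$local_end] + 1L,
    stringsAsFactors = FALSE
  )
}
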