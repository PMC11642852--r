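#' Open a genome from an indexed FASTA file
#'
#' Opens a (multi-record) FASTA file for random access via a `.fai` positional
#' index, building the index if it is absent. No sequence data is loaded;
#' segment fetches stream from disk.
#'
#' All coordinates in this package are 0-based, half-open `[start, end)`,
#' matching the BED/indexed-FASTA convention.
#'
#' @param path Path to a FASTA file.
#' @return An object of class `genome_source` with elements `path` (the FASTA
#'   path) and `references`, a data frame with columns `name` and `length`
#'   (nucleotides) in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chrA", "ACGTACGT", ">chrB", "ACGT"), fa)
#' g <- open_genome(fa)
#' g$references
#' @export
open_genome <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  fai <- paste0(path, ".fai")
  if (!file.exists(fai)) {
    # indexFa fails on a zero-record file; treat that as an empty genome
    empty <- length(readLines(path, n = 1L, warn = FALSE)) == 0L
    if (!empty) {
      tryCatch(
        Rsamtools::indexFa(path),
        error = function(e) {
          # a FASTA whose records are all zero-length cannot be indexed;
          # that is still a valid (degenerate) genome
          lines <- readLines(path, warn = FALSE)
          if (all(startsWith(lines, ">") | !nzchar(lines))) {
            writeLines(character(0), fai)
          } else {
            stop("malformed FASTA '", path, "': ", conditionMessage(e))
          }
        }
      )
    } else {
      writeLines(character(0), fai)
    }
  }
  idx <- if (file.size(fai) == 0) {
    data.frame(name = character(0), length = numeric(0))
  } else utils::read.table(fai, sep = "\t", stringsAsFactors = FALSE,
                           col.names = c("name", "length", "offset",
                                         "linebases", "linewidth"),
                           colClasses = c("character", "numeric", "numeric",
                                          "numeric", "numeric"),
                           fill = TRUE, quote = "")
  # the .fai omits zero-length records, so recover the full record list
  # (names only — no sequence is retained) from a streamed header scan
  headers <- .scan_fasta_headers(path)
  if (anyDuplicated(headers)) {
    stop("malformed FASTA '", path, "': duplicate record name '",
         headers[duplicated(headers)][1L], "'")
  }
  if (!all(idx$name %in% headers)) {
    stop("malformed FASTA '", path, "': index and headers disagree")
  }
  m <- match(headers, idx$name)
  refs <- data.frame(name = headers,
                     length = ifelse(is.na(m), 0L, as.integer(idx$length[m])),
                     offset = ifelse(is.na(m), NA_real_, idx$offset[m]),
                     linebases = ifelse(is.na(m), NA_real_, idx$linebases[m]),
                     linewidth = ifelse(is.na(m), NA_real_, idx$linewidth[m]),
                     stringsAsFactors = FALSE)
  structure(list(path = path, references = refs), class = "genome_source")
}

.scan_fasta_headers <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  out <- character(0)
  repeat {
    lines <- readLines(con, n = 10000L, warn = FALSE)
    if (length(lines) == 0L) break
    h <- lines[startsWith(lines, ">")]
    out <- c(out, sub("^>([^ \t]*).*$", "\\1", h))
  }
  out
}

#' @export
print.genome_source <- function(x, ...) {
  cat("<genome_source> ", x$path, "\n", sep = "")
  cat("  ", nrow(x$references), " reference(s), ",
      format(sum(as.numeric(x$references$length)), big.mark = ","),
      " nt total\n", sep = "")
  invisible(x)
}

.ref_length <- function(genome, reference) {
  i <- match(reference, genome$references$name)
  if (is.na(i)) stop("unknown reference: ", reference)
  genome$references$length[i]
}

#' Chunk length for a model token budget
#'
#' A transformer's input limit is counted in tokens. Every token covers at
#' least one nucleotide, so a chunk of `model_max_tokens - n_special_tokens`
#' nucleotides can never exceed the budget once special (class/separator)
#' tokens are accounted for, regardless of tokenizer.
#'
#' @param model_max_tokens Maximum model input length in tokens (> 0).
#' @param n_special_tokens Number of special tokens the tokenizer adds (>= 0).
#' @return Chunk length in nucleotides.
#' @examples
#' compute_chunk_length(512, 2)  # 510
#' @export
compute_chunk_length <- function(model_max_tokens, n_special_tokens) {
  if (n_special_tokens < 0 || model_max_tokens <= n_special_tokens) {
    stop("invalid configuration: model_max_tokens (", model_max_tokens,
         ") must exceed n_special_tokens (", n_special_tokens, ")")
  }
  as.integer(model_max_tokens - n_special_tokens)
}

#' Tile a reference into chunks
#'
#' Returns the chunks that tile a reference exactly: all of length
#' `chunk_length` except possibly the last, so `ceiling(L / chunk_length)`
#' chunks in total and no base omitted.
#'
#' @param genome A `genome_source`.
#' @param reference Reference name.
#' @param chunk_length Chunk size in nucleotides (>= 1).
#' @param sequences If `TRUE` (default) each chunk carries its raw sequence
#'   (fetched by random access, one chunk at a time); if `FALSE` only the
#'   coordinates are returned.
#' @return A list of `sequence_chunk` objects, each with `reference`, `start`
#'   (0-based), `length`, and (if requested) `raw_sequence`.
#' @export
iter_chunks <- function(genome, reference, chunk_length, sequences = TRUE) {
  L <- .ref_length(genome, reference)
  if (chunk_length < 1) stop("chunk_length must be >= 1")
  if (L == 0L) return(list())
  starts <- seq.int(0L, L - 1L, by = chunk_length)
  lapply(starts, function(s) {
    len <- min(chunk_length, L - s)
    seq_chr <- if (sequences) fetch_segment(genome, reference, s, s + len)
               else NULL
    structure(list(reference = reference, start = as.integer(s),
                   length = as.integer(len), raw_sequence = seq_chr),
              class = "sequence_chunk")
  })
}

#' Fetch a raw genome segment
#'
#' Random-access fetch of the uncleaned subsequence `[start, end)` (0-based,
#' half-open) from an indexed FASTA. Lowercase and ambiguity characters are
#' returned as stored in the file.
#'
#' @param genome A `genome_source`.
#' @param reference Reference name.
#' @param start,end 0-based half-open interval; `0 <= start <= end <= length`.
#' @return Character scalar of length `end - start`.
#' @export
fetch_segment <- function(genome, reference, start, end) {
  L <- .ref_length(genome, reference)
  if (start < 0 || end < start || end > L) {
    stop("coordinates [", start, ", ", end, ") out of range for reference '",
         reference, "' of length ", L)
  }
  if (end == start) return("")
  # read the bytes through the .fai offsets rather than scanFa: DNAStringSet
  # normalizes soft-masked bases to uppercase, but the raw segment contract
  # preserves case exactly as stored
  r <- genome$references[match(reference, genome$references$name), ]
  byte_of <- function(pos) r$offset + (pos %/% r$linebases) * r$linewidth +
    pos %% r$linebases
  con <- file(genome$path, "rb")
  on.exit(close(con))
  seek(con, byte_of(start))
  raw_bytes <- readChar(con, byte_of(end - 1L) - byte_of(start) + 1L,
                        useBytes = TRUE)
  gsub("[\r\n]", "", raw_bytes)
}

#' Clean a chunk while preserving genomic coordinates
#'
#' Uppercases the chunk and removes every character outside `{A, C, G, T}`
#' (soft-masked lowercase bases are kept; `N` and ambiguity codes are dropped
#' uniformly). Removed characters still occupy genomic coordinates, so each
#' retained base records its original position in `coord_map`.
#'
#' @param chunk A `sequence_chunk` with a `raw_sequence`.
#' @return A `cleaned_chunk` with `reference`, `start`, `cleaned_sequence`
#'   (over ACGT), and `coord_map` — an integer vector giving, for each cleaned
#'   index `k` (1-based in R), the 0-based genomic coordinate of that base.
#' @examples
#' ch <- structure(list(reference = "r", start = 100L, length = 4L,
#'                      raw_sequence = "NNAC"), class = "sequence_chunk")
#' clean_chunk(ch)$coord_map  # 102 103
#' @export
clean_chunk <- function(chunk) {
  raw <- toupper(chunk$raw_sequence)
  chars <- strsplit(raw, "", fixed = TRUE)[[1L]]
  keep <- chars %in% c("A", "C", "G", "T")
  structure(list(
    reference = chunk$reference,
    start = chunk$start,
    cleaned_sequence = paste(chars[keep], collapse = ""),
    coord_map = as.integer(chunk$start + which(keep) - 1L)
  ), class = "cleaned_chunk")
}
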