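# All generator randomness flows through one named, versioned scheme
# ("tg-rng-1": Mersenne-Twister + Inversion + Rejection sampling, as in
# R >= 3.6), so a given seed yields byte-identical fixtures across releases.
# The caller's RNG state is saved and restored: generators are pure in seed.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  old_kind <- RNGkind("Mersenne-Twister", "Inversion", "Rejection")
  on.exit({
    do.call(RNGkind, as.list(old_kind))
    if (had) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Generate a synthetic genome FASTA
#'
#' Writes a multi-record FASTA emulating the awkward parts of real
#' references: invalid nucleotides (N and ambiguity codes) injected at
#' `invalid_char_rate` and soft-masked lowercase bases at `lowercase_rate`.
#' A sidecar truth TSV of `(reference, position, original_char)` (0-based
#' positions) is written next to the FASTA for coordinate-soundness checks.
#' Output is fully determined by `seed` (scheme tg-rng-1; see README), so
#' reruns are byte-identical. No attempt is made to model realistic genome
#' composition; reference names are prefixed `synth_`.
#'
#' @param path Output FASTA path.
#' @param lengths Integer vector of reference lengths (nucleotides).
#' @param invalid_char_rate Fraction of positions replaced by non-ACGT
#'   characters, in `[0, 1)`.
#' @param lowercase_rate Fraction of retained bases written lowercase,
#'   in `[0, 1)`.
#' @param seed Integer seed.
#' @param ref_names Reference names (default `synth_ref1`, `synth_ref2`, ...).
#' @param wrap Line width for sequence wrapping (default 60).
#' @param truth_path Sidecar TSV path (default `<path>.truth.tsv`).
#' @return `path`, invisibly.
#' @export
synth_genome <- function(path, lengths, invalid_char_rate = 0,
                         lowercase_rate = 0, seed = 1L,
                         ref_names = sprintf("synth_ref%d",
                                             seq_along(lengths)),
                         wrap = 60L,
                         truth_path = paste0(path, ".truth.tsv")) {
  stopifnot(all(lengths >= 0), invalid_char_rate >= 0, invalid_char_rate < 1,
            lowercase_rate >= 0, lowercase_rate < 1,
            length(ref_names) == length(lengths),
            !anyDuplicated(ref_names))
  invalid_alphabet <- c("N", "N", "N", "R", "Y", "W", "S")  # N-heavy mix
  .with_seed(seed, {
    fa <- file(path, "w")
    on.exit(close(fa), add = TRUE)
    tr <- file(truth_path, "w")
    on.exit(close(tr), add = TRUE)
    writeLines("reference\tposition\toriginal_char", tr)
    for (r in seq_along(lengths)) {
      L <- lengths[r]
      chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
      if (invalid_char_rate > 0 && L > 0) {
        inv <- stats::runif(L) < invalid_char_rate
        chars[inv] <- sample(invalid_alphabet, sum(inv), replace = TRUE)
      }
      if (lowercase_rate > 0 && L > 0) {
        lc <- stats::runif(L) < lowercase_rate
        chars[lc] <- tolower(chars[lc])
      }
      writeLines(paste0(">", ref_names[r]), fa)
      if (L > 0) {
        line_starts <- seq.int(1L, L, by = wrap)
        writeLines(vapply(line_starts, function(s)
          paste(chars[s:min(L, s + wrap - 1L)], collapse = ""), ""), fa)
        writeLines(sprintf("%s\t%d\t%s", ref_names[r], seq_len(L) - 1L,
                           chars), tr)
      }
    }
  })
  invisible(path)
}

# fixed default motifs planted by synth_epi_dataset: 29 nt each. A length of
# 6q + 5 yields exactly q complete in-frame 6-mers for every planting frame
# under non-overlapping 6-mer tokenization, so each planted copy contributes
# exactly 4 motif tokens with no frame jitter.
.default_motif_a <- "GGGGTGTGCCTTTTTAAGCGCCTGTATCG"
.default_motif_b <- "GAATTTTCGATCTCGGCAGGGTTTTAGGG"

#' Generate a synthetic enhancer-promoter interaction dataset
#'
#' Writes a TSV of labeled sequence pairs (`seq_a`, `seq_b`, `label`) whose
#' class signal is a plantable motif co-occurrence: positives carry
#' `motif_a` in `seq_a` AND `motif_b` in `seq_b`; negatives carry at most
#' one of the two (one of the three patterns a-only / b-only / neither,
#' chosen uniformly). Background sequences are uniform ACGT. Each planted
#' side receives `copies` copies of its motif at random positions in
#' disjoint slots — regulatory elements are typically clusters of binding
#' sites, and disjoint placement keeps the planted motif-token count exact.
#' The default 5,000-nt length matches the cell-line EPI benchmark setting;
#' shorter lengths keep tests fast. Deterministic in `seed` (scheme
#' tg-rng-1).
#'
#' @param path Output TSV path (`NULL` to skip writing).
#' @param n_pairs Number of pairs.
#' @param seq_length Length of each sequence (default 5000).
#' @param motif_a,motif_b Planted motifs over ACGT (29 nt by default; see
#'   the methods vignette for why the length is congruent to 5 mod 6).
#' @param copies Copies of the motif planted per planted side (default 4).
#' @param positive_fraction Fraction of positive pairs in `(0, 1)`.
#' @param seed Integer seed.
#' @return The dataset as a data frame (invisibly if `path` is given).
#' @export
synth_epi_dataset <- function(path = NULL, n_pairs = 200L, seq_length = 5000L,
                              motif_a = .default_motif_a,
                              motif_b = .default_motif_b,
                              copies = 4L,
                              positive_fraction = 0.5, seed = 1L) {
  stopifnot(positive_fraction > 0, positive_fraction < 1, copies >= 1,
            grepl("^[ACGT]+$", motif_a), grepl("^[ACGT]+$", motif_b))
  slot <- seq_length %/% copies
  if (nchar(motif_a) > slot || nchar(motif_b) > slot) {
    stop("motif longer than seq_length / copies: each of the ", copies,
         " planting slots spans only ", slot, " nt")
  }
  out <- .with_seed(seed, {
    n_pos <- round(n_pairs * positive_fraction)
    labels <- c(rep(1L, n_pos), rep(0L, n_pairs - n_pos))
    rand_seq <- function() paste(sample(c("A", "C", "G", "T"), seq_length,
                                        replace = TRUE), collapse = "")
    plant <- function(s, motif) {
      for (k in 0:(copies - 1L)) {
        pos <- k * slot + sample.int(slot - nchar(motif) + 1L, 1L)
        s <- paste0(substr(s, 1L, pos - 1L), motif,
                    substr(s, pos + nchar(motif), nchar(s)))
      }
      s
    }
    rows <- lapply(labels, function(y) {
      a <- rand_seq(); b <- rand_seq()
      if (y == 1L) {
        a <- plant(a, motif_a); b <- plant(b, motif_b)
      } else {
        pattern <- sample(c("a_only", "b_only", "neither"), 1L)
        if (pattern == "a_only") a <- plant(a, motif_a)
        if (pattern == "b_only") b <- plant(b, motif_b)
      }
      list(a = a, b = b, y = y)
    })
    data.frame(seq_a = vapply(rows, `[[`, "", "a"),
               seq_b = vapply(rows, `[[`, "", "b"),
               label = vapply(rows, `[[`, 0L, "y"),
               stringsAsFactors = FALSE)
  })
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(out))
  }
  out
}
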