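#' Trim 3' adapters from reads
#'
#' Removes the best-scoring 3' occurrence of the adapter from each read,
#' in the spirit of classical small-RNA adapter trimmers: a full internal
#' adapter match (the read continues past the adapter) or a suffix overlap
#' of at least `min_overlap` nt, allowing at most
#' `floor(max_error_rate * matched_adapter_length)` unit-cost edits
#' (substitutions, insertions, deletions). Everything from the occurrence
#' start to the read end is removed. Ties are resolved by smallest edit
#' count first, then leftmost start; reads without an admissible
#' occurrence are returned unchanged. Empty reads are returned unchanged
#' and counted in a warning.
#'
#' Exact occurrences are found by vectorized string search; only reads
#' without an exact candidate (possible when `max_error_rate` admits >= 1
#' edit) go through a per-read semi-global alignment.
#'
#' @param reads tibble with `read_id` and `sequence` (or a character
#'   vector).
#' @param adapter 3' adapter sequence (DNA).
#' @param max_error_rate maximum allowed error rate per matched adapter
#'   base (default 0.1).
#' @param min_overlap minimum adapter suffix overlap considered (nt).
#' @return the read tibble with `sequence` trimmed, plus `length` and
#'   logical `trimmed` columns; attribute `exomir_report` holds counts of
#'   reads in / trimmed / empty.
#' @export
trim_adapters <- function(reads, adapter, max_error_rate = 0.1,
                          min_overlap = 3) {
  if (is.character(reads)) {
    reads <- tibble(read_id = sprintf("r%06d", seq_along(reads)),
                    sequence = reads)
  }
  if (!nzchar(adapter)) abort("adapter must be non-empty")
  if (max_error_rate < 0 || max_error_rate >= 1) {
    abort("`max_error_rate` must lie in [0, 1)")
  }
  seqs <- reads$sequence
  n_empty <- sum(!nzchar(seqs))
  if (n_empty > 0) {
    warn(sprintf("%d empty read(s) returned unchanged", n_empty))
  }
  m <- nchar(adapter)

  # leftmost exact full-adapter occurrence
  full_pos <- stringr::str_locate(seqs, stringr::fixed(adapter))[, "start"]
  cut <- full_pos                                 # NA where no full match
  # exact suffix overlaps: longest adapter prefix at the very end of the read
  nc <- nchar(seqs)
  for (o in seq(m - 1L, max(min_overlap, 1L))) {
    if (o < min_overlap) break
    pre <- substr(adapter, 1L, o)
    hit <- is.na(cut) & nc >= o & substr(seqs, nc - o + 1L, nc) == pre
    cut[hit] <- nc[hit] - o + 1L
  }

  max_edits_full <- floor(max_error_rate * m)
  if (max_edits_full >= 1) {
    todo <- which(is.na(cut) & nzchar(seqs))
    for (i in todo) {
      cut[i] <- .adapter_dp(seqs[i], adapter, max_error_rate, min_overlap)
    }
  }

  trimmed <- !is.na(cut)
  seqs[trimmed] <- substr(seqs[trimmed], 1L, cut[trimmed] - 1L)
  out <- reads
  out$sequence <- seqs
  out$length <- nchar(seqs)
  out$trimmed <- trimmed
  attr(out, "exomir_report") <- list(n_in = nrow(reads),
                                     n_trimmed = sum(trimmed),
                                     n_empty = n_empty)
  out
}

# Semi-global DP of the adapter against one read: returns the 1-based read
# position where the best admissible occurrence starts, or NA. Candidates
# are full-adapter alignments ending anywhere in the read (matched length =
# |adapter|) and adapter-prefix alignments ending at the read end (suffix
# overlap, matched length = prefix length >= min_overlap). Admissible:
# edits <= floor(rate * matched length); best: fewest edits, then leftmost.
.adapter_dp <- function(read, adapter, rate, min_overlap) {
  n <- nchar(read); m <- nchar(adapter)
  r <- strsplit(read, "")[[1]]
  a <- strsplit(adapter, "")[[1]]
  D <- matrix(0L, m + 1L, n + 1L)      # edits; row i = adapter prefix i
  S <- matrix(0L, m + 1L, n + 1L)      # start position of the alignment
  D[, 1L] <- 0:m
  S[, 1L] <- 1L
  S[1L, ] <- c(1L, seq_len(n) + 1L)    # alignment starting after read pos k
  for (k in seq_len(n)) {
    for (i in seq_len(m)) {
      sub <- D[i, k] + (a[i] != r[k])
      del <- D[i, k + 1L] + 1L         # adapter base unmatched
      ins <- D[i + 1L, k] + 1L         # read base inserted
      best <- min(sub, del, ins)
      # prefer the leftmost start among equal-cost predecessors
      starts <- c(if (sub == best) S[i, k],
                  if (del == best) S[i, k + 1L],
                  if (ins == best) S[i + 1L, k])
      D[i + 1L, k + 1L] <- best
      S[i + 1L, k + 1L] <- min(starts)
    }
  }
  cand_cost <- integer(0); cand_start <- integer(0)
  # full internal matches, ending at any read position
  ks <- which(D[m + 1L, -1L] <= floor(rate * m))
  if (length(ks)) {
    cand_cost <- D[m + 1L, ks + 1L]
    cand_start <- S[m + 1L, ks + 1L]
  }
  # suffix overlaps with adapter prefix i, ending at the read end
  is <- seq(min_overlap, m - 1L)
  is <- is[is >= 1L]
  ok <- D[is + 1L, n + 1L] <= floor(rate * is)
  if (any(ok)) {
    cand_cost <- c(cand_cost, D[is[ok] + 1L, n + 1L])
    cand_start <- c(cand_start, S[is[ok] + 1L, n + 1L])
  }
  if (!length(cand_cost)) return(NA_integer_)
  best <- which(cand_cost == min(cand_cost))
  min(cand_start[best])
}

#' Exclude reads shorter than a length floor
#'
#' Drops adapter-trimmed reads shorter than `min_length` nt.
#'
#' @param reads tibble with `sequence`.
#' @param min_length minimum kept read length (nt, default 15).
#' @return the kept reads; attribute `exomir_n_removed` holds the number
#'   removed, so kept + removed equals the input count.
#' @export
filter_min_length <- function(reads, min_length = 15) {
  keep <- nchar(reads$sequence) >= min_length
  out <- reads[keep, , drop = FALSE]
  attr(out, "exomir_n_removed") <- sum(!keep)
  out
}
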