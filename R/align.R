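#' Align reads to a set of reference sequences
#'
#' Ungapped alignment of each read to the references, reporting all hits
#' in the best stratum (minimum mismatch count among admissible hits), in
#' the spirit of a classical `-v`-mode short-read aligner: no indels, at
#' most `max_mismatches` substitutions. Exact matching (`max_mismatches =
#' 0`) uses a substring-index join and is bit-reproducible; mismatch
#' search verifies Hamming neighborhoods per unique read sequence.
#'
#' For genome-style targets both strands are searched
#' (`strands = c("+", "-")`); hairpin targets are conventionally searched
#' forward-only (`strands = "+"`). A `"-"` hit means the reverse
#' complement of the read matches the target at the reported forward
#' coordinates.
#'
#' @param reads tibble with `read_id`, `sequence`, or a character vector
#'   (names become read ids).
#' @param targets named character vector of reference sequences (or a
#'   `DNAStringSet`).
#' @param max_mismatches 0, 1 or 2.
#' @param strands strands to search.
#' @return hits tibble: `read_id`, `target_id`, `start` (0-based), `end`
#'   (half-open), `strand`, `mismatches`. Reads without an admissible hit
#'   are absent.
#' @export
align_reads <- function(reads, targets, max_mismatches = 0,
                        strands = c("+", "-")) {
  if (is.character(reads) || inherits(reads, "DNAStringSet")) {
    ids <- names(reads)
    if (is.null(ids)) ids <- sprintf("r%06d", seq_along(reads))
    reads <- tibble(read_id = ids, sequence = as.character(reads))
  }
  if (inherits(targets, "DNAStringSet")) {
    targets <- setNames(as.character(targets), names(targets))
  }
  if (!length(targets) || any(!nzchar(targets))) {
    abort("reference is empty")
  }
  if (!max_mismatches %in% 0:2) abort("`max_mismatches` must be 0, 1 or 2")

  uniq <- unique(reads$sequence)
  uniq <- uniq[nzchar(uniq)]
  hit_list <- list()
  for (s in strands) {
    qry <- if (s == "+") uniq else revcomp(uniq)
    h <- if (max_mismatches == 0) {
      .align_exact(qry, targets)
    } else {
      .align_mismatch(qry, targets, max_mismatches)
    }
    if (nrow(h)) {
      h$sequence <- uniq[match(h$query, qry)]
      h$strand <- s
      hit_list[[s]] <- h
    }
  }
  hits <- dplyr::bind_rows(hit_list)
  if (!nrow(hits)) {
    return(tibble(read_id = character(0), target_id = character(0),
                  start = integer(0), end = integer(0),
                  strand = character(0), mismatches = integer(0)))
  }
  # best stratum per read sequence
  hits <- hits |>
    dplyr::group_by(sequence) |>
    dplyr::filter(mismatches == min(mismatches)) |>
    dplyr::ungroup()
  reads |>
    dplyr::inner_join(hits, by = "sequence",
                      relationship = "many-to-many") |>
    dplyr::select(read_id, target_id, start, end, strand, mismatches)
}

.align_exact <- function(queries, targets) {
  lens <- unique(nchar(queries))
  idx <- substring_index(targets, lens)
  if (!nrow(idx)) {
    return(tibble(query = character(0), target_id = character(0),
                  start = integer(0), end = integer(0),
                  mismatches = integer(0)))
  }
  tibble(query = queries, seq = queries) |>
    dplyr::inner_join(idx, by = "seq", relationship = "many-to-many") |>
    dplyr::mutate(mismatches = 0L) |>
    dplyr::select(query, target_id, start, end, mismatches)
}

.align_mismatch <- function(queries, targets, max_mismatches) {
  out <- list()
  for (tid in names(targets)) {
    subj <- Biostrings::DNAString(targets[[tid]])
    for (q in queries) {
      if (nchar(q) > length(subj)) next
      mt <- Biostrings::matchPattern(q, subj, max.mismatch = max_mismatches)
      if (!length(mt)) next
      mm <- Biostrings::neditStartingAt(q, subj,
                                        starting.at = Biostrings::start(mt),
                                        with.indels = FALSE)
      out[[length(out) + 1L]] <- tibble(
        query = q, target_id = tid,
        start = Biostrings::start(mt) - 1L,
        end = Biostrings::end(mt),
        mismatches = mm)
    }
  }
  dplyr::bind_rows(out) %||% tibble(query = character(0))
}

`%||%` <- function(x, y) if (is.null(x) || (is.data.frame(x) && !nrow(x))) y else x

#' Distribute multi-mapper weight across hits
#'
#' A read with `k` admissible hits contributes weight `1/k` to each, so
#' per-read weights sum to 1 for every mapped read.
#'
#' @param hits hits tibble from [align_reads()].
#' @return hits with a `weight` column.
#' @export
weight_multimappers <- function(hits) {
  hits |>
    dplyr::add_count(read_id, name = ".k") |>
    dplyr::mutate(weight = 1 / .k) |>
    dplyr::select(-".k")
}
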