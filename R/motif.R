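IUPAC_CLASSES <- c(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]",
  B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")

iupac_to_regex <- function(motif) {
  letters <- strsplit(toupper(motif), "")[[1]]
  bad <- setdiff(letters, names(IUPAC_CLASSES))
  if (length(bad)) {
    abort(sprintf("invalid IUPAC symbol(s): %s", paste(bad, collapse = ", ")))
  }
  paste(IUPAC_CLASSES[letters], collapse = "")
}

#' Scan sequences for an IUPAC motif
#'
#' Deterministic scanning of miRNA sequences for a candidate export motif
#' (e.g. the hnRNP A2B1-bound `GGAG`, or `YCC` for U/CC). Sequences and
#' motif are normalized to the DNA alphabet (U = T), all overlapping
#' matches are reported, and `three_prime_window` restricts hits to those
#' ending within the final `k` nt of the sequence — the region where
#' export motifs of exosome-targeted miRNAs such as the miR-320 family
#' sit.
#'
#' @param seqs named character vector of sequences (RNA or DNA), or a
#'   tibble with `seq_id` and `sequence`.
#' @param motif IUPAC motif string.
#' @param three_prime_window `NULL` (anywhere) or window size `k >=`
#'   motif length.
#' @return tibble: `seq_id`, `motif`, `start` (0-based from 5'), `end`,
#'   `dist_from_3p` (sequence length minus match end), `match`.
#' @export
scan_motif <- function(seqs, motif, three_prime_window = NULL) {
  if (is.data.frame(seqs)) {
    seqs <- setNames(seqs$sequence, seqs$seq_id)
  }
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%04d", seq_along(seqs))
  seqs_dna <- to_dna(seqs)
  rx <- iupac_to_regex(to_dna(motif))
  mlen <- nchar(motif)
  if (!is.null(three_prime_window) && three_prime_window < mlen) {
    abort("`three_prime_window` must be >= motif length")
  }
  # lookahead: overlapping matches
  loc <- stringr::str_locate_all(seqs_dna, paste0("(?=(", rx, "))"))
  names(loc) <- names(seqs_dna)
  out <- purrr::imap(loc, function(l, id) {
    if (!nrow(l)) return(NULL)
    s <- unname(as.integer(l[, "start"]))
    tibble(seq_id = id, motif = motif, start = s - 1L, end = s - 1L + mlen,
           dist_from_3p = nchar(seqs_dna[[id]]) - (s - 1L + mlen),
           match = substr(seqs_dna[[id]], s, s + mlen - 1L))
  })
  out <- dplyr::bind_rows(out)
  if (!nrow(out)) {
    out <- tibble(seq_id = character(0), motif = character(0),
                  start = integer(0), end = integer(0),
                  dist_from_3p = integer(0), match = character(0))
  }
  if (!is.null(three_prime_window)) {
    # keep hits whose last matched base lies within the final k nt
    out <- out |> dplyr::filter(dist_from_3p < three_prime_window)
  }
  out
}

#' Motif enrichment between two sequence sets
#'
#' 2x2 contingency table (motif-bearing vs not, set A vs set B) and the
#' one-sided hypergeometric tail probability of seeing at least as many
#' motif-bearing sequences in set A under random assignment of the
#' motif-bearing sequences to the two sets.
#'
#' @param n_with_a,n_total_a motif-bearing and total sequences in set A.
#' @param n_with_b,n_total_b same for set B.
#' @return list with `table` (2x2 matrix) and `p_value`.
#' @export
motif_enrichment <- function(n_with_a, n_total_a, n_with_b, n_total_b) {
  if (n_total_a + n_total_b == 0) abort("empty universe")
  stopifnot(n_with_a <= n_total_a, n_with_b <= n_total_b)
  tab <- matrix(c(n_with_a, n_total_a - n_with_a,
                  n_with_b, n_total_b - n_with_b),
                nrow = 2, byrow = TRUE,
                dimnames = list(set = c("A", "B"),
                                motif = c("with", "without")))
  m <- n_with_a + n_with_b
  n <- (n_total_a - n_with_a) + (n_total_b - n_with_b)
  p <- phyper(n_with_a - 1, m, n, n_total_a, lower.tail = FALSE)
  list(table = tab, p_value = p)
}

#' Fraction of sequences bearing a motif, per set
#'
#' Convenience wrapper: scans each set and counts sequences with at least
#' one hit, feeding [motif_enrichment()].
#'
#' @param seqs_a,seqs_b named character vectors of sequences.
#' @param motif IUPAC motif.
#' @param three_prime_window optional 3' window (see [scan_motif()]).
#' @return list with per-set counts, the 2x2 `table` and `p_value`.
#' @export
motif_set_test <- function(seqs_a, seqs_b, motif, three_prime_window = NULL) {
  hits_a <- scan_motif(seqs_a, motif, three_prime_window)
  hits_b <- scan_motif(seqs_b, motif, three_prime_window)
  wa <- dplyr::n_distinct(hits_a$seq_id)
  wb <- dplyr::n_distinct(hits_b$seq_id)
  c(list(n_with_a = wa, n_total_a = length(seqs_a),
         n_with_b = wb, n_total_b = length(seqs_b)),
    motif_enrichment(wa, length(seqs_a), wb, length(seqs_b)))
}
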