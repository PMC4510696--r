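DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' @noRd
#' Convert RNA-space sequences to the DNA alphabet used internally.
to_dna <- function(x) {
  toupper(chartr("Uu", "Tt", x))
}

# 0-based half-open substring: seq[start, end)
substr0 <- function(x, start, end) {
  substr(x, start + 1L, end)
}

# vectorized longest common prefix length of two character vectors
lcp_len <- function(a, b) {
  n <- pmin(nchar(a), nchar(b))
  out <- integer(length(a))
  todo <- n > 0L
  k <- 0L
  while (any(todo)) {
    k <- k + 1L
    same <- todo & substr(a, k, k) == substr(b, k, k)
    out[same] <- k
    todo <- same & k < n
  }
  out
}

# Table of all substrings of `targets` at the given lengths, with 0-based
# start coordinates. Targets shorter than a length contribute nothing.
substring_index <- function(targets, lengths) {
  stopifnot(!is.null(names(targets)))
  lengths <- sort(unique(lengths))
  out <- vector("list", length(targets) * length(lengths))
  i <- 0L
  for (tid in names(targets)) {
    tlen <- nchar(targets[[tid]])
    for (L in lengths) {
      if (L < 1L || L > tlen) next
      starts <- 0:(tlen - L)
      i <- i + 1L
      out[[i]] <- tibble(
        target_id = tid,
        start = starts,
        end = starts + L,
        seq = substr0(rep(targets[[tid]], length(starts)), starts, starts + L)
      )
    }
  }
  dplyr::bind_rows(out[seq_len(i)])
}

assert_fraction <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must lie in [0, 1]", name))
  }
  invisible(x)
}
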