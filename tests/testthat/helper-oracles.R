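# Independent brute-force oracles used across the suite. These deliberately
# use the slowest possible formulation (exhaustive enumeration, closed
# formulas) and never share code with the implementation.

# Adapter occurrence by exhaustive enumeration: for every start position,
# every segment end (full internal match) and every adapter prefix length
# (suffix overlap), score with utils::adist and apply the error-rate rule.
# Returns the 1-based start of the best occurrence or NA.
oracle_adapter_start <- function(read, adapter, rate = 0.1, min_overlap = 3) {
  n <- nchar(read); m <- nchar(adapter)
  best_cost <- Inf; best_start <- NA_integer_
  for (j in seq_len(n)) {
    costs <- c()
    for (e in j:n) {
      costs <- c(costs, c(utils::adist(adapter, substr(read, j, e)), m))
    }
    if (m - 1 >= min_overlap) {
      for (i in min_overlap:(m - 1)) {
        costs <- c(costs,
                   c(utils::adist(substr(adapter, 1, i), substr(read, j, n)), i))
      }
    }
    costs <- matrix(costs, ncol = 2, byrow = TRUE)
    ok <- costs[, 1] <= floor(rate * costs[, 2])
    if (any(ok)) {
      cst <- min(costs[ok, 1])
      if (cst < best_cost) {
        best_cost <- cst
        best_start <- j
      }
    }
  }
  best_start
}

oracle_trim <- function(read, adapter, rate = 0.1, min_overlap = 3) {
  j <- oracle_adapter_start(read, adapter, rate, min_overlap)
  if (is.na(j)) read else substr(read, 1, j - 1)
}

# Exact alignment by naive substring scan over every position and strand.
oracle_align <- function(query, targets, strands = c("+", "-")) {
  out <- list()
  rc <- function(s) {
    paste(rev(chartr("ACGT", "TGCA", strsplit(s, "")[[1]])), collapse = "")
  }
  for (tid in names(targets)) {
    t <- targets[[tid]]
    for (s in strands) {
      q <- if (s == "+") query else rc(query)
      L <- nchar(q)
      if (L > nchar(t)) next
      for (i in 1:(nchar(t) - L + 1)) {
        if (substr(t, i, i + L - 1) == q) {
          out[[length(out) + 1]] <- data.frame(
            target_id = tid, start = i - 1L, end = i - 1L + L, strand = s)
        }
      }
    }
  }
  do.call(rbind, out)
}

# Spearman correlation from the explicit rank formula (average ranks).
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# One-sided hypergeometric upper tail by explicit enumeration with choose().
oracle_hyper_p <- function(k_obs, n_with, n_without, draws) {
  ks <- max(0, draws - n_without):min(draws, n_with)
  probs <- choose(n_with, ks) * choose(n_without, draws - ks) /
    choose(n_with + n_without, draws)
  sum(probs[ks >= k_obs])
}

# Seven-region partition from per-element membership patterns.
oracle_partition_region <- function(in_a, in_b, in_c, names_abc) {
  members <- names_abc[c(in_a, in_b, in_c)]
  if (length(members) == 3) {
    paste(names_abc[c(1, 3, 2)], collapse = "&")
  } else if (length(members) == 2) {
    if (in_a && in_b) paste(names_abc[1], names_abc[2], sep = "&")
    else if (in_a && in_c) paste(names_abc[1], names_abc[3], sep = "&")
    else paste(names_abc[3], names_abc[2], sep = "&")
  } else {
    members
  }
}

# small deterministic reference shared by several tests
tiny_ref <- function(seed = 42, ...) {
  sim_reference(n_hairpins = 6, seed = seed, ...)
}
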