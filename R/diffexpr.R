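#' Build a weighted miRNA count matrix
#'
#' Sums multi-mapper weights of miRNA-annotated reads into a mature x
#' sample matrix; fractional counts are expected. Samples with zero miRNA
#' reads are retained as zero columns with a warning.
#'
#' @param annotated tibble of annotated reads across samples: needs
#'   `sample`, `mature_id`, `weight` columns (e.g. the row-bound outputs
#'   of [annotate_reads()] filtered to `category == "miRNA"`, or isomiR
#'   calls).
#' @param samples metadata tibble with a `sample` column (e.g. cell line,
#'   compartment, replicate); defines the column order and the retained
#'   zero columns.
#' @return an `exo_counts`: list with `counts` matrix and `samples`
#'   metadata. [tidy()] returns the long form.
#' @export
build_counts <- function(annotated, samples) {
  stopifnot(all(c("sample", "mature_id", "weight") %in% names(annotated)),
            "sample" %in% names(samples))
  if (anyDuplicated(samples$sample)) abort("duplicate sample ids")
  long <- annotated |>
    dplyr::filter(!is.na(mature_id)) |>
    dplyr::group_by(sample, mature_id) |>
    dplyr::summarise(count = sum(weight), .groups = "drop")
  mirnas <- sort(unique(long$mature_id))
  mat <- matrix(0, length(mirnas), nrow(samples),
                dimnames = list(mirnas, samples$sample))
  mat[cbind(match(long$mature_id, mirnas), match(long$sample, samples$sample))] <-
    long$count
  zero <- colSums(mat) == 0
  if (any(zero)) {
    warn(sprintf("sample(s) with zero miRNA reads retained as zero columns: %s",
                 paste(names(zero)[zero], collapse = ", ")))
  }
  structure(list(counts = mat, samples = samples), class = "exo_counts")
}

#' @export
print.exo_counts <- function(x, ...) {
  cat(sprintf("<exo_counts> %d miRNAs x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' @export
tidy.exo_counts <- function(x, ...) {
  as_tibble(x$counts, rownames = "mature_id") |>
    tidyr::pivot_longer(-mature_id, names_to = "sample",
                        values_to = "count") |>
    dplyr::left_join(x$samples, by = "sample")
}

.count_matrix <- function(x) {
  if (inherits(x, "exo_counts")) x$counts else as.matrix(x)
}

#' Reads-per-million normalization
#'
#' Scales every sample column to sum to 1e6, preserving within-column
#' ratios.
#'
#' @param counts an `exo_counts` or a numeric matrix.
#' @return RPM matrix.
#' @export
rpm_normalize <- function(counts) {
  m <- .count_matrix(counts)
  cs <- colSums(m)
  if (any(cs == 0)) {
    abort(sprintf("zero total count in sample(s): %s",
                  paste(colnames(m)[cs == 0], collapse = ", ")))
  }
  sweep(m, 2, cs / 1e6, "/")
}

#' Trimmed mean of M-values normalization factors
#'
#' Between-sample scaling factors computed as the weighted mean of doubly
#' trimmed log2 expression ratios (M-values) against a reference sample:
#' for each sample, genes with positive counts in both members of the
#' pair contribute `M = log2((y/N) / (r/N_r))`, the upper and lower
#' `trim_m` of M-values and `trim_a` of average log expression (A-values)
#' are discarded, and the remainder are averaged with inverse
#' approximate-variance weights. Factors are reported normalized to
#' geometric mean 1; a factor below 1 means the sample's counts are
#' scaled up. Pairs with fewer than 10 usable genes fall back to pure
#' library-size normalization (factor 1) with a warning.
#'
#' @param counts an `exo_counts` or matrix (>= 2 samples).
#' @param ref_sample reference sample id, or `NULL` to pick the sample
#'   whose upper-quartile expression is closest to the mean.
#' @param trim_m two-sided trim fraction on M-values (default 0.30).
#' @param trim_a two-sided trim fraction on A-values (default 0.05).
#' @return named vector of normalization factors.
#' @export
tmm_factors <- function(counts, ref_sample = NULL,
                        trim_m = 0.30, trim_a = 0.05) {
  m <- .count_matrix(counts)
  if (ncol(m) < 2) abort("TMM needs at least 2 samples")
  lib <- colSums(m)
  if (any(lib == 0)) abort("zero library size")
  if (is.null(ref_sample)) {
    f75 <- apply(m, 2, function(y) quantile(y[y > 0], 0.75)) / lib
    ref_sample <- colnames(m)[which.min(abs(f75 - mean(f75)))]
  }
  r <- m[, ref_sample]
  f <- setNames(rep(1, ncol(m)), colnames(m))
  for (s in colnames(m)) {
    if (s == ref_sample) next
    y <- m[, s]
    ok <- y > 0 & r > 0
    if (sum(ok) < 10) {
      warn(sprintf(
        "fewer than 10 usable genes for %s vs %s; library-size fallback",
        s, ref_sample))
      next
    }
    yp <- y[ok] / lib[s]
    rp <- r[ok] / lib[ref_sample]
    M <- log2(yp / rp)
    A <- 0.5 * (log2(yp) + log2(rp))
    v <- (lib[s] - y[ok]) / (lib[s] * y[ok]) +
      (lib[ref_sample] - r[ok]) / (lib[ref_sample] * r[ok])
    n <- length(M)
    loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
    keep <- rank(M, ties.method = "first") >= loM &
      rank(M, ties.method = "first") <= hiM &
      rank(A, ties.method = "first") >= loA &
      rank(A, ties.method = "first") <= hiA
    if (!any(keep)) keep <- rep(TRUE, n)
    f[s] <- 2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
  }
  f / exp(mean(log(f)))
}

# per-sample scaling combining library size and TMM factor, geometric
# mean 1, so normalized counts stay on the counting scale
.size_factors <- function(m, norm_factors = NULL) {
  lib <- colSums(m)
  if (is.null(norm_factors)) norm_factors <- tmm_factors(m)
  s <- lib * norm_factors[colnames(m)]
  s / exp(mean(log(s)))
}

#' Estimate per-miRNA negative-binomial dispersion
#'
#' Method-of-moments gene-wise dispersion `alpha = max(0, (s^2 - mu) /
#' mu^2)` on normalized counts, with the variance pooled across all
#' replicated conditions (`method = "pooled"`) or estimated within each
#' condition and maximized (`method = "per-condition"`). A local
#' regression of log dispersion on log mean supplies a mean-dispersion
#' trend, and the final value is the maximum of the gene-wise estimate
#' and the trend — deliberately conservative for low-replicate designs.
#'
#' @param counts an `exo_counts` or matrix.
#' @param groups factor/character vector of condition labels per sample.
#' @param method `"pooled"` or `"per-condition"`.
#' @param norm_factors optional TMM factors (computed if missing).
#' @return tibble: `mature_id`, `mean`, `dispersion_genewise`,
#'   `dispersion_trend`, `dispersion`.
#' @export
estimate_dispersion <- function(counts, groups,
                                method = c("pooled", "per-condition"),
                                norm_factors = NULL) {
  method <- match.arg(method)
  m <- .count_matrix(counts)
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(m))
  reps <- table(groups)
  if (!any(reps >= 2)) {
    abort("no replicated condition: supply a fixed dispersion instead")
  }
  q <- sweep(m, 2, .size_factors(m, norm_factors), "/")
  mu <- rowMeans(q)

  if (method == "pooled") {
    # pooled within-condition variance across all samples
    ss <- 0; df <- 0
    for (g in names(reps)) {
      if (reps[[g]] < 2) next
      qg <- q[, groups == g, drop = FALSE]
      ss <- ss + rowSums((qg - rowMeans(qg))^2)
      df <- df + reps[[g]] - 1
    }
    s2 <- ss / df
    a_gene <- ifelse(mu > 0, pmax(0, (s2 - mu) / mu^2), 0)
  } else {
    a_gene <- rep(0, nrow(q))
    for (g in names(reps)) {
      if (reps[[g]] < 2) next
      qg <- q[, groups == g, drop = FALSE]
      mug <- rowMeans(qg)
      s2g <- apply(qg, 1, var)
      ag <- ifelse(mug > 0, pmax(0, (s2g - mug) / mug^2), 0)
      a_gene <- pmax(a_gene, ag)
    }
  }

  pos <- a_gene > 0 & mu > 0
  if (sum(pos) >= 5) {
    fit <- lowess(log(mu[pos]), log(a_gene[pos]), f = 2 / 3)
    a_trend <- exp(approx(fit$x, fit$y, xout = log(pmax(mu, min(mu[mu > 0]))),
                          rule = 2, ties = mean)$y)
  } else {
    a_trend <- rep(if (any(pos)) median(a_gene[pos]) else 0, length(mu))
  }
  tibble(mature_id = rownames(m), mean = mu,
         dispersion_genewise = a_gene, dispersion_trend = a_trend,
         dispersion = pmax(a_gene, a_trend))
}

#' Negative-binomial two-group test per miRNA
#'
#' Compares normalized counts between exactly two groups. For each miRNA,
#' small-count cases (rounded group-sum total <= `exact_max_total`) use a
#' sum-conditioned exact NB test: conditional on the total, the two-sided
#' p-value sums the probabilities of all splits at most as likely as the
#' observed one; larger totals use a Wald test on the log2 group means
#' with NB (delta-method) variance. Fold changes are computed on
#' normalized group means with a pseudocount; p-values get
#' Benjamini-Hochberg adjustment across tested miRNAs. miRNAs with zero
#' counts everywhere are reported untested (`NA` p-value).
#'
#' @param counts an `exo_counts` or matrix.
#' @param groups two-level factor/character per sample; the fold change is
#'   `log2(first level / second level)` with the first level taken from
#'   `contrast` (default: sorted unique order).
#' @param dispersions tibble from [estimate_dispersion()] or named vector
#'   of per-miRNA dispersions; computed (pooled) when missing.
#' @param contrast optional length-2 character giving (numerator,
#'   denominator) group labels.
#' @param norm_factors optional TMM factors.
#' @param exact_max_total largest conditioned total for the exact test.
#' @param pseudocount added to group means for the fold change.
#' @return an `exo_enrichment` tibble: `mature_id`, `base_mean`,
#'   `log2_fold_change`, `dispersion`, `p_value`, `fdr`, `test`.
#' @export
nb_test <- function(counts, groups, dispersions = NULL, contrast = NULL,
                    norm_factors = NULL, exact_max_total = 5000,
                    pseudocount = 0.5) {
  m <- .count_matrix(counts)
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(m))
  levs <- unique(groups)
  if (length(levs) != 2) abort("exactly two groups required per contrast")
  if (!is.null(contrast)) {
    stopifnot(all(contrast %in% levs), length(contrast) == 2)
    levs <- contrast
  } else {
    levs <- sort(levs)
  }
  if (is.null(dispersions)) {
    dispersions <- estimate_dispersion(m, groups, norm_factors = norm_factors)
  }
  disp <- if (is.data.frame(dispersions)) {
    setNames(dispersions$dispersion, dispersions$mature_id)[rownames(m)]
  } else {
    dispersions[rownames(m)]
  }
  q <- sweep(m, 2, .size_factors(m, norm_factors), "/")
  ia <- groups == levs[1]; ib <- groups == levs[2]
  na <- sum(ia); nb <- sum(ib)
  qa <- q[, ia, drop = FALSE]; qb <- q[, ib, drop = FALSE]
  mean_a <- rowMeans(qa); mean_b <- rowMeans(qb)
  base_mean <- rowMeans(q)
  lfc <- log2((mean_a + pseudocount) / (mean_b + pseudocount))

  p <- rep(NA_real_, nrow(m))
  test <- rep(NA_character_, nrow(m))
  for (i in seq_len(nrow(m))) {
    ka <- round(sum(qa[i, ])); kb <- round(sum(qb[i, ]))
    S <- ka + kb
    if (S == 0) next
    a <- disp[i]
    if (S <= exact_max_total) {
      p[i] <- .nb_exact_p(ka, kb, na, nb, a)
      test[i] <- "exact"
    } else {
      v <- (mean_a[i] + a * mean_a[i]^2) / na /
        ((mean_a[i] + pseudocount)^2 * log(2)^2) +
        (mean_b[i] + a * mean_b[i]^2) / nb /
        ((mean_b[i] + pseudocount)^2 * log(2)^2)
      z <- lfc[i] / sqrt(v)
      p[i] <- 2 * pnorm(-abs(z))
      test[i] <- "wald"
    }
  }
  fdr <- rep(NA_real_, length(p))
  fdr[!is.na(p)] <- p.adjust(p[!is.na(p)], method = "BH")
  out <- tibble(mature_id = rownames(m), base_mean = unname(base_mean),
                log2_fold_change = unname(lfc), dispersion = unname(disp),
                p_value = p, fdr = fdr, test = test)
  class(out) <- c("exo_enrichment", class(out))
  out
}

# sum-conditioned exact NB test: under the null both group sums share one
# mean per sample; enumerate all splits of the conditioned total
.nb_exact_p <- function(ka, kb, na, nb, alpha) {
  S <- ka + kb
  mu <- S / (na + nb)
  ks <- 0:S
  if (is.na(alpha) || alpha <= 0) {
    pa <- dpois(ks, na * mu)
    pb <- dpois(S - ks, nb * mu)
  } else {
    pa <- dnbinom(ks, mu = na * mu, size = na / alpha)
    pb <- dnbinom(S - ks, mu = nb * mu, size = nb / alpha)
  }
  pk <- pa * pb
  tot <- sum(pk)
  if (tot == 0) return(1)
  pobs <- pk[ka + 1]
  min(1, sum(pk[pk <= pobs * (1 + 1e-7)]) / tot)
}

#' Call enriched miRNAs at fold-change and FDR thresholds
#'
#' Boundary-inclusive calling: `|log2 fold change| >= lfc_min` and
#' `fdr <= fdr_max`. Positive fold changes are called in the numerator
#' direction (`"exosome-enriched"` for an exosome-vs-cell contrast),
#' negative in the denominator direction.
#'
#' @param results an `exo_enrichment` from [nb_test()].
#' @param lfc_min minimum absolute log2 fold change (default 1).
#' @param fdr_max maximum FDR (default 0.001).
#' @param labels length-2 labels for the positive / negative directions.
#' @return `results` with a `call` column (`labels[1]`, `labels[2]` or
#'   `"not-called"`).
#' @export
call_enriched <- function(results, lfc_min = 1, fdr_max = 0.001,
                          labels = c("exosome-enriched", "cell-enriched")) {
  results |>
    dplyr::mutate(call = dplyr::case_when(
      !is.na(fdr) & fdr <= fdr_max & log2_fold_change >= lfc_min ~ labels[1],
      !is.na(fdr) & fdr <= fdr_max & log2_fold_change <= -lfc_min ~ labels[2],
      TRUE ~ "not-called"))
}

#' @export
glance.exo_enrichment <- function(x, ...) {
  tibble(n_mirnas = nrow(x),
         n_tested = sum(!is.na(x$p_value)),
         n_called = if ("call" %in% names(x)) sum(x$call != "not-called")
                    else NA_integer_)
}

#' Seven-region partition of three enriched sets
#'
#' Splits three named miRNA sets into the standard seven regions of a
#' three-set partition: unique to each set, each pairwise-only
#' intersection, and the triple intersection. Regions are disjoint and
#' their union is the union of the input sets.
#'
#' @param sets named list of exactly three character vectors.
#' @return an `exo_partition` tibble (`category`, `mirna`);
#'   [partition_counts()] tabulates all seven regions.
#' @export
partition_sets <- function(sets) {
  stopifnot(length(sets) == 3, !is.null(names(sets)))
  nm <- names(sets)
  labs <- .partition_labels(nm)
  u <- unique(unlist(sets))
  inA <- u %in% sets[[1]]; inB <- u %in% sets[[2]]; inC <- u %in% sets[[3]]
  category <- dplyr::case_when(
    inA & inB & inC ~ labs[7],
    inA & inB ~ labs[4],
    inA & inC ~ labs[5],
    inC & inB ~ labs[6],
    inA ~ labs[1], inB ~ labs[2], inC ~ labs[3])
  out <- tibble(category = category, mirna = u) |>
    dplyr::arrange(factor(category, levels = labs), mirna)
  structure(out, class = c("exo_partition", class(out)), set_names = nm)
}

#' Per-category counts of a seven-region partition
#'
#' @param partition an `exo_partition` (from [partition_sets()] or
#'   [read_category_table()]).
#' @return tibble (`category`, `n`) listing all seven regions, including
#'   empty ones.
#' @export
partition_counts <- function(partition) {
  labs <- .partition_labels(attr(partition, "set_names"))
  cnt <- partition |> dplyr::count(category)
  tibble(category = labs) |>
    dplyr::left_join(cnt, by = "category") |>
    dplyr::mutate(n = ifelse(is.na(n), 0L, n))
}

#' Spearman correlation matrix between samples
#'
#' Rank-based correlation (average ranks on ties) between sample columns.
#' Constant columns yield `NA` entries and a warning; the diagonal is 1.
#'
#' @param mat expression matrix (features x samples), e.g. RPM or
#'   TMM-normalized counts.
#' @return symmetric correlation matrix.
#' @export
spearman_matrix <- function(mat) {
  mat <- .count_matrix(mat)
  if (nrow(mat) < 3) abort("need at least 3 features")
  const <- apply(mat, 2, function(x) length(unique(x)) == 1)
  r <- suppressWarnings(cor(mat, method = "spearman"))
  if (any(const)) {
    warn(sprintf("constant sample(s) give undefined correlations: %s",
                 paste(colnames(mat)[const], collapse = ", ")))
  }
  diag(r) <- 1
  r
}

#' Principal component analysis of samples
#'
#' PCA of log-transformed (pseudocount) expression, samples as
#' observations, via singular value decomposition of the centered matrix.
#' The sign of each component is fixed so the largest-magnitude loading
#' is positive, making scores reproducible across platforms.
#'
#' @param mat expression matrix (features x samples).
#' @param log2_transform log2(x + pseudocount) before decomposition.
#' @param pseudocount added before the log (default 1).
#' @param center center features (default TRUE).
#' @param n_components components to keep (truncated with a warning if
#'   more than `n_samples - 1` are requested).
#' @return an `exo_pca`: list with `scores` tibble, `var_explained`,
#'   `rotation`. [tidy()] returns scores, [glance()] the variance
#'   fractions.
#' @export
pca_samples <- function(mat, log2_transform = TRUE, pseudocount = 1,
                        center = TRUE, n_components = 2) {
  mat <- .count_matrix(mat)
  if (ncol(mat) < 2) abort("need at least 2 samples")
  x <- t(if (log2_transform) log2(mat + pseudocount) else mat)
  keep <- apply(x, 2, function(v) var(v) > 0)
  pc <- prcomp(x[, keep, drop = FALSE], center = center, scale. = FALSE)
  k_max <- ncol(pc$x)
  if (n_components > k_max) {
    warn(sprintf("only %d component(s) available; truncating", k_max))
    n_components <- k_max
  }
  for (k in seq_len(ncol(pc$rotation))) {
    j <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[j, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- as_tibble(pc$x[, seq_len(n_components), drop = FALSE],
                      rownames = "sample")
  out <- list(scores = scores, var_explained = ve, rotation = pc$rotation,
              prcomp = pc)
  class(out) <- "exo_pca"
  out
}

#' @export
tidy.exo_pca <- function(x, ...) x$scores

#' @export
glance.exo_pca <- function(x, ...) {
  tibble(component = seq_along(x$var_explained),
         var_explained = x$var_explained)
}

#' @export
print.exo_pca <- function(x, ...) {
  cat(sprintf("<exo_pca> %d samples; PC1 %.1f%%, PC2 %.1f%% variance\n",
              nrow(x$scores), 100 * x$var_explained[1],
              100 * ifelse(length(x$var_explained) > 1,
                           x$var_explained[2], 0)))
  invisible(x)
}
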