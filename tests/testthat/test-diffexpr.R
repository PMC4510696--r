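mk_counts <- function(mat, groups = NULL) {
  samples <- tibble::tibble(sample = colnames(mat))
  if (!is.null(groups)) samples$group <- groups
  structure(list(counts = mat, samples = samples), class = "exo_counts")
}

test_that("count building sums weights and conserves totals", {
  ann <- tibble::tibble(
    sample = c(rep("s1", 11), "s2"),
    mature_id = c(rep("mirA", 10), "mirB", "mirA"),
    weight = c(rep(1, 10), 0.5, 0.5))
  samples <- tibble::tibble(sample = c("s1", "s2", "s3"))
  expect_warning(cm <- build_counts(ann, samples), "zero")
  expect_equal(cm$counts["mirA", "s1"], 10)
  expect_equal(cm$counts["mirB", "s1"], 0.5)
  expect_equal(sum(cm$counts), sum(ann$weight))
  expect_equal(unname(colSums(cm$counts)["s3"]), 0)
  # tidy() round-trips the matrix
  td <- tidy(cm)
  expect_equal(sum(td$count), sum(ann$weight))
})

test_that("RPM scales columns to one million and preserves ratios", {
  m <- matrix(c(5, 5, 30, 10), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  r <- rpm_normalize(m)
  expect_equal(unname(r[, "s1"]), c(5e5, 5e5))
  expect_equal(unname(colSums(r)), c(1e6, 1e6), tolerance = 1e-6)
  expect_equal(r["a", "s2"] / r["b", "s2"], 3)
  m0 <- m; m0[, 2] <- 0
  expect_error(rpm_normalize(m0), "s2")
})

test_that("TMM factors behave like trimmed M-value means", {
  set.seed(61)
  base <- rlnorm(300, log(100), 1.2)
  m <- cbind(s1 = round(base), s2 = round(base))
  rownames(m) <- sprintf("g%03d", 1:300)
  f_same <- tmm_factors(m)
  expect_equal(unname(f_same), c(1, 1), tolerance = 1e-12)

  # pure depth difference: all M = 0 after library-size accounting
  m2 <- cbind(s1 = round(base), s2 = 2 * round(base))
  expect_equal(unname(tmm_factors(m2)), c(1, 1), tolerance = 1e-9)

  # robustness: 5% wildly deviating genes barely move the *effective*
  # scaling (library size x factor); the trimmed mean absorbs them
  m3 <- m2
  idx <- sample(300, 15)
  m3[idx, 2] <- m3[idx, 2] * 50
  eff2 <- colSums(m2) * tmm_factors(m2)
  eff3 <- colSums(m3) * tmm_factors(m3)
  expect_lt(abs((eff3[["s2"]] / eff3[["s1"]]) /
                  (eff2[["s2"]] / eff2[["s1"]]) - 1), 0.01)

  # invariance to global depth rescaling of one sample (up to the
  # depth-dependent precision weights)
  m4 <- cbind(m, s3 = round(base * rlnorm(300, 0, 0.1)))
  f_a <- tmm_factors(m4, ref_sample = "s1")
  m5 <- m4; m5[, "s3"] <- m5[, "s3"] * 7
  f_b <- tmm_factors(m5, ref_sample = "s1")
  expect_equal(unname(f_a), unname(f_b), tolerance = 0.005)
})

test_that("TMM factors agree with the established implementation", {
  skip_if_not_installed("edgeR")
  set.seed(62)
  mu <- rlnorm(400, log(80), 1.3)
  m <- sapply(1:4, function(i) rpois(400, mu * c(1, 1.5, 0.8, 1.2)[i]))
  dimnames(m) <- list(sprintf("g%03d", 1:400), sprintf("s%d", 1:4))
  ours <- tmm_factors(m, ref_sample = "s1")
  theirs <- edgeR::calcNormFactors(m, method = "TMM", refColumn = 1)
  theirs <- theirs / exp(mean(log(theirs)))
  expect_equal(unname(ours), unname(theirs), tolerance = 0.02)
})

test_that("dispersion estimation recovers simulated parameters", {
  set.seed(63)
  n <- 10
  groups <- rep(c("A", "B"), each = n / 2)
  # Poisson data: dispersion ~ 0
  m_pois <- matrix(rpois(500 * n, 100), 500, n,
                   dimnames = list(sprintf("g%03d", 1:500),
                                   sprintf("s%d", 1:n)))
  d_pois <- estimate_dispersion(m_pois, groups,
                                norm_factors = setNames(rep(1, n),
                                                        colnames(m_pois)))
  expect_lt(median(d_pois$dispersion_genewise), 0.01)

  # NB alpha = 0.2
  m_nb <- matrix(rnbinom(500 * n, mu = 100, size = 5), 500, n,
                 dimnames = dimnames(m_pois))
  d_nb <- estimate_dispersion(m_nb, groups,
                              norm_factors = setNames(rep(1, n),
                                                      colnames(m_nb)))
  expect_gt(median(d_nb$dispersion_genewise), 0.1)
  expect_lt(median(d_nb$dispersion_genewise), 0.3)

  # constant counts: gene-wise alpha 0 before trend flooring
  m_const <- matrix(50, 20, n, dimnames = list(sprintf("c%02d", 1:20),
                                               colnames(m_pois)))
  d_const <- estimate_dispersion(m_const, groups,
                                 norm_factors = setNames(rep(1, n),
                                                         colnames(m_const)))
  expect_true(all(d_const$dispersion_genewise == 0))

  # per-condition takes the worse of the two conditions
  m_mix <- cbind(matrix(rpois(200 * 5, 100), 200, 5),
                 matrix(rnbinom(200 * 5, mu = 100, size = 2), 200, 5))
  dimnames(m_mix) <- dimnames(m_pois[1:200, ])
  d_pc <- estimate_dispersion(m_mix, groups, method = "per-condition",
                              norm_factors = setNames(rep(1, n),
                                                      colnames(m_mix)))
  expect_gt(median(d_pc$dispersion_genewise), 0.2)

  expect_error(estimate_dispersion(m_pois[, 1:2], c("A", "B")),
               "replicated")
})

test_that("NB test is calibrated under the null and detects 4-fold shifts", {
  set.seed(64)
  n <- 3; a <- 0.1; ngene <- 3000
  m0 <- cbind(matrix(rnbinom(ngene * n, mu = 100, size = 1 / a), ngene),
              matrix(rnbinom(ngene * n, mu = 100, size = 1 / a), ngene))
  dimnames(m0) <- list(sprintf("g%05d", 1:ngene),
                       c(paste0("A", 1:n), paste0("B", 1:n)))
  groups <- rep(c("A", "B"), each = n)
  disp <- setNames(rep(a, ngene), rownames(m0))
  res0 <- nb_test(m0, groups, disp, contrast = c("A", "B"))
  frac <- mean(res0$p_value < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / ngene))

  # symmetric 4-fold changes: power at FDR 0.05
  nt <- 300
  mu_a <- c(rep(100, 1500), rep(200, nt), rep(50, nt))
  mu_b <- c(rep(100, 1500), rep(50, nt), rep(200, nt))
  mp <- cbind(sapply(1:n, function(i) rnbinom(length(mu_a), mu = mu_a, size = 1 / a)),
              sapply(1:n, function(i) rnbinom(length(mu_b), mu = mu_b, size = 1 / a)))
  dimnames(mp) <- list(sprintf("t%05d", seq_along(mu_a)), colnames(m0))
  resp <- nb_test(mp, groups,
                  setNames(rep(a, nrow(mp)), rownames(mp)),
                  contrast = c("A", "B"))
  istrue <- seq_along(mu_a) > 1500
  power <- mean(resp$fdr[istrue] <= 0.05 &
                  sign(resp$log2_fold_change[istrue]) ==
                  rep(c(1, -1), each = nt))
  expect_gt(power, 0.8)

  # identical group means with tiny counts: p near 1
  m_eq <- matrix(c(5, 5, 5, 5, 5, 5), 1, 6,
                 dimnames = list("g1", colnames(m0)))
  r_eq <- nb_test(m_eq, groups, setNames(0, "g1"), contrast = c("A", "B"),
                  norm_factors = setNames(rep(1, 6), colnames(m0)))
  expect_equal(r_eq$p_value, 1, tolerance = 1e-9)
  expect_equal(r_eq$log2_fold_change, 0)

  # all-zero miRNAs are reported untested
  m_z <- rbind(m0[1:5, ], zero = 0)
  r_z <- nb_test(m_z, groups, setNames(rep(a, 6), rownames(m_z)),
                 contrast = c("A", "B"),
                 norm_factors = setNames(rep(1, 6), colnames(m0)))
  expect_true(is.na(r_z$p_value[r_z$mature_id == "zero"]))
})

test_that("enrichment calls are boundary-inclusive with signed directions", {
  res <- tibble::tibble(
    mature_id = c("a", "b", "c", "d"),
    base_mean = 100, dispersion = 0.1, test = "exact",
    log2_fold_change = c(1.0, 0.99, -1.5, 3),
    p_value = c(1e-5, 1e-10, 1e-5, 0.5),
    fdr = c(0.001, 1e-9, 1e-4, 0.9))
  class(res) <- c("exo_enrichment", class(res))
  called <- call_enriched(res)
  expect_equal(called$call,
               c("exosome-enriched", "not-called", "cell-enriched",
                 "not-called"))
})

test_that("seven-region partition matches brute force on the membership lattice", {
  nm <- c("DKO-1", "DKs-8", "DLD-1")
  # spec example
  p <- partition_sets(list(`DKO-1` = c("a", "b"), `DKs-8` = c("b", "c"),
                           `DLD-1` = "b"))
  cnt <- setNames(partition_counts(p)$n, partition_counts(p)$category)
  expect_equal(unname(cnt["DKO-1&DLD-1&DKs-8"]), 1)
  expect_equal(unname(cnt["DKO-1"]), 1)
  expect_equal(unname(cnt["DKs-8"]), 1)
  expect_equal(sum(cnt), 3)

  # identical sets -> all in the triple intersection
  p2 <- partition_sets(setNames(list(letters[1:4], letters[1:4],
                                     letters[1:4]), nm))
  c2 <- partition_counts(p2)
  expect_equal(c2$n[c2$category == "DKO-1&DLD-1&DKs-8"], 4)
  expect_equal(sum(c2$n), 4)

  # disjoint sets -> only unique regions
  p3 <- partition_sets(setNames(list("x", "y", "z"), nm))
  c3 <- partition_counts(p3)
  expect_equal(c3$n[match(nm, c3$category)], c(1, 1, 1))
  expect_equal(sum(c3$n), 3)

  # exhaustive: one element per non-empty membership pattern, all 2^6
  # two-element combinations implicitly covered by pattern independence
  pats <- expand.grid(a = c(TRUE, FALSE), b = c(TRUE, FALSE),
                      c = c(TRUE, FALSE))
  pats <- pats[rowSums(pats) > 0, ]
  els <- sprintf("e%d", seq_len(nrow(pats)))
  sets <- setNames(list(els[pats$a], els[pats$b], els[pats$c]), nm)
  p4 <- partition_sets(sets)
  for (i in seq_len(nrow(pats))) {
    want <- oracle_partition_region(pats$a[i], pats$b[i], pats$c[i], nm)
    expect_equal(p4$category[p4$mirna == els[i]], want)
  }
  # disjointness and union
  expect_equal(sort(p4$mirna), sort(els))
})

test_that("published table partitions reproduce the footnote counts", {
  t1 <- partition_counts(
    structure(exo_table_cells(), class = c("exo_partition", "tbl_df",
                                           "tbl", "data.frame"),
              set_names = c("DKO-1", "DKs-8", "DLD-1")))
  cnt1 <- setNames(t1$n, t1$category)
  expect_equal(unname(cnt1[c("DKO-1&DLD-1&DKs-8", "DKO-1", "DKs-8", "DLD-1")]),
               c(25, 39, 13, 15))
  t2c <- exo_table_exosomes() |> dplyr::count(category)
  cnt2 <- setNames(t2c$n, t2c$category)
  expect_equal(unname(cnt2[c("DKO-1&DLD-1&DKs-8", "DKO-1", "DKs-8", "DLD-1")]),
               c(29, 94, 10, 6))
})

test_that("Spearman matrix matches the rank-formula oracle", {
  set.seed(65)
  m <- matrix(rlnorm(20 * 4), 20, 4,
              dimnames = list(NULL, paste0("s", 1:4)))
  r <- spearman_matrix(m)
  expect_equal(diag(r), setNames(rep(1, 4), paste0("s", 1:4)))
  expect_equal(r, t(r))
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(r[i, j], oracle_spearman(m[, i], m[, j]), tolerance = 1e-12)
  }
  # perfect anti-ranking
  m2 <- cbind(a = 1:10, b = 10:1, c = rnorm(10))
  expect_equal(spearman_matrix(m2)["a", "b"], -1)
  expect_warning(spearman_matrix(cbind(m, const = 1)), "constant")
})

test_that("PCA separates constructed clusters and reconstructs the data", {
  set.seed(66)
  prof1 <- rlnorm(100, log(50), 1)
  prof2 <- prof1 * 2^(sample(c(-2, 2), 100, TRUE))
  m <- cbind(a1 = rpois(100, prof1), a2 = rpois(100, prof1),
             a3 = rpois(100, prof1),
             b1 = rpois(100, prof2), b2 = rpois(100, prof2),
             b3 = rpois(100, prof2))
  rownames(m) <- sprintf("g%03d", 1:100)
  pc <- pca_samples(m)
  expect_gt(pc$var_explained[1], 0.9)
  pc1 <- setNames(pc$scores$PC1, pc$scores$sample)
  expect_true(max(pc1[1:3]) < min(pc1[4:6]) ||
                min(pc1[1:3]) > max(pc1[4:6]))
  # variance fractions sorted, sum to 1
  expect_true(all(diff(pc$var_explained) <= 1e-12))
  expect_equal(sum(pc$var_explained), 1, tolerance = 1e-9)
  # reconstruction from all components
  x <- t(log2(m + 1))
  keep <- apply(x, 2, var) > 0
  rec <- pc$prcomp$x %*% t(pc$prcomp$rotation)
  cent <- scale(x[, keep], center = TRUE, scale = FALSE)
  attr(cent, "scaled:center") <- NULL
  expect_equal(unname(rec), unname(cent), tolerance = 1e-9)
  expect_warning(pca_samples(m[, 1:2], n_components = 5), "truncating")
})

test_that("pipeline recovers simulated exosome-sorted miRNAs end to end", {
  ref <- sim_reference(n_hairpins = 30, seed = 41)
  nm <- ref$matures$mature_id
  exported <- setNames(rep(c(2, 3), 5), nm[seq(1, 20, 2)])
  ex <- sim_experiment(ref, export_log2_bias = exported, genotypes = "WT",
                       n_rep = 3, read_count = 6000, seed = 43,
                       templated_frac = 0)
  ann <- purrr::imap(ex$libraries, function(lib, id) {
    tr <- filter_min_length(trim_adapters(lib$reads, "AGATCGGAAGAGC"))
    h <- align_reads(tr, c(toygenome = ref$genome), 0) |>
      weight_multimappers()
    annotate_reads(h, ref) |>
      dplyr::filter(category == "miRNA") |>
      dplyr::mutate(sample = id)
  })
  cm <- build_counts(dplyr::bind_rows(ann), ex$samples)
  res <- nb_test(cm, ex$samples$compartment, contrast = c("exosome", "cell"))
  called <- call_enriched(res)
  hits <- called$mature_id[called$call == "exosome-enriched"]
  expect_gte(mean(names(exported) %in% hits), 0.8)
  # false-call fraction among calls stays negligible
  expect_lte(sum(!hits %in% names(exported)), max(1, 0.005 * length(hits)))
})
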