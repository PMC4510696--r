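# helper: build reads directly from a reference mature with a chosen
# modification, bypassing the simulator
mk_read <- function(ref, mature_row, trim = 0, tail = "") {
  m <- ref$matures[mature_row, ]
  h <- ref$hairpins$sequence[match(m$hairpin_id, ref$hairpins$hairpin_id)]
  tibble::tibble(
    read_id = sprintf("t_%d_%s", trim, tail),
    sequence = paste0(substr(h, m$start + 1, m$end - trim), tail))
}

test_that("intact, trimmed and tailed reads are classified as constructed", {
  ref <- tiny_ref()
  m <- ref$matures[1, ]
  h <- ref$hairpins$sequence[match(m$hairpin_id, ref$hairpins$hairpin_id)]

  # intact: maps at round 0 with empty suffix
  calls <- classify_isomirs(mk_read(ref, 1), ref)
  expect_equal(calls$status, "intact")
  expect_equal(calls$rounds_used, 0)
  expect_equal(calls$trim_len, 0)
  expect_equal(calls$tail_seq, "")

  # trimmed by 2
  calls <- classify_isomirs(mk_read(ref, 1, trim = 2), ref)
  expect_equal(calls$status, "trimmed")
  expect_equal(calls$trim_len, 2)

  # pure NTA tail discordant with the hairpin continuation: pick a base
  # different from the continuation, repeated 3 times
  cont <- substr(h, m$end + 1, m$end + 1)
  bad <- setdiff(c("A", "C", "G", "T"), cont)[1]
  tail <- strrep(bad, 3)
  calls <- classify_isomirs(mk_read(ref, 1, tail = tail), ref)
  expect_equal(calls$status, "tailed")
  expect_equal(calls$rounds_used, 3)
  expect_equal(calls$tail_seq, tail)
  expect_equal(calls$nta_seq, tail)
  expect_equal(calls$tail_templated_len, 0)

  # trimmed + tailed
  cont2 <- substr(h, m$end - 2 + 1, m$end - 2 + 1)
  bad2 <- setdiff(c("A", "C", "G", "T"), cont2)[1]
  calls <- classify_isomirs(mk_read(ref, 1, trim = 2, tail = bad2), ref)
  expect_equal(calls$status, "trimmed+tailed")
  expect_equal(calls$trim_len, 2)
  expect_equal(calls$nta_seq, bad2)
})

test_that("reads with long discordant tails exhaust the trim rounds", {
  ref <- tiny_ref()
  m <- ref$matures[1, ]
  h <- ref$hairpins$sequence[match(m$hairpin_id, ref$hairpins$hairpin_id)]
  cont <- substr(h, m$end + 1, m$end + 1)
  bad <- setdiff(c("A", "C", "G", "T"), cont)[1]
  # 11 discordant nt cannot be removed in 10 rounds
  calls <- classify_isomirs(mk_read(ref, 1, tail = strrep(bad, 11)), ref,
                            rounds = 10, genome_screen = FALSE)
  expect_equal(unique(calls$disposition), "unclassified")
  # with 11 rounds it maps
  calls11 <- classify_isomirs(mk_read(ref, 1, tail = strrep(bad, 11)), ref,
                              rounds = 11, genome_screen = FALSE)
  expect_equal(unique(calls11$disposition), "classified")
})

test_that("genome-mapping non-miRNA reads are screened out", {
  ref <- tiny_ref()
  trna <- ref$features[ref$features$class == "tRNA", ][1, ]
  frag <- substr(ref$genome, trna$start + 1, trna$start + 22)
  calls <- classify_isomirs(
    tibble::tibble(read_id = "g1", sequence = frag), ref)
  expect_equal(calls$disposition, "non_miRNA")
})

test_that("resolve_tail splits templated and non-templated tail parts", {
  # constructed hairpin: mature [0, 8), continuation "CA..."
  hp <- "ACGTACGTCATTTTT"
  # mapped to canonical end, suffix "CA": continuation starts "C" -> 1 nt
  # templated, "A" non-templated (longest-common-prefix oracle: "CA" vs
  # "CATTTTT" shares "CA"... both match)
  res <- resolve_tail(hp, mature_end = 8, mapped_end = 8, suffix = "GA")
  expect_equal(res$tail_templated_len, 0)
  expect_equal(res$nta_seq, "GA")
  res2 <- resolve_tail(hp, mature_end = 8, mapped_end = 8, suffix = "CG")
  expect_equal(res2$tail_templated_len, 1)
  expect_equal(res2$nta_seq, "G")
  expect_equal(res2$status, "tailed")
  # mapped beyond the canonical end: overshoot is templated tail
  res3 <- resolve_tail(hp, mature_end = 8, mapped_end = 10, suffix = "")
  expect_equal(res3$trim_len, 0)
  expect_equal(res3$tail_seq, "CA")
  expect_equal(res3$tail_templated_len, 2)
  expect_equal(res3$nta_seq, "")
  # trimmed with empty suffix
  res4 <- resolve_tail(hp, mature_end = 8, mapped_end = 6, suffix = "")
  expect_equal(res4$trim_len, 2)
  expect_equal(res4$status, "trimmed")
  # invariant: |tail| = templated + |nta|
  for (r in list(res, res2, res3, res4)) {
    expect_equal(nchar(r$tail_seq), r$tail_templated_len + nchar(r$nta_seq))
  }
})

test_that("classifier recovers simulated trims and NTA tails", {
  ref <- sim_reference(n_hairpins = 12, seed = 31)
  prof <- sim_profile(ref, read_count = 4000, seed = 8, templated_frac = 0,
                      class_fracs = c(tRNA = 0.05), unmappable_frac = 0.02)
  lib <- sim_reads(ref, prof)
  tr <- filter_min_length(trim_adapters(lib$reads, prof$adapter))
  calls <- classify_isomirs(tr |> dplyr::select(read_id, sequence), ref)
  truth <- lib$truth |>
    dplyr::filter(class == "miRNA", expected_classifiable)
  joined <- dplyr::inner_join(
    calls |> dplyr::filter(disposition == "classified"),
    truth, by = "read_id")
  # every classifiable read classified, attribution correct
  expect_equal(nrow(joined), nrow(truth))
  expect_true(all(joined$mature_id.x == joined$mature_id.y))
  # exact (trim, NTA) recovery against the truth table
  expect_true(all(joined$trim_len.x == joined$expected_trim))
  expect_true(all(joined$nta_seq == joined$expected_nta))
  expect_gt(nrow(joined), 1000)
})

test_that("increasing rounds never declassifies reads", {
  ref <- tiny_ref()
  prof <- sim_profile(ref, read_count = 1500, seed = 21, templated_frac = 0)
  lib <- sim_reads(ref, prof)
  tr <- filter_min_length(trim_adapters(lib$reads, prof$adapter))
  n_classified <- vapply(c(0, 2, 5, 10), function(r) {
    calls <- classify_isomirs(tr |> dplyr::select(read_id, sequence), ref,
                              rounds = r)
    sum(calls$disposition == "classified")
  }, numeric(1))
  expect_true(all(diff(n_classified) >= 0))
})

test_that("classification dispositions partition the input reads", {
  ref <- tiny_ref()
  prof <- sim_profile(ref, read_count = 2000, seed = 23)
  lib <- sim_reads(ref, prof)
  tr <- filter_min_length(trim_adapters(lib$reads, prof$adapter))
  calls <- classify_isomirs(tr |> dplyr::select(read_id, sequence), ref)
  # per-read disposition is unique even with multiple hits
  per_read <- calls |> dplyr::distinct(read_id, disposition)
  expect_equal(nrow(per_read), dplyr::n_distinct(calls$read_id))
  expect_equal(dplyr::n_distinct(calls$read_id), nrow(tr))
})

test_that("trim/tail summary fractions are normalized and match truth", {
  ref <- tiny_ref()
  # trimming-only profile with 30% trimmed reads
  prof <- sim_profile(ref, read_count = 1e4, seed = 17,
                      trim_probs = c(0.7, 0.3), tail_probs = 1,
                      templated_frac = 0,
                      class_fracs = c(tRNA = 0), unmappable_frac = 0)
  lib <- sim_reads(ref, prof)
  tr <- filter_min_length(trim_adapters(lib$reads, prof$adapter))
  calls <- classify_isomirs(tr |> dplyr::select(read_id, sequence), ref)
  tt <- trim_tail_summary(calls)
  expect_equal(sum(tt$summary$fraction), 1, tolerance = 1e-9)
  trimmed_frac <- tt$summary$fraction[tt$summary$status == "trimmed"]
  expect_lt(abs(trimmed_frac - 0.3), 3 * sqrt(0.3 * 0.7 / 1e4))
  # all-intact simulation
  prof0 <- sim_profile(ref, read_count = 500, seed = 18,
                       trim_probs = 1, tail_probs = 1,
                       class_fracs = c(tRNA = 0), unmappable_frac = 0)
  lib0 <- sim_reads(ref, prof0)
  tr0 <- filter_min_length(trim_adapters(lib0$reads, prof0$adapter))
  tt0 <- trim_tail_summary(
    classify_isomirs(tr0 |> dplyr::select(read_id, sequence), ref))
  expect_equal(tt0$summary$status, "intact")
  expect_equal(tt0$summary$fraction, 1)
})

test_that("NTA profile honours composition, round cap and count threshold", {
  ref <- tiny_ref()
  # 100% 1-nt A-tails, non-templated
  prof <- sim_profile(ref, read_count = 3000, seed = 25,
                      trim_probs = 1, tail_probs = c(0, 1),
                      tail_nt_probs = c(A = 1, C = 0, G = 0, T = 0),
                      templated_frac = 0,
                      class_fracs = c(tRNA = 0), unmappable_frac = 0)
  lib <- sim_reads(ref, prof)
  tr <- filter_min_length(trim_adapters(lib$reads, prof$adapter))
  reads <- tr |> dplyr::select(read_id, sequence)
  np <- nta_profile(reads, ref, min_count = 0)
  a1 <- np$profile |> dplyr::filter(position == 1)
  expect_true(all(a1$nt == "A"))
  expect_true(all(a1$fraction == 1))

  # a read with a 4-nt discordant tail never maps within 3 trims
  m <- ref$matures[1, ]
  h <- ref$hairpins$sequence[match(m$hairpin_id, ref$hairpins$hairpin_id)]
  bad <- setdiff(c("A", "C", "G", "T"), substr(h, m$end + 1, m$end + 1))[1]
  r4 <- mk_read(ref, 1, tail = strrep(bad, 4))
  np4 <- nta_profile(r4, ref, min_count = 0)
  expect_equal(nrow(np4$profile), 0)

  # count threshold: matures below min_count in either compartment drop out
  reads$compartment <- rep(c("cell", "exosome"), length.out = nrow(reads))
  np_thr <- nta_profile(reads, ref, min_count = 1e6)
  expect_equal(nrow(np_thr$profile), 0)
  np_ok <- nta_profile(reads, ref, min_count = 1)
  expect_gt(nrow(np_ok$profile), 0)
})

test_that("5' offsets of canonical reads concentrate at zero", {
  ref <- tiny_ref()
  prof <- sim_profile(ref, read_count = 800, seed = 26,
                      class_fracs = c(tRNA = 0), unmappable_frac = 0)
  lib <- sim_reads(ref, prof)
  tr <- filter_min_length(trim_adapters(lib$reads, prof$adapter))
  calls <- classify_isomirs(tr |> dplyr::select(read_id, sequence), ref)
  off <- five_prime_offsets(calls, ref)
  expect_true(all(off$offset == 0))
  expect_true(all(abs(off$offset) <= 2))
  expect_true(all(off$fraction == 1))
})
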