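#' Classify 3' modification status of small-RNA reads
#'
#' Implements the iterative trim-and-remap procedure for isomiR calling.
#' Each adapter-trimmed read is first confronted with the hairpin
#' sequences (forward strand, exact matching); reads that fail are
#' screened once against the genome (both strands) and, if they map
#' there, are excluded from isomiR calling as non-miRNA. The remaining
#' reads are trimmed 1 nt from the 3' end and remapped to hairpins, up to
#' `rounds` times (10 by default), never trimming below `min_len` nt. The
#' removed suffix is recorded verbatim.
#'
#' Each mapped read is attributed to the mature miRNA whose extended
#' window (`mature_extension` nt each side) contains the mapped interval;
#' reads mapping a hairpin outside every extended window are not
#' attributed ("unattributed", reported as unclassified). The 3' status is
#' then resolved against the canonical mature 3' end: `trim_len =
#' max(0, canonical_end - mapped_end)`, the removed suffix is split into
#' its longest prefix matching the hairpin continuation beyond the mapped
#' end (templated) and the remainder (non-templated addition, NTA), and
#' the read is called `intact`, `trimmed`, `tailed` or `trimmed+tailed`.
#' Because mapping is maximal, a templated extension is absorbed into the
#' mapped prefix, so templated re-synthesis beyond the canonical end shows
#' up as `tail_templated_len > 0` while the suffix itself is (almost
#' always) pure NTA.
#'
#' Reads mapping several hairpins at the same round are weighted `1/k`,
#' consistent with genome multi-mapper weighting.
#'
#' @param reads tibble with `read_id`, `sequence` (adapter-trimmed,
#'   length-filtered).
#' @param ref an `exo_reference`.
#' @param rounds maximum 3' trim-and-remap rounds (default 10).
#' @param min_len never trim a read below this length (default 15, the
#'   global length floor).
#' @param mature_extension extension of mature windows for attribution.
#' @param genome_screen screen full-length non-hairpin reads against the
#'   genome once before iterating (set `FALSE` to skip).
#' @param high_confidence_only restrict attribution to the reference's
#'   high-confidence mature subset.
#' @return tibble of per-read-per-hit calls: `read_id`, `disposition`
#'   (`classified`, `non_miRNA`, `unclassified`), `mature_id`,
#'   `hairpin_id`, `mapped_start`, `mapped_end`, `rounds_used`,
#'   `trim_len`, `tail_seq`, `tail_templated_len`, `nta_seq`, `status`,
#'   `weight`.
#' @export
classify_isomirs <- function(reads, ref, rounds = 10, min_len = 15,
                             mature_extension = 2, genome_screen = TRUE,
                             high_confidence_only = FALSE) {
  stopifnot(inherits(ref, "exo_reference"))
  hp <- setNames(ref$hairpins$sequence, ref$hairpins$hairpin_id)
  useq <- unique(reads$sequence)
  nlen <- nchar(useq)
  lens <- unique(unlist(lapply(nlen, function(L) {
    seq(L, max(min_len, L - rounds))
  })))
  idx <- substring_index(hp, lens[lens >= min_len])

  state <- tibble(sequence = useq, n = nlen, mapped = FALSE,
                  rounds_used = NA_integer_)
  hit_rows <- list()

  for (r in 0:rounds) {
    open <- !state$mapped & (state$n - r) >= min_len
    if (!any(open)) break
    pre <- substr(state$sequence[open], 1L, state$n[open] - r)
    m <- tibble(sequence = state$sequence[open], prefix = pre) |>
      dplyr::inner_join(idx, by = c(prefix = "seq"),
                        relationship = "many-to-many")
    if (r == 0 && genome_screen) {
      unhit <- setdiff(state$sequence[open], m$sequence)
      if (length(unhit)) {
        g <- align_reads(setNames(unhit, unhit),
                         c(toygenome = ref$genome), max_mismatches = 0,
                         strands = c("+", "-"))
        gen_mapped <- unique(g$read_id)
        state$mapped[state$sequence %in% gen_mapped] <- TRUE
        state$rounds_used[state$sequence %in% gen_mapped] <- -1L  # genome
      }
    }
    if (nrow(m)) {
      m$rounds_used <- r
      hit_rows[[length(hit_rows) + 1L]] <- m
      state$mapped[state$sequence %in% m$sequence] <- TRUE
      state$rounds_used[state$sequence %in% m$sequence] <- r
    }
  }

  hits <- dplyr::bind_rows(hit_rows)
  calls <- .resolve_calls(hits, ref, mature_extension, high_confidence_only)

  per_seq <- dplyr::bind_rows(
    calls,
    tibble(sequence = state$sequence[state$rounds_used %in% -1L],
           disposition = "non_miRNA"),
    tibble(sequence = state$sequence[!state$mapped],
           disposition = "unclassified", status = "unclassified"))

  reads |>
    dplyr::select(read_id, sequence) |>
    dplyr::inner_join(per_seq, by = "sequence",
                      relationship = "many-to-many") |>
    dplyr::select(-sequence)
}

# turn hairpin placements into isomiR calls (vectorized)
.resolve_calls <- function(hits, ref, mature_extension, high_confidence_only) {
  empty <- tibble(sequence = character(0), disposition = character(0),
                  mature_id = character(0), hairpin_id = character(0),
                  mapped_start = integer(0), mapped_end = integer(0),
                  rounds_used = integer(0), trim_len = integer(0),
                  tail_seq = character(0), tail_templated_len = integer(0),
                  nta_seq = character(0), status = character(0),
                  weight = numeric(0))
  if (is.null(hits) || !nrow(hits)) return(empty)

  hits <- hits |>
    dplyr::add_count(sequence, name = ".k") |>
    dplyr::mutate(weight = 1 / .k)

  mw <- ref$matures
  if (high_confidence_only) {
    mw <- mw[mw$mature_id %in% ref$high_confidence, , drop = FALSE]
  }
  n <- nrow(hits)
  mature_row <- rep(NA_integer_, n)
  best_dist <- rep(Inf, n)
  for (j in seq_len(nrow(mw))) {
    # the mapped interval must lie within the extended mature window; a
    # trimmed read falls short of the canonical end (allowed), a templated
    # extension may overshoot it by at most the extension
    ok <- hits$target_id == mw$hairpin_id[j] &
      hits$start >= mw$start[j] - mature_extension &
      hits$end <= mw$end[j] + mature_extension
    d <- abs(hits$start - mw$start[j])
    take <- ok & d < best_dist
    mature_row[take] <- j
    best_dist[take] <- d[take]
  }

  hseq <- setNames(ref$hairpins$sequence, ref$hairpins$hairpin_id)[hits$target_id]
  suffix <- substr(hits$sequence, nchar(hits$sequence) - hits$rounds_used + 1L,
                   nchar(hits$sequence))
  attributed <- !is.na(mature_row)

  out <- tibble(
    sequence = hits$sequence,
    disposition = ifelse(attributed, "classified", "unclassified"),
    mature_id = ifelse(attributed, mw$mature_id[mature_row], NA),
    hairpin_id = hits$target_id,
    mapped_start = hits$start, mapped_end = hits$end,
    rounds_used = hits$rounds_used,
    trim_len = NA_integer_, tail_seq = NA_character_,
    tail_templated_len = NA_integer_, nta_seq = NA_character_,
    status = ifelse(attributed, NA_character_, "unclassified"),
    weight = hits$weight)

  if (any(attributed)) {
    res <- resolve_tail(
      hairpin_seq = hseq[attributed],
      mature_end = mw$end[mature_row[attributed]],
      mapped_end = hits$end[attributed],
      suffix = suffix[attributed])
    out$trim_len[attributed] <- res$trim_len
    out$tail_seq[attributed] <- res$tail_seq
    out$tail_templated_len[attributed] <- res$tail_templated_len
    out$nta_seq[attributed] <- res$nta_seq
    out$status[attributed] <- res$status
  }
  out
}

#' Resolve a removed 3' suffix into trim, templated tail and NTA
#'
#' Given a read's mapped placement on a hairpin, the canonical mature 3'
#' end and the suffix removed during iterative trimming, computes
#' `trim_len = max(0, mature_end - mapped_end)`, splits the tail into its
#' longest prefix matching the hairpin continuation beyond the mapped end
#' (templated) plus the remainder (NTA), and assigns the status. A mapped
#' end beyond the canonical mature end contributes mapped, hence
#' templated, tail bases. All arguments are vectorized.
#'
#' @param hairpin_seq hairpin sequence(s).
#' @param mature_end canonical mature 3' end (0-based half-open, hairpin
#'   coordinates).
#' @param mapped_end mapped 3' end of the read prefix.
#' @param suffix removed 3' suffix (possibly empty).
#' @return tibble: `trim_len`, `tail_seq`, `tail_templated_len`,
#'   `nta_seq`, `status`.
#' @export
resolve_tail <- function(hairpin_seq, mature_end, mapped_end, suffix) {
  continuation <- substr(hairpin_seq, mapped_end + 1L, nchar(hairpin_seq))
  e <- lcp_len(suffix, continuation)
  trim_len <- pmax(0L, mature_end - mapped_end)
  templated_mapped <- pmax(0L, mapped_end - mature_end)
  # read bases 3' of the canonical end: mapped overshoot + removed suffix
  tail_seq <- paste0(
    substr(hairpin_seq, mature_end + 1L, mature_end + templated_mapped),
    suffix)
  tail_templated_len <- templated_mapped + e
  nta_seq <- substr(suffix, e + 1L, nchar(suffix))
  status <- dplyr::case_when(
    trim_len == 0L & !nzchar(tail_seq) ~ "intact",
    trim_len > 0L & !nzchar(tail_seq) ~ "trimmed",
    trim_len == 0L ~ "tailed",
    TRUE ~ "trimmed+tailed")
  tibble(trim_len = trim_len, tail_seq = tail_seq,
         tail_templated_len = tail_templated_len, nta_seq = nta_seq,
         status = status)
}

#' Per-sample 3' status summary and per-miRNA trim/tail detail
#'
#' Pools classified isomiR calls into weighted fractions of `intact`,
#' `trimmed`, `tailed` and `trimmed+tailed` reads (summing to 1 over
#' classified reads), optionally per sample, and emits the per-miRNA
#' heat-map analogue: weighted counts per (mature, trim length, tail
#' length).
#'
#' @param calls output of [classify_isomirs()]; add a `sample` column to
#'   summarise several libraries at once.
#' @return an `exo_trimtail`: list with `summary` and `by_mirna` tibbles.
#' @export
trim_tail_summary <- function(calls) {
  grp <- if ("sample" %in% names(calls)) "sample" else character(0)
  cls <- calls |> dplyr::filter(disposition == "classified")
  if (!nrow(cls)) {
    warn("no classified reads; empty 3' status summary")
    out <- list(summary = tibble(status = character(0), weight = numeric(0),
                                 fraction = numeric(0)),
                by_mirna = tibble(), empty = TRUE)
    class(out) <- "exo_trimtail"
    return(out)
  }
  summary <- cls |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grp, "status")))) |>
    dplyr::summarise(weight = sum(weight), .groups = "drop_last") |>
    dplyr::mutate(fraction = weight / sum(weight)) |>
    dplyr::ungroup()
  by_mirna <- cls |>
    dplyr::mutate(tail_len = nchar(tail_seq)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c(grp, "mature_id", "trim_len", "tail_len")))) |>
    dplyr::summarise(weight = sum(weight), .groups = "drop")
  out <- list(summary = summary, by_mirna = by_mirna, empty = FALSE)
  class(out) <- "exo_trimtail"
  out
}

#' Non-templated addition composition profile
#'
#' Emulates the dedicated NTA analysis: reads at least `min_len` nt
#' (default 18) that map neither hairpins nor the genome at full length
#' are trimmed 1 nt at a time from the 3' terminus, at most `max_nta`
#' times (default 3), and remapped to hairpin sequences; the removed
#' suffix is the NTA. Per-miRNA nucleotide composition is reported by tail
#' position, and only miRNAs with at least `min_count` weighted reads in
#' *both* compartments enter the cell-vs-exosome comparison table.
#'
#' @param reads tibble with `read_id`, `sequence`, and a `compartment`
#'   column (`"cell"` / `"exosome"`) when comparing compartments.
#' @param ref an `exo_reference`.
#' @param max_nta maximum NTA length probed (default 3).
#' @param min_len minimum read length entering the analysis (default 18).
#' @param min_count weighted read-count threshold per compartment
#'   (default 500); set to 0 to keep all miRNAs.
#' @return list with `profile` (mature_id [, compartment], position, nt,
#'   weight, fraction) and `counts` (weighted miRNA-attributed reads per
#'   mature [and compartment], used for the threshold).
#' @export
nta_profile <- function(reads, ref, max_nta = 3, min_len = 18,
                        min_count = 500) {
  has_comp <- "compartment" %in% names(reads)
  grp <- if (has_comp) "compartment" else character(0)
  reads <- reads[nchar(reads$sequence) >= min_len, , drop = FALSE]
  calls <- classify_isomirs(reads |> dplyr::select(read_id, sequence), ref,
                            rounds = max_nta, min_len = min_len - max_nta)
  if (has_comp) {
    calls <- calls |>
      dplyr::left_join(reads |> dplyr::select(read_id, compartment),
                       by = "read_id")
  }
  attributed <- calls |> dplyr::filter(disposition == "classified")
  counts <- attributed |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("mature_id", grp)))) |>
    dplyr::summarise(total_weight = sum(weight), .groups = "drop")

  keep <- counts
  if (min_count > 0 && has_comp) {
    keep <- counts |>
      tidyr::pivot_wider(names_from = "compartment",
                         values_from = "total_weight", values_fill = 0) |>
      dplyr::filter(dplyr::if_all(-mature_id, ~ .x >= min_count))
  } else if (min_count > 0) {
    keep <- counts |> dplyr::filter(total_weight >= min_count)
  }

  tails <- attributed |>
    dplyr::filter(nzchar(nta_seq), mature_id %in% keep$mature_id)
  if (!nrow(tails)) {
    return(list(profile = tibble(), counts = counts))
  }
  prof <- tails |>
    tidyr::uncount(nchar(nta_seq), .remove = FALSE, .id = "position") |>
    dplyr::mutate(nt = substr(nta_seq, position, position)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c("mature_id", grp, "position", "nt")))) |>
    dplyr::summarise(weight = sum(weight), .groups = "drop_last") |>
    dplyr::mutate(fraction = weight / sum(weight)) |>
    dplyr::ungroup()
  list(profile = prof, counts = counts)
}

#' Histogram of 5' start offsets per miRNA
#'
#' Offsets of mapped 5' ends relative to the canonical mature start,
#' bounded to the window allowed by the annotation extension (-2..+2 by
#' default). A library of canonically processed miRNAs puts all mass at
#' offset 0.
#'
#' @param calls output of [classify_isomirs()].
#' @param ref an `exo_reference`.
#' @return tibble: `mature_id`, `offset`, `weight`, `fraction`.
#' @export
five_prime_offsets <- function(calls, ref) {
  cls <- calls |> dplyr::filter(disposition == "classified")
  m <- ref$matures
  cls |>
    dplyr::mutate(offset = mapped_start -
                    m$start[match(mature_id, m$mature_id)]) |>
    dplyr::group_by(mature_id, offset) |>
    dplyr::summarise(weight = sum(weight), .groups = "drop_last") |>
    dplyr::mutate(fraction = weight / sum(weight)) |>
    dplyr::ungroup()
}
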