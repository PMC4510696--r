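#' Annotate genome hits into ncRNA classes
#'
#' Assigns each hit exactly one category. A forward-strand hit whose
#' interval lies entirely within an extended mature-miRNA window
#' `[mature.start - ext, mature.end + ext)` is `miRNA` (the extension, 2
#' nt by default, accommodates imprecise precursor processing); otherwise
#' the hit takes the class of the feature containing it, resolved by the
#' fixed priority `miRNA > tRNA > rRNA > snRNA > repeat > other_ncRNA`.
#' Hits inside a hairpin but outside every extended mature window are
#' `other_ncRNA` (precursor fragments); hits contained in no feature are
#' `unannotated`. Reads listed in `all_read_ids` but absent from `hits`
#' are appended as `unmapped`.
#'
#' When a hit fits more than one extended mature window, the window whose
#' start is closest to the hit start wins (first by coordinate on ties).
#'
#' @param hits weighted hits tibble (see [weight_multimappers()]) with
#'   genome coordinates.
#' @param ref an `exo_reference`.
#' @param mature_extension nt added on both sides of each mature window.
#' @param all_read_ids optional character vector of every read entering
#'   the aligner, used to report unmapped reads.
#' @return tibble: `read_id`, `category`, `mature_id`, `weight`,
#'   `target_id`, `start`, `end`, `strand`.
#' @export
annotate_reads <- function(hits, ref, mature_extension = 2,
                           all_read_ids = NULL) {
  stopifnot(inherits(ref, "exo_reference"))
  if (!"weight" %in% names(hits)) hits <- weight_multimappers(hits)
  n <- nrow(hits)
  category <- rep(NA_character_, n)
  mature_id <- rep(NA_character_, n)

  if (n > 0) {
    # miRNA: containment in an extended mature window, forward strand
    mw <- ref$matures
    best_dist <- rep(Inf, n)
    for (j in seq_len(nrow(mw))) {
      ws <- mw$genome_start[j] - mature_extension
      we <- mw$genome_end[j] + mature_extension
      inside <- hits$strand == "+" & hits$start >= ws & hits$end <= we
      d <- abs(hits$start - mw$genome_start[j])
      take <- inside & d < best_dist
      category[take] <- "miRNA"
      mature_id[take] <- mw$mature_id[j]
      best_dist[take] <- d[take]
    }

    class_order <- c(tRNA = "tRNA", rRNA = "rRNA", snRNA = "snRNA",
                     `repeat` = "repeat", other = "other_ncRNA",
                     miRNA_hairpin = "other_ncRNA")
    for (cls in c("tRNA", "rRNA", "snRNA", "repeat", "other", "miRNA_hairpin")) {
      f <- ref$features[ref$features$class == cls, , drop = FALSE]
      if (!nrow(f)) next
      f <- f[order(f$start), , drop = FALSE]
      pos <- findInterval(hits$start, f$start)
      contained <- pos >= 1L & is.na(category)
      contained[contained] <- hits$end[contained] <= f$end[pos[contained]]
      category[contained] <- class_order[[cls]]
    }
    category[is.na(category)] <- "unannotated"
  }

  out <- tibble(
    read_id = hits$read_id, category = category, mature_id = mature_id,
    weight = hits$weight, target_id = hits$target_id,
    start = hits$start, end = hits$end, strand = hits$strand)

  if (!is.null(all_read_ids)) {
    missing <- setdiff(all_read_ids, hits$read_id)
    if (length(missing)) {
      out <- dplyr::bind_rows(out, tibble(
        read_id = missing, category = "unmapped", mature_id = NA_character_,
        weight = 1, target_id = NA_character_,
        start = NA_integer_, end = NA_integer_, strand = NA_character_))
    }
  }
  out
}

#' Weighted composition of a sample by ncRNA category
#'
#' Summarises annotated reads into weighted fractions per category over
#' mapped reads (fractions sum to 1), alongside mapping statistics:
#' fractions of reads mapped, uniquely mapped, multi-mapped and unmapped.
#'
#' @param annotated output of [annotate_reads()].
#' @return an `exo_composition`: list with `composition` (category,
#'   weight, fraction) and `mapping` tibbles. With zero mapped reads the
#'   composition is empty and the `empty` flag set.
#' @export
composition_summary <- function(annotated) {
  mapped <- annotated |> dplyr::filter(category != "unmapped")
  n_unmapped <- dplyr::n_distinct(annotated$read_id[annotated$category == "unmapped"])
  n_reads <- dplyr::n_distinct(annotated$read_id)
  if (!nrow(mapped)) {
    warn("no mapped reads; returning empty composition")
    out <- list(composition = tibble(category = character(0),
                                     weight = numeric(0), fraction = numeric(0)),
                mapping = tibble(n_reads = n_reads, mapped_fraction = 0,
                                 unique_fraction = 0, multi_fraction = 0,
                                 unmapped_fraction = 1),
                empty = TRUE)
    class(out) <- "exo_composition"
    return(out)
  }
  comp <- mapped |>
    dplyr::group_by(category) |>
    dplyr::summarise(weight = sum(weight), .groups = "drop") |>
    dplyr::mutate(fraction = weight / sum(weight))
  per_read <- mapped |> dplyr::count(read_id, name = "k")
  mapping <- tibble(
    n_reads = n_reads,
    mapped_fraction = nrow(per_read) / n_reads,
    unique_fraction = sum(per_read$k == 1) / n_reads,
    multi_fraction = sum(per_read$k > 1) / n_reads,
    unmapped_fraction = n_unmapped / n_reads)
  out <- list(composition = comp, mapping = mapping, empty = FALSE)
  class(out) <- "exo_composition"
  out
}

#' @export
print.exo_composition <- function(x, ...) {
  cat("<exo_composition>\n")
  print(x$composition)
  print(x$mapping)
  invisible(x)
}

#' Read length by 5' base profile
#'
#' Weighted counts of reads by (length, first base), the standard
#' length-distribution panel of a small-RNA library coloured by 5'
#' nucleotide. A canonical miRNA-dominated library has its mode at 22 nt.
#'
#' @param reads tibble with `read_id`, `sequence`.
#' @param hits optional hits tibble; when supplied with
#'   `restrict = "mapped"` only reads present in `hits` are profiled, each
#'   weighted by its summed hit weight (1 for any mapped read).
#' @param restrict `"all"` or `"mapped"`.
#' @return tibble: `length`, `base`, `weight`; row sums per length equal
#'   the weighted read counts at that length.
#' @export
length_firstbase_profile <- function(reads, hits = NULL,
                                     restrict = c("all", "mapped")) {
  restrict <- match.arg(restrict)
  df <- tibble(read_id = reads$read_id,
               length = nchar(reads$sequence),
               base = substr(reads$sequence, 1, 1),
               weight = 1)
  if (restrict == "mapped") {
    if (is.null(hits)) abort("`hits` required when restrict = \"mapped\"")
    df <- df |> dplyr::filter(read_id %in% hits$read_id)
  }
  if (!nrow(df)) {
    return(tibble(length = integer(0), base = character(0),
                  weight = numeric(0)))
  }
  df |>
    dplyr::group_by(length, base) |>
    dplyr::summarise(weight = sum(weight), .groups = "drop")
}
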