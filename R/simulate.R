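#' Define a simulated small-RNA library profile
#'
#' A library profile fixes everything the read simulator needs for one
#' sample: per-mature expected abundance, the 3' modification model
#' (trimming up to 10 nt, tailing up to 3 nt with templated vs
#' non-templated resolution), the non-miRNA background composition, the
#' unmappable fraction, the adapter, the read count and the seed. Defaults
#' emulate a small-RNA library whose mapped reads are mostly mature miRNAs
#' of modal length 22 nt with mostly-intact 3' ends and an A-biased
#' non-templated tail composition.
#'
#' @param ref an `exo_reference` the profile refers to.
#' @param condition free-text condition label (e.g. "WT-cell", "MUT-exo").
#' @param read_count number of reads to simulate.
#' @param abundance named non-negative vector of expected abundances per
#'   mature id (need not be normalized). Default: log-normal draws over all
#'   matures of the reference.
#' @param trim_probs probability vector over 3' trim lengths `0..10`.
#' @param tail_probs probability vector over tail lengths `0..3`.
#' @param tail_nt_probs tail nucleotide composition (A, C, G, T).
#' @param templated_frac fraction of tails drawn from the hairpin
#'   continuation (templated) rather than from `tail_nt_probs`
#'   (non-templated addition, NTA).
#' @param class_fracs named fractions of reads drawn from tRNA, rRNA,
#'   snRNA, repeat and other loci; together with `unmappable_frac` they
#'   must sum to at most 1, the remainder being miRNA-derived reads.
#' @param unmappable_frac fraction of reads made of random sequence absent
#'   from the reference.
#' @param adapter 3' adapter sequence ligated to every insert.
#' @param read_len fixed instrument read length; the insert plus adapter is
#'   truncated to this many cycles.
#' @param seed integer seed; fixes the library bit-exactly.
#' @return an `exo_profile` list.
#' @export
sim_profile <- function(ref,
                        condition = "cell",
                        read_count = 20000,
                        abundance = NULL,
                        trim_probs = c(0.75, 0.12, 0.06, 0.03, 0.02,
                                       0.01, 0.005, 0.002, 0.002, 0.0005, 0.0005),
                        tail_probs = c(0.70, 0.20, 0.07, 0.03),
                        tail_nt_probs = c(A = 0.5, C = 0.2, G = 0.15, T = 0.15),
                        templated_frac = 0.2,
                        class_fracs = c(tRNA = 0.08, rRNA = 0.12, snRNA = 0.04,
                                        `repeat` = 0.08, other = 0.03),
                        unmappable_frac = 0.05,
                        adapter = "AGATCGGAAGAGC",
                        read_len = 50,
                        seed = 1) {
  stopifnot(inherits(ref, "exo_reference"))
  if (is.null(abundance)) {
    abundance <- setNames(rlnorm(nrow(ref$matures), log(100), 1),
                          ref$matures$mature_id)
  }
  if (!all(names(abundance) %in% ref$matures$mature_id)) {
    abort("`abundance` names must be mature ids of `ref`")
  }
  if (any(abundance < 0)) abort("abundances must be >= 0")
  assert_fraction(class_fracs, "class_fracs")
  assert_fraction(unmappable_frac, "unmappable_frac")
  assert_fraction(templated_frac, "templated_frac")
  if (sum(class_fracs) + unmappable_frac > 1) {
    abort("class fractions plus unmappable fraction exceed 1")
  }
  trim_probs <- trim_probs / sum(trim_probs)
  tail_probs <- tail_probs / sum(tail_probs)
  tail_nt_probs <- tail_nt_probs / sum(tail_nt_probs)
  min_mat <- min(ref$matures$end - ref$matures$start)
  max_trim <- max(which(trim_probs > 0)) - 1L
  if (max_trim >= min_mat) {
    abort("trim lengths with positive probability must be < mature length")
  }
  if (!nzchar(adapter)) abort("adapter must be non-empty")
  structure(list(
    condition = condition, read_count = read_count, abundance = abundance,
    trim_probs = trim_probs, tail_probs = tail_probs,
    tail_nt_probs = tail_nt_probs, templated_frac = templated_frac,
    class_fracs = class_fracs, unmappable_frac = unmappable_frac,
    adapter = adapter, read_len = read_len, seed = seed
  ), class = "exo_profile")
}

#' Simulate one small-RNA library with per-read ground truth
#'
#' Draws read sources by multinomial sampling from the profile's
#' composition, builds each miRNA read as
#' `mature[start .. end - trim] + tail + adapter` truncated to the read
#' length, samples non-miRNA reads as fragments of tRNA/rRNA/snRNA/repeat/
#' other loci and unmappable reads as random sequence absent from the
#' reference, and records a complete truth table.
#'
#' Besides the intended modification, the truth table carries the
#' *expected* maximal-mapping classification (`expected_trim`,
#' `expected_nta`, `expected_classifiable`): a non-templated tail whose
#' first bases coincide with the hairpin continuation is indistinguishable
#' from a shorter trim by any remapping procedure, and
#' `template_coincident` marks those reads.
#'
#' @param ref an `exo_reference`.
#' @param profile an `exo_profile` built for `ref`.
#' @param min_len classification length floor used to derive
#'   `expected_classifiable` (reads whose mappable prefix is shorter are
#'   unclassifiable by construction).
#' @param mature_extension annotation window extension used to derive
#'   `expected_classifiable` (a templated extension overshooting the
#'   canonical end by more than this is unattributable).
#' @return list with `reads` (tibble: read_id, sequence, quality) and
#'   `truth` (one record per read).
#' @export
sim_reads <- function(ref, profile, min_len = 15, mature_extension = 2) {
  stopifnot(inherits(ref, "exo_reference"), inherits(profile, "exo_profile"))
  if (!is.null(profile$seed)) set.seed(profile$seed)
  n <- profile$read_count

  src_probs <- c(miRNA = 1 - sum(profile$class_fracs) - profile$unmappable_frac,
                 profile$class_fracs, unmappable = profile$unmappable_frac)
  src <- sample(names(src_probs), n, replace = TRUE, prob = src_probs)

  insert <- character(n)
  truth <- tibble(
    read_id = sprintf("r%06d", seq_len(n)),
    class = src,
    feature_id = NA_character_, mature_id = NA_character_,
    trim_len = NA_integer_, tail_seq = NA_character_,
    tail_templated = NA, template_coincident = NA,
    expected_trim = NA_integer_, expected_nta = NA_character_,
    expected_classifiable = NA, insert_len = NA_integer_
  )

  is_mir <- src == "miRNA"
  n_mir <- sum(is_mir)
  if (n_mir > 0) {
    ab <- profile$abundance
    mi <- sample(names(ab), n_mir, replace = TRUE, prob = ab)
    mrow <- match(mi, ref$matures$mature_id)
    hseq <- ref$hairpins$sequence[match(ref$matures$hairpin_id[mrow],
                                        ref$hairpins$hairpin_id)]
    m_start <- ref$matures$start[mrow]
    m_end <- ref$matures$end[mrow]

    trim <- sample(seq_along(profile$trim_probs), n_mir, replace = TRUE,
                   prob = profile$trim_probs) - 1L
    tail_len <- sample(seq_along(profile$tail_probs), n_mir, replace = TRUE,
                       prob = profile$tail_probs) - 1L
    templated <- runif(n_mir) < profile$templated_frac & tail_len > 0

    body <- substr0(hseq, m_start, m_end - trim)
    cont <- substr0(hseq, m_end - trim, nchar(hseq))   # hairpin continuation

    tail <- character(n_mir)
    # templated tails copy the hairpin continuation (truncated at hairpin end)
    tail[templated] <- substr(cont[templated], 1, tail_len[templated])
    nt_idx <- !templated & tail_len > 0
    if (any(nt_idx)) {
      draw <- function(k) paste(sample(names(profile$tail_nt_probs), k,
                                       replace = TRUE,
                                       prob = profile$tail_nt_probs),
                                collapse = "")
      tail[nt_idx] <- vapply(tail_len[nt_idx], draw, "")
    }
    tail_len <- nchar(tail)                 # templated tails may truncate
    templated <- templated & tail_len > 0

    # maximal-mapping expectation: part of the tail matching the hairpin
    # continuation is absorbed into the mapped prefix
    e <- lcp_len(tail, cont)
    mapped_end_exp <- (m_end - trim) + e
    exp_trim <- pmax(0L, m_end - mapped_end_exp)
    exp_nta <- substr(tail, e + 1L, tail_len)
    coincident <- !templated & tail_len > 0 & e > 0
    mapped_len <- (m_end - trim - m_start) + e

    insert[is_mir] <- paste0(body, tail)
    truth$feature_id[is_mir] <- ref$matures$hairpin_id[mrow]
    truth$mature_id[is_mir] <- mi
    truth$trim_len[is_mir] <- trim
    truth$tail_seq[is_mir] <- tail
    truth$tail_templated[is_mir] <- templated
    truth$template_coincident[is_mir] <- coincident
    truth$expected_trim[is_mir] <- exp_trim
    truth$expected_nta[is_mir] <- exp_nta
    truth$expected_classifiable[is_mir] <-
      nchar(insert[is_mir]) >= min_len & mapped_len >= min_len &
      (tail_len - e) <= 10 & (e - trim) <= mature_extension
  }

  for (cls in names(profile$class_fracs)) {
    idx <- which(src == cls)
    if (!length(idx)) next
    fl <- ref$features |> dplyr::filter(class == .to_feature_class(cls))
    if (!nrow(fl)) abort(sprintf("reference has no '%s' features", cls))
    pick <- sample(nrow(fl), length(idx), replace = TRUE)
    flen <- sample(16:32, length(idx), replace = TRUE)
    flen <- pmin(flen, fl$end[pick] - fl$start[pick])
    off <- floor(runif(length(idx)) * (fl$end[pick] - fl$start[pick] - flen + 1))
    insert[idx] <- substr0(ref$genome, fl$start[pick] + off,
                           fl$start[pick] + off + flen)
    truth$feature_id[idx] <- fl$feature_id[pick]
  }

  idx <- which(src == "unmappable")
  if (length(idx)) {
    for (i in idx) {
      repeat {
        s <- random_dna(22)
        if (!grepl(s, ref$genome, fixed = TRUE) &&
            !grepl(revcomp(s), ref$genome, fixed = TRUE)) break
      }
      insert[i] <- s
    }
  }

  truth$insert_len <- nchar(insert)
  reads <- tibble(
    read_id = truth$read_id,
    sequence = substr(paste0(insert, profile$adapter), 1, profile$read_len)
  )
  reads$quality <- strrep("I", nchar(reads$sequence))
  list(reads = reads, truth = truth)
}

.to_feature_class <- function(cls) {
  c(tRNA = "tRNA", rRNA = "rRNA", snRNA = "snRNA",
    `repeat` = "repeat", other = "other")[[cls]]
}

#' Simulate a cell-vs-exosome experiment across KRAS genotypes
#'
#' Builds one library per (genotype x compartment x replicate) combination
#' from a common per-mature base abundance. Exosome libraries multiply the
#' abundance of each mature by `2^export_log2_bias`, emulating selective
#' cargo sorting; cell libraries use the base abundance. Per-replicate
#' seeds are derived from `seed`.
#'
#' @param ref an `exo_reference`.
#' @param export_log2_bias named log2 cell-vs-exosome export bias per
#'   mature id (positive = exosome-enriched); unnamed matures get 0.
#' @param genotypes condition labels for the cell lines (default
#'   wild-type and mutant KRAS).
#' @param n_rep replicates per condition.
#' @param read_count reads per library.
#' @param base_abundance named base abundance (default log-normal).
#' @param seed master seed.
#' @param ... further arguments passed to [sim_profile()].
#' @return list with `libraries` (named list of `sim_reads()` results) and
#'   `samples` (metadata tibble: sample, genotype, compartment, replicate).
#' @export
sim_experiment <- function(ref,
                           export_log2_bias = NULL,
                           genotypes = c("WT", "MUT"),
                           n_rep = 3,
                           read_count = 15000,
                           base_abundance = NULL,
                           seed = 1,
                           ...) {
  set.seed(seed)
  if (is.null(base_abundance)) {
    base_abundance <- setNames(rlnorm(nrow(ref$matures), log(100), 1),
                               ref$matures$mature_id)
  }
  bias <- setNames(rep(0, nrow(ref$matures)), ref$matures$mature_id)
  if (!is.null(export_log2_bias)) {
    bias[names(export_log2_bias)] <- export_log2_bias
  }
  libraries <- list()
  samples <- list()
  k <- 0L
  for (g in genotypes) {
    for (comp in c("cell", "exosome")) {
      ab <- if (comp == "exosome") base_abundance * 2^bias else base_abundance
      for (r in seq_len(n_rep)) {
        k <- k + 1L
        id <- sprintf("%s_%s_%d", g, comp, r)
        prof <- sim_profile(ref, condition = id, read_count = read_count,
                            abundance = ab, seed = seed * 1000L + k, ...)
        libraries[[id]] <- sim_reads(ref, prof)
        samples[[k]] <- tibble(sample = id, genotype = g,
                               compartment = comp, replicate = r)
      }
    }
  }
  list(libraries = libraries, samples = dplyr::bind_rows(samples))
}

#' Write reads to FASTQ
#'
#' @param reads tibble with `read_id`, `sequence`, and optionally `quality`
#'   (constant high quality is filled in when absent).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  qual <- if ("quality" %in% names(reads)) reads$quality
          else strrep("I", nchar(reads$sequence))
  x <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id))
  q <- Biostrings::BStringSet(qual)
  qs <- Biostrings::QualityScaledDNAStringSet(x, Biostrings::PhredQuality(q))
  Biostrings::writeQualityScaledXStringSet(qs, path)
  invisible(path)
}

#' Read a FASTQ file into a read tibble
#'
#' @param path FASTQ file.
#' @return tibble with `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  tibble(
    read_id = sub(" .*", "", names(x)),
    sequence = unname(as.character(x)),
    quality = unname(as.character(S4Vectors::mcols(x)$qualities))
  )
}
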