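#' Build a synthetic small-RNA reference world
#'
#' Generates a toy reference bundle for simulation and pipeline testing: a
#' set of miRNA hairpin (pre-miRNA) sequences each carrying a 5p and a 3p
#' mature window, plus a single-"chromosome" toy genome in which the
#' hairpins are embedded verbatim alongside tRNA, rRNA, snRNA, repeat and
#' other ncRNA loci separated by random spacers. All coordinates are
#' 0-based half-open internally; the GFF3 writers convert to 1-based
#' inclusive at the file boundary.
#'
#' Mature windows are rejection-sampled so that each mature sequence occurs
#' exactly once in the genome, which makes read-to-miRNA attribution
#' unambiguous. `shared_mature > 0` instead copies the first hairpin's 5p
#' mature sequence into that many additional hairpins, creating deliberate
#' multi-mapping loci for weighting tests. Repeat loci are `n_repeat_loci`
#' verbatim copies of one repeat unit, so reads from them multi-map by
#' construction.
#'
#' @param n_hairpins number of hairpins (each contributes a 5p and a 3p
#'   mature miRNA).
#' @param hairpin_len integer range (min, max) of hairpin lengths, nt.
#' @param mature_len integer range of mature miRNA lengths, nt.
#' @param n_trna,n_rrna,n_snrna,n_other number of loci per ncRNA class.
#' @param n_repeat_loci number of identical repeat-unit copies placed in the
#'   genome (0 disables the repeat class).
#' @param repeat_len length of the repeat unit, nt.
#' @param spacer_len integer range of inter-feature spacer lengths, nt.
#' @param shared_mature number of additional hairpins whose 5p mature window
#'   is overwritten with hairpin 1's 5p mature sequence (default 0: all
#'   mature sequences unique).
#' @param high_confidence_frac fraction of mature ids flagged high
#'   confidence (the real-data analysis restricts to a curated
#'   high-confidence miRNA subset; synthetic bundles define their own).
#' @param seed integer seed; fixed seed gives a byte-identical bundle.
#' @param max_tries bounded retries for the mature-uniqueness rejection
#'   sampler before failing.
#'
#' @return An object of class `exo_reference`: a list with `hairpins`,
#'   `matures`, `features` tibbles, the `genome` string and the
#'   `high_confidence` mature-id vector.
#' @export
sim_reference <- function(n_hairpins = 20,
                          hairpin_len = c(70, 90),
                          mature_len = c(21, 23),
                          n_trna = 4, n_rrna = 3, n_snrna = 3,
                          n_repeat_loci = 3, repeat_len = 40,
                          n_other = 2,
                          spacer_len = c(20, 40),
                          shared_mature = 0,
                          high_confidence_frac = 1,
                          seed = NULL,
                          max_tries = 50) {
  if (n_hairpins < 1) abort("`n_hairpins` must be >= 1")
  if (min(hairpin_len) < max(mature_len) * 2 + 12) {
    abort("hairpins must be long enough to hold disjoint 5p and 3p mature windows")
  }
  if (shared_mature >= n_hairpins) abort("`shared_mature` must be < `n_hairpins`")
  if (!is.null(seed)) set.seed(seed)

  for (try in seq_len(max_tries)) {
    bundle <- .build_bundle(n_hairpins, hairpin_len, mature_len,
                            n_trna, n_rrna, n_snrna,
                            n_repeat_loci, repeat_len, n_other,
                            spacer_len, shared_mature)
    if (.matures_unique(bundle, shared_mature)) {
      bundle$high_confidence <-
        bundle$matures$mature_id[seq_len(ceiling(high_confidence_frac *
                                                   nrow(bundle$matures)))]
      class(bundle) <- "exo_reference"
      return(bundle)
    }
  }
  abort(sprintf(
    "could not satisfy mature-window sequence uniqueness after %d tries",
    max_tries))
}

.build_bundle <- function(n_hairpins, hairpin_len, mature_len,
                          n_trna, n_rrna, n_snrna,
                          n_repeat_loci, repeat_len, n_other,
                          spacer_len, shared_mature) {
  rint <- function(rng) sample(seq(rng[1], rng[2]), 1L)

  hp <- vector("list", n_hairpins)
  mat <- vector("list", n_hairpins)
  for (i in seq_len(n_hairpins)) {
    L <- rint(hairpin_len)
    m5 <- rint(mature_len)
    m3 <- rint(mature_len)
    s5 <- sample(3:5, 1L)
    e3 <- L - sample(3:5, 1L)              # 3p mature ends >= 3 nt before hairpin end
    seqs <- random_dna(L)
    hp[[i]] <- tibble(hairpin_id = sprintf("hp%02d", i), sequence = seqs)
    mat[[i]] <- tibble(
      mature_id = sprintf("mir-%02d-%s", i, c("5p", "3p")),
      hairpin_id = sprintf("hp%02d", i),
      start = c(s5, e3 - m3),
      end = c(s5 + m5, e3),
      arm = c("5p", "3p")
    )
  }
  hairpins <- dplyr::bind_rows(hp)
  matures <- dplyr::bind_rows(mat)

  # deliberate multi-mapper construction: copy hairpin 1's 5p mature
  # sequence into the 5p window of the next `shared_mature` hairpins
  if (shared_mature > 0) {
    donor <- matures[matures$hairpin_id == "hp01" & matures$arm == "5p", ]
    donor_seq <- substr0(hairpins$sequence[1], donor$start, donor$end)
    for (i in seq_len(shared_mature) + 1L) {
      w <- which(matures$hairpin_id == sprintf("hp%02d", i) & matures$arm == "5p")
      len <- nchar(donor_seq)
      matures$end[w] <- matures$start[w] + len
      s <- hairpins$sequence[i]
      substr(s, matures$start[w] + 1L, matures$end[w]) <- donor_seq
      hairpins$sequence[i] <- s
    }
  }

  elements <- list()
  add <- function(id, class, seqs) {
    elements[[length(elements) + 1L]] <<- list(id = id, class = class, seq = seqs)
  }
  for (i in seq_len(n_hairpins)) {
    add(hairpins$hairpin_id[i], "miRNA_hairpin", hairpins$sequence[i])
  }
  for (i in seq_len(n_trna))  add(sprintf("trna%02d", i), "tRNA", random_dna(sample(70:76, 1L)))
  for (i in seq_len(n_rrna))  add(sprintf("rrna%02d", i), "rRNA", random_dna(sample(110:130, 1L)))
  for (i in seq_len(n_snrna)) add(sprintf("snrna%02d", i), "snRNA", random_dna(sample(90:110, 1L)))
  if (n_repeat_loci > 0) {
    unit <- random_dna(repeat_len)
    for (i in seq_len(n_repeat_loci)) add(sprintf("rep%02d", i), "repeat", unit)
  }
  for (i in seq_len(n_other)) add(sprintf("other%02d", i), "other", random_dna(sample(60:90, 1L)))

  rint2 <- function() sample(seq(spacer_len[1], spacer_len[2]), 1L)
  pieces <- character(0)
  pos <- 0L
  feat <- vector("list", length(elements))
  for (k in seq_along(elements)) {
    sp <- random_dna(rint2())
    pieces <- c(pieces, sp, elements[[k]]$seq)
    pos <- pos + nchar(sp)
    feat[[k]] <- tibble(
      feature_id = elements[[k]]$id,
      class = elements[[k]]$class,
      start = pos,
      end = pos + nchar(elements[[k]]$seq),
      strand = "+"
    )
    pos <- pos + nchar(elements[[k]]$seq)
  }
  pieces <- c(pieces, random_dna(rint2()))
  genome <- paste(pieces, collapse = "")
  features <- dplyr::bind_rows(feat)

  hairpins <- dplyr::left_join(
    hairpins,
    features |> dplyr::select(feature_id, genome_start = start, genome_end = end),
    by = c("hairpin_id" = "feature_id"))
  matures <- dplyr::left_join(
    matures, hairpins |> dplyr::select(hairpin_id, genome_start), by = "hairpin_id") |>
    dplyr::mutate(
      sequence = substr0(hairpins$sequence[match(hairpin_id, hairpins$hairpin_id)],
                         start, end),
      genome_start = genome_start + start,
      genome_end = genome_start + (end - start))

  list(hairpins = hairpins, matures = matures, features = features,
       genome = genome, high_confidence = character(0))
}

# exactly-once occurrence of every mature sequence in the genome
# (shared group: exactly `shared + 1` occurrences of the donor sequence)
.matures_unique <- function(bundle, shared_mature) {
  count_occ <- function(p) {
    sum(gregexpr(p, bundle$genome, fixed = TRUE)[[1]] > 0)
  }
  seqs <- bundle$matures$sequence
  expected <- rep(1L, length(seqs))
  if (shared_mature > 0) {
    donor_seq <- seqs[bundle$matures$hairpin_id == "hp01" &
                        bundle$matures$arm == "5p"]
    shared <- seqs == donor_seq
    if (sum(shared) != shared_mature + 1L) return(FALSE)
    expected[shared] <- shared_mature + 1L
    if (anyDuplicated(seqs[!shared])) return(FALSE)
  } else if (anyDuplicated(seqs)) {
    return(FALSE)
  }
  occ <- vapply(seqs, count_occ, integer(1))
  all(occ == expected)
}

#' @export
print.exo_reference <- function(x, ...) {
  cat(sprintf(
    "<exo_reference> %d hairpins, %d matures, genome %d nt, %d features (%s)\n",
    nrow(x$hairpins), nrow(x$matures), nchar(x$genome), nrow(x$features),
    paste(unique(x$features$class), collapse = ", ")))
  invisible(x)
}

#' Write a reference bundle to FASTA + GFF3 files
#'
#' Emits `hairpins.fa`, `genome.fa`, and `annotation.gff3` (genome features
#' and mature windows in genome coordinates, 1-based inclusive per the GFF3
#' standard).
#'
#' @param ref an `exo_reference`.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of file paths written.
#' @export
write_reference <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hp <- Biostrings::DNAStringSet(setNames(ref$hairpins$sequence,
                                          ref$hairpins$hairpin_id))
  gn <- Biostrings::DNAStringSet(setNames(ref$genome, "toygenome"))
  f_hp <- file.path(dir, "hairpins.fa")
  f_gn <- file.path(dir, "genome.fa")
  f_gff <- file.path(dir, "annotation.gff3")
  Biostrings::writeXStringSet(hp, f_hp)
  Biostrings::writeXStringSet(gn, f_gn)

  feats <- GenomicRanges::GRanges(
    seqnames = "toygenome",
    ranges = IRanges::IRanges(start = ref$features$start + 1L,
                              end = ref$features$end),
    strand = ref$features$strand,
    type = ref$features$class,
    ID = ref$features$feature_id)
  mats <- GenomicRanges::GRanges(
    seqnames = "toygenome",
    ranges = IRanges::IRanges(start = ref$matures$genome_start + 1L,
                              end = ref$matures$genome_end),
    strand = "+",
    type = "miRNA",
    ID = ref$matures$mature_id,
    Parent = ref$matures$hairpin_id)
  rtracklayer::export(c(feats, mats), f_gff, format = "gff3")
  invisible(c(f_hp, f_gn, f_gff))
}

#' Read a reference bundle back from FASTA + GFF3
#'
#' Inverse of [write_reference()]. Hairpin-local mature coordinates are
#' recovered from genome coordinates via the hairpin feature offsets.
#'
#' @param dir directory holding `hairpins.fa`, `genome.fa`,
#'   `annotation.gff3`.
#' @return an `exo_reference`.
#' @export
read_reference <- function(dir) {
  hp <- Biostrings::readDNAStringSet(file.path(dir, "hairpins.fa"))
  gn <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  gff <- rtracklayer::import(file.path(dir, "annotation.gff3"), format = "gff3")
  is_mat <- gff$type == "miRNA"
  feats <- gff[!is_mat]
  features <- tibble(
    feature_id = as.character(feats$ID),
    class = as.character(feats$type),
    start = GenomicRanges::start(feats) - 1L,
    end = GenomicRanges::end(feats),
    strand = as.character(GenomicRanges::strand(feats)))
  hairpins <- tibble(
    hairpin_id = names(hp),
    sequence = unname(as.character(hp))) |>
    dplyr::left_join(features |>
                       dplyr::select(feature_id, genome_start = start,
                                     genome_end = end),
                     by = c("hairpin_id" = "feature_id"))
  mats <- gff[is_mat]
  parent <- vapply(mats$Parent, function(p) as.character(p)[1], "")
  matures <- tibble(
    mature_id = as.character(mats$ID),
    hairpin_id = parent,
    genome_start = GenomicRanges::start(mats) - 1L,
    genome_end = GenomicRanges::end(mats)) |>
    dplyr::mutate(
      start = genome_start -
        hairpins$genome_start[match(hairpin_id, hairpins$hairpin_id)],
      end = start + (genome_end - genome_start),
      arm = ifelse(grepl("5p$", mature_id), "5p", "3p"),
      sequence = unname(substr0(
        hairpins$sequence[match(hairpin_id, hairpins$hairpin_id)],
        start, end))) |>
    dplyr::select(mature_id, hairpin_id, start, end, arm, sequence,
                  genome_start, genome_end)
  out <- list(hairpins = hairpins, matures = matures, features = features,
              genome = as.character(gn[[1]]),
              high_confidence = matures$mature_id)
  class(out) <- "exo_reference"
  out
}
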