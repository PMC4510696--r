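#' Published miRNA enrichment tables and copy numbers
#'
#' Accessors for the packaged transcriptions of the published results this
#' pipeline reproduces: the seven-category lists of miRNAs differentially
#' enriched in cells (`exo_table_cells()`) and in exosomes
#' (`exo_table_exosomes()`) across the three KRAS-isogenic CRC lines
#' (DKO-1 mutant, DKs-8 wild-type, DLD-1 parental), and the absolute
#' miR-100 copy numbers measured by Taqman qPCR in recipient cells from
#' the Transwell co-culture experiment (`mir100_copy_numbers()`).
#'
#' Categories are the standard seven regions of a three-set partition,
#' labelled `"DKO-1"`, `"DKs-8"`, `"DLD-1"` (unique to one line),
#' `"DKO-1&DKs-8"`, `"DKO-1&DLD-1"`, `"DLD-1&DKs-8"` (pairwise), and
#' `"DKO-1&DLD-1&DKs-8"` (shared by all three).
#'
#' @return `exo_table_cells()` / `exo_table_exosomes()`: tibble with
#'   `category` and `mirna`. `mir100_copy_numbers()`: tibble with
#'   `condition` (`"AI-100"`, `"AI-CTL"`, `"no donor"`), `copies`, `sem`.
#' @export
exo_table_cells <- function() {
  .category_list_to_tibble(.cell_enriched_mirnas)
}

#' @rdname exo_table_cells
#' @export
exo_table_exosomes <- function() {
  .category_list_to_tibble(.exosome_enriched_mirnas)
}

#' @rdname exo_table_cells
#' @export
mir100_copy_numbers <- function() {
  as_tibble(.mir100_copy_numbers)
}

.category_list_to_tibble <- function(x) {
  dplyr::bind_rows(lapply(names(x), function(cat) {
    tibble(category = cat, mirna = x[[cat]])
  }))
}

#' Write the packaged result tables as TSV fixtures
#'
#' Emits `table1_cells.tsv` and `table2_exosomes.tsv` (seven category
#' blocks of miRNA names each) and `mir100_copy_numbers.tsv` (printed
#' absolute copy numbers with SEMs) into `outdir`.
#'
#' @param outdir output directory (created if needed).
#' @return invisibly, the vector of paths written.
#' @export
write_fixture_tables <- function(outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(outdir, "table1_cells.tsv")
  p2 <- file.path(outdir, "table2_exosomes.tsv")
  p3 <- file.path(outdir, "mir100_copy_numbers.tsv")
  utils::write.table(exo_table_cells(), p1, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(exo_table_exosomes(), p2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(mir100_copy_numbers(), p3, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(p1, p2, p3))
}

#' Parse a seven-category miRNA table fixture
#'
#' Reads a TSV with columns `category` and `mirna`, validates the category
#' labels against the seven regions of a three-set partition over the
#' given set names, and rejects duplicate miRNA names within a block.
#' Errors cite the offending line number.
#'
#' @param path TSV file as written by [write_fixture_tables()].
#' @param set_names the three underlying set names (default the three CRC
#'   cell lines).
#' @return an `exo_partition`: tibble (`category`, `mirna`) whose
#'   [partition_counts()] gives per-category counts for all seven regions.
#' @export
read_category_table <- function(path,
                                set_names = c("DKO-1", "DKs-8", "DLD-1")) {
  lines <- readLines(path)
  if (!length(lines) || !identical(strsplit(lines[1], "\t")[[1]],
                                   c("category", "mirna"))) {
    abort(sprintf("%s: line 1: expected header 'category\\tmirna'", path))
  }
  valid <- .partition_labels(set_names)
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  out <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r) != 2L || !nzchar(r[1]) || !nzchar(r[2])) {
      abort(sprintf("%s: line %d: malformed row", path, i + 1L))
    }
    if (!r[1] %in% valid) {
      abort(sprintf("%s: line %d: unknown category block '%s'",
                    path, i + 1L, r[1]))
    }
    out[[i]] <- tibble(category = r[1], mirna = r[2])
  }
  df <- dplyr::bind_rows(out)
  dup <- df |> dplyr::count(category, mirna) |> dplyr::filter(n > 1)
  if (nrow(dup)) {
    first_dup <- which(duplicated(paste(df$category, df$mirna)))[1]
    abort(sprintf("%s: line %d: duplicate name '%s' within block '%s'",
                  path, first_dup + 1L,
                  df$mirna[first_dup], df$category[first_dup]))
  }
  structure(df, class = c("exo_partition", class(df)),
            set_names = set_names)
}

.partition_labels <- function(set_names) {
  stopifnot(length(set_names) == 3)
  a <- set_names[1]; b <- set_names[2]; c <- set_names[3]
  c(a, b, c,
    paste(a, b, sep = "&"), paste(a, c, sep = "&"), paste(c, b, sep = "&"),
    paste(a, c, b, sep = "&"))
}
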