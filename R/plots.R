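#' Stacked-bar plot of library composition by ncRNA class
#'
#' @param x an `exo_composition` (or a tibble binding several with a
#'   `sample` column).
#' @return a ggplot.
#' @export
plot_composition <- function(x) {
  df <- if (inherits(x, "exo_composition")) x$composition else x
  if (!"sample" %in% names(df)) df$sample <- "library"
  ggplot2::ggplot(df, ggplot2::aes(x = sample, y = fraction, fill = category)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "fraction of mapped reads",
                  fill = "class") +
    ggplot2::theme_minimal()
}

#' Length distribution coloured by 5' base
#'
#' @param profile output of [length_firstbase_profile()].
#' @return a ggplot.
#' @export
plot_length_firstbase <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = length, y = weight, fill = base)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "read length (nt)", y = "weighted reads",
                  fill = "5' base") +
    ggplot2::theme_minimal()
}

#' Bar plot of 3' modification status fractions
#'
#' @param x an `exo_trimtail` from [trim_tail_summary()].
#' @return a ggplot.
#' @export
plot_trim_tail <- function(x) {
  df <- x$summary
  has_sample <- "sample" %in% names(df)
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = if (has_sample) sample else status,
    y = fraction,
    fill = status)) +
    ggplot2::geom_col(position = if (has_sample) "stack" else "dodge") +
    ggplot2::labs(x = NULL, y = "fraction of classified reads",
                  fill = "3' status") +
    ggplot2::theme_minimal()
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' PCA score plot
#'
#' @param object an `exo_pca` from [pca_samples()].
#' @param colour optional vector (length = samples) to colour points by.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.exo_pca <- function(object, colour = NULL, ...) {
  df <- object$scores
  if (!is.null(colour)) df$colour <- colour
  p <- ggplot2::ggplot(df, ggplot2::aes(x = PC1, y = PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2])) +
    ggplot2::theme_minimal()
  if (is.null(colour)) p + ggplot2::geom_point()
  else p + ggplot2::geom_point(ggplot2::aes(colour = colour)) +
    ggplot2::labs(colour = NULL)
}

#' Standard-curve plot with fitted regression line
#'
#' @param curve an `exo_std_curve`.
#' @return a ggplot.
#' @export
plot_standard_curve <- function(curve) {
  ggplot2::ggplot(curve$dilution_table,
                  ggplot2::aes(x = log10_copies, y = mean_ct)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = curve$slope, intercept = curve$intercept,
                         linetype = 2) +
    ggplot2::labs(x = "log10(copies/ul)", y = "mean Ct") +
    ggplot2::theme_minimal()
}
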