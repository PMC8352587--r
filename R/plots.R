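#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_col geom_raster
#'   geom_hline labs facet_wrap scale_fill_viridis_c theme_minimal autoplot
NULL

#' @export
ggplot2::autoplot

#' Heatmap of an insertion-centric signal matrix
#'
#' Rows sorted by genomic coordinate (the default sort of the underlying
#' insertion table); x axis is the distance to the junction, oriented 5'->3'.
#'
#' @param object a [insertion_matrix()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.signal_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$offset, y = .data$id, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c(name = "rpm", na.value = "grey90") +
    labs(x = "distance to junction (bp, 5'→3')", y = NULL) +
    theme_minimal()
}

#' @export
tidy.signal_matrix <- function(x, ...) {
  m <- x$matrix
  offsets <- seq(-x$flank, x$flank - x$bin_size, by = x$bin_size)
  tibble(
    id = rep(rownames(m), times = ncol(m)),
    offset = rep(offsets, each = nrow(m)),
    value = as.vector(m))
}

#' Metaplot of a signal matrix
#'
#' @param sm a [insertion_matrix()] result (or a [metaprofile()] tibble).
#' @return a ggplot.
#' @export
plot_metaprofile <- function(sm) {
  mp <- if (inherits(sm, "signal_matrix")) metaprofile(sm) else sm
  ggplot(mp, aes(x = .data$offset, y = .data$mean)) +
    geom_line() +
    labs(x = "distance to junction (bp, 5'→3')", y = "mean rpm") +
    theme_minimal()
}

#' TE transcriptome fraction across the time course
#'
#' @param tc a [te_fraction_timecourse()] result.
#' @param by_family plot per-family percentages instead of the total.
#' @return a ggplot.
#' @export
plot_te_timecourse <- function(tc, by_family = FALSE) {
  if (by_family) {
    ggplot(tc$by_family,
           aes(x = .data$timepoint, y = .data$pct, group = .data$family,
               colour = .data$family)) +
      geom_line() + geom_point() +
      labs(x = "timepoint (h AEL)", y = "% of transcriptome") +
      theme_minimal()
  } else {
    ggplot(tc$total, aes(x = .data$timepoint, y = .data$te_pct, group = 1)) +
      geom_line() + geom_point() +
      labs(x = "timepoint (h AEL)", y = "TE % of transcriptome") +
      theme_minimal()
  }
}

#' MA plot of a differential result
#'
#' @param object a [te_differential()] / [nb_test()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.nb_diff <- function(object, ...) {
  df <- tidy(object)
  if (!"log10_base_mean" %in% names(df))
    df$log10_base_mean <- log10(df$base_mean + 1)
  if (!"class" %in% names(df))
    df$class <- ifelse(!is.na(df$padj) & df$padj < 0.05, "sig", "ns")
  ggplot(dplyr::filter(df, .data$status == "tested"),
         aes(x = .data$log10_base_mean, y = .data$log2fc,
             colour = .data$class)) +
    geom_point(size = 0.8) +
    geom_hline(yintercept = 0, linetype = 2) +
    labs(x = "log10 base mean", y = "log2 fold-change") +
    theme_minimal()
}

#' Small RNA size profile plot
#'
#' @param profile a [size_profile()] tibble.
#' @return a ggplot.
#' @export
plot_size_profile <- function(profile) {
  ggplot(profile, aes(x = .data$length, y = .data$count,
                      fill = .data$orientation)) +
    geom_col(position = "dodge") +
    labs(x = "read length (nt)", y = "reads") +
    theme_minimal()
}
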