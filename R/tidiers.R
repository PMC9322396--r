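#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy per-gene records of a pipeline result
#'
#' @param x An `hrp_result`.
#' @param ... Unused.
#' @return The per-gene tibble (one row per output gene model).
#' @exportS3Method generics::tidy
tidy.hrp_result <- function(x, ...) x$genes

#' One-row summary of a pipeline result
#'
#' @param x An `hrp_result`.
#' @param ... Unused.
#' @return A one-row tibble with totals by block.
#' @exportS3Method generics::glance
glance.hrp_result <- function(x, ...) {
  g <- x$genes
  tibble(
    n_genes = nrow(g),
    n_full_length = sum(g$full_length),
    n_partial = sum(!g$full_length),
    n_pseudogenes = sum(g$pseudogene),
    n_cnl = sum(g$class == "CNL"), n_tnl = sum(g$class == "TNL"),
    n_rnl = sum(g$class == "RNL"), n_nl = sum(g$class == "NL"),
    n_rescued = nrow(x$rescued), n_motifs = length(x$motifs)
  )
}

#' Class-count bar chart for a pipeline result
#'
#' @param object An `hrp_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.hrp_result <- function(object, ...) {
  g <- object$genes
  df <- g |>
    dplyr::count(.data$class, .data$full_length) |>
    mutate(block = ifelse(.data$full_length, "full-length", "partial"))
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$class, -.data$n),
                                   y = .data$n, fill = .data$block)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "architecture class", y = "gene models",
                  fill = NULL, title = "Predicted NB-LRR repertoire") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Exon-structure plot of gene models in a genomic interval
#'
#' @param models Gene-model tibble.
#' @param seqid Sequence to display (default: first).
#' @param xlim Optional genomic interval `c(from, to)`.
#' @return A ggplot object with one row per model and boxes for exons.
#' @export
plot_gene_models <- function(models, seqid = NULL, xlim = NULL) {
  seqid <- seqid %||% models$seqid[1]
  m <- models[models$seqid == seqid, ]
  sp <- model_span(m)
  if (!is.null(xlim)) {
    keep <- sp$end >= xlim[1] & sp$start <= xlim[2]
    m <- m[keep, ]; sp <- sp[keep, ]
  }
  ex <- bind_rows(map(seq_len(nrow(m)), function(i) {
    e <- m$exons[[i]]
    tibble(id = m$id[i], strand = m$strand[i], y = i,
           start = e[, "start"], end = e[, "end"])
  }))
  sp$y <- seq_len(nrow(m)); sp$id <- m$id
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = sp, ggplot2::aes(x = .data$start,
                                                  xend = .data$end,
                                                  y = .data$y, yend = .data$y),
                          linewidth = 0.3) +
    ggplot2::geom_rect(data = ex, ggplot2::aes(
      xmin = .data$start, xmax = .data$end,
      ymin = .data$y - 0.3, ymax = .data$y + 0.3, fill = .data$strand)) +
    ggplot2::scale_y_continuous(breaks = sp$y, labels = sp$id) +
    ggplot2::labs(x = sprintf("%s position (bp)", seqid), y = NULL,
                  fill = "strand") +
    ggplot2::theme_minimal()
}
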