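#' Plot a 2-D cell embedding
#'
#' @param embedding An `scms_embedding` from [embed_cells()].
#' @param labels Optional per-cell labels used for colour.
#' @param method Which stored embedding to draw.
#' @return A ggplot.
#' @export
plot_embedding <- function(embedding, labels = NULL, method = "umap") {
  stopifnot(inherits(embedding, "scms_embedding"))
  if (!method %in% names(embedding$embeddings)) {
    abort(paste0("Embedding '", method, "' was not computed."))
  }
  xy <- embedding$embeddings[[method]]
  df <- tibble(x = xy[, 1], y = xy[, 2],
               label = if (is.null(labels)) "cell" else as.character(labels))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, colour = .data$label)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.8) +
    ggplot2::labs(x = paste0(method, " 1"), y = paste0(method, " 2"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential-expression result
#'
#' @param object An `scms_de` tibble from [welch_de()].
#' @param ... Unused.
#' @return A ggplot of log2 fold change against -log10 p, significant
#'   proteins highlighted.
#' @method autoplot scms_de
#' @export
autoplot.scms_de <- function(object, ...) {
  df <- dplyr::filter(object, .data$tested, is.finite(.data$log2fc))
  ggplot2::ggplot(df, ggplot2::aes(.data$log2fc, -log10(.data$p),
                                   colour = .data$significant)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p", colour = "significant") +
    ggplot2::theme_minimal()
}

#' Histogram of per-protein mean CVs
#'
#' @param object An `scms_cv_profile` from [protein_cv_profile()].
#' @param ... Unused.
#' @return A ggplot with the CV threshold marked.
#' @method autoplot scms_cv_profile
#' @export
autoplot.scms_cv_profile <- function(object, ...) {
  df <- dplyr::filter(object$per_protein, !is.na(.data$mean_cv))
  ggplot2::ggplot(df, ggplot2::aes(.data$mean_cv)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue") +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = 2) +
    ggplot2::labs(x = "mean CV per protein", y = "proteins") +
    ggplot2::theme_minimal()
}

#' Trajectory cluster signatures along pseudotime
#'
#' @param object An `scms_signatures` from [protein_cluster_signatures()].
#' @param ... Unused.
#' @return A ggplot of each cluster signature across the ordered cells.
#' @method autoplot scms_signatures
#' @export
autoplot.scms_signatures <- function(object, ...) {
  sig <- object$signatures
  df <- tibble(
    cluster = rep(rownames(sig), times = ncol(sig)),
    position = rep(seq_len(ncol(sig)), each = nrow(sig)),
    value = as.vector(sig)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$position, .data$value,
                                   colour = .data$cluster)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "cells ordered by pseudotime",
                  y = "signature (0-1 normalized)", colour = NULL) +
    ggplot2::theme_minimal()
}
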