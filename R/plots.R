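#' Heat map of a clone-by-site methylation matrix
#'
#' One tile per clone and CpG site, coloured black (frequency 0) through
#' blue (0.5) to yellow (1), the convention of the assay's published heat
#' maps; clones are grouped by expression label.
#'
#' @param object A `meth_matrix`.
#' @param fragment Optional fragment name to restrict to.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.meth_matrix <- function(object, fragment = NULL, ...) {
  tbl <- object$sites
  if (!is.null(fragment)) tbl <- filter(tbl, .data$fragment == !!fragment)
  tbl <- mutate(tbl,
                group = ifelse(.data$expression == 1, "expressing",
                               "non-expressing"))
  ggplot2::ggplot(tbl, ggplot2::aes(x = factor(.data$site),
                                    y = .data$clone_id,
                                    fill = .data$frequency)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradientn(
      colours = c("black", "blue", "yellow"), limits = c(0, 1),
      name = "methylation\nfrequency") +
    ggplot2::facet_grid(group ~ fragment, scales = "free",
                        space = "free") +
    ggplot2::labs(x = "CpG site (promoter coordinate)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
}

#' Per-site significance profile
#'
#' -log10 p-value of the expressing vs non-expressing comparison along
#' the promoter, with the significance threshold drawn as a dashed line.
#'
#' @param site_tests Result of [compare_sites()].
#' @param alpha Threshold to draw (default 0.05).
#' @return A ggplot object.
#' @export
plot_site_tests <- function(site_tests, alpha = 0.05) {
  ggplot2::ggplot(site_tests,
                  ggplot2::aes(x = .data$site,
                               y = -log10(.data$p_value),
                               colour = .data$fragment)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::labs(x = "CpG site (promoter coordinate)",
                  y = expression(-log[10]~p)) +
    ggplot2::theme_minimal()
}

#' Diagram of a fitted classification tree
#'
#' Branch nodes are drawn as ellipse-style labels with their threshold
#' inequality; every node shows its majority label (A/P) and
#' misclassification ratio.
#'
#' @param object A `meth_cart`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.meth_cart <- function(object, ...) {
  nodes <- tidy(object)
  pos <- list()
  counter <- new.env()
  assign("x", 0, envir = counter)
  layout <- function(node, id, depth) {
    if (is.null(node$split)) {
      x <- get("x", envir = counter) + 1
      assign("x", x, envir = counter)
      pos[[as.character(id)]] <<- c(x = x, y = -depth)
      return(list(id = id, x = x, next_id = id + 1L))
    }
    l <- layout(node$left, id + 1L, depth + 1)
    r <- layout(node$right, l$next_id, depth + 1)
    x <- (l$x + r$x) / 2
    pos[[as.character(id)]] <<- c(x = x, y = -depth)
    list(id = id, x = x, next_id = r$next_id)
  }
  layout(object$root, 1L, 0)
  xy <- do.call(rbind, pos[as.character(nodes$node)])
  nodes$x <- xy[, "x"]
  nodes$y <- xy[, "y"]
  edges <- filter(nodes, !is.na(.data$parent)) %>%
    left_join(select(nodes, "node", px = "x", py = "y"),
              by = c(parent = "node"))
  nodes <- mutate(nodes,
                  txt = ifelse(.data$leaf,
                               sprintf("%s\n%d/%d", .data$label,
                                       pmin(.data$n_exp, .data$n_nonexp),
                                       .data$n_exp + .data$n_nonexp),
                               sprintf("%s %s < %.3g\n%d/%d", .data$label,
                                       .data$site, .data$threshold,
                                       pmin(.data$n_exp, .data$n_nonexp),
                                       .data$n_exp + .data$n_nonexp)))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$px, y = .data$py,
                                       xend = .data$x, yend = .data$y),
                          colour = "grey50") +
    ggplot2::geom_label(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     label = .data$txt,
                                     fill = .data$leaf),
                        size = 3, show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "grey90",
                                          `FALSE` = "lightsteelblue1")) +
    ggplot2::theme_void()
}
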