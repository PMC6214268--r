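#' Tidiers and plots for census objects
#'
#' `tidy()` returns the counts in long form (one row per unit, orbit and
#' kind); `glance()` a one-row summary of the graph and scan; `autoplot()` a
#' column chart of the total count per orbit.
#'
#' @param x a `quad_census` or `triad_census` object.
#' @param ... unused.
#' @return a tibble (`tidy`, `glance`) or a ggplot (`autoplot`).
#' @name census-methods
NULL

census_long <- function(counts, id_cols, orbit_meta) {
  purrr::imap_dfr(counts, function(tb, nm) {
    if (!any(grepl("^o[0-9]+$", names(tb)))) return(NULL)
    long <- tidyr::pivot_longer(tb, cols = dplyr::matches("^o[0-9]+$"),
                                names_to = "orbit", values_to = "count")
    long$orbit <- as.integer(sub("^o", "", long$orbit))
    long$kind <- if (grepl("noninduced", nm)) "non_induced" else "induced"
    dplyr::left_join(long, orbit_meta, by = "orbit")
  })
}

#' @rdname census-methods
#' @export
tidy.quad_census <- function(x, ...) {
  info <- quad_orbit_info()
  out <- list()
  node_meta <- info$nodes[, c("orbit", "quad")]
  edge_meta <- info$edges[, c("orbit", "quad")]
  nds <- x$counts[grep("^node", names(x$counts))]
  eds <- x$counts[grep("^edge", names(x$counts))]
  res <- dplyr::bind_rows(
    census_long(nds, "node", node_meta),
    census_long(eds, c("u", "v"), edge_meta)
  )
  if (!is.null(x$counts$graph)) {
    res <- dplyr::bind_rows(res, dplyr::mutate(x$counts$graph,
                                               kind = "induced"))
  }
  tibble::as_tibble(res)
}

#' @rdname census-methods
#' @export
glance.quad_census <- function(x, ...) {
  tibble::tibble(
    n = x$graph$n, m = x$graph$m, degeneracy = x$degeneracy,
    n_triangles = x$n_triangles, n_k4 = x$n_k4,
    n_c4_noninduced = x$n_c4_noninduced,
    n_quads = choose(x$graph$n, 4)
  )
}

#' @rdname census-methods
#' @export
tidy.triad_census <- function(x, ...) {
  blocks <- triad_blocks()
  meta <- tibble::tibble(
    orbit = unlist(blocks, use.names = FALSE),
    triad = rep(names(blocks), lengths(blocks))
  )
  long <- tidyr::pivot_longer(x$counts$node,
                              cols = dplyr::matches("^o[0-9]+$"),
                              names_to = "orbit", values_to = "count")
  long$orbit <- as.integer(sub("^o", "", long$orbit))
  tibble::as_tibble(dplyr::left_join(long, meta, by = "orbit"))
}

#' @rdname census-methods
#' @export
glance.triad_census <- function(x, ...) {
  g <- x$graph_obj
  tibble::tibble(
    n = g$n, m = g$m,
    mutual_dyads = sum(g$d_mut) / 2,
    asymmetric_dyads = g$m - sum(g$d_mut),
    n_triads = choose(g$n, 3)
  )
}

#' @rdname census-methods
#' @param object a census object (ggplot2 convention).
#' @export
autoplot.quad_census <- function(object, ...) {
  long <- tidy(object)
  long <- long[!is.na(long$orbit), ]
  agg <- dplyr::summarise(dplyr::group_by(long, .data$orbit, .data$kind),
                          count = sum(.data$count), .groups = "drop")
  ggplot2::ggplot(agg, ggplot2::aes(x = factor(.data$orbit),
                                    y = .data$count,
                                    fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "orbit", y = "total count",
                  title = "Quad orbit counts") +
    ggplot2::theme_minimal()
}

#' @rdname census-methods
#' @export
autoplot.triad_census <- function(object, ...) {
  gr <- object$counts$graph
  gr$triad <- factor(gr$triad, levels = triad_class_names())
  ggplot2::ggplot(gr, ggplot2::aes(x = .data$triad, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "triad class", y = "count",
                  title = "Graph-level triad census") +
    ggplot2::theme_minimal()
}
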