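#' Write census tables as TSV
#'
#' Node level: columns `node`, `o0..`; edge level: `u`, `v`, `o0..`; graph
#' level: one labelled row. Counts are written as plain integers.
#'
#' @param x a `quad_census` or `triad_census` object.
#' @param path output file path (or `""` for stdout).
#' @param which which counts table to write (a name of `x$counts`); may be
#'   omitted when the object holds exactly one table.
#' @return `path`, invisibly.
#' @export
write_census_tsv <- function(x, path, which = NULL) {
  stopifnot(inherits(x, c("quad_census", "triad_census")))
  if (is.null(which)) {
    if (length(x$counts) != 1L) {
      stop("object holds ", length(x$counts),
           " tables; pass `which` (one of: ",
           paste(names(x$counts), collapse = ", "), ")", call. = FALSE)
    }
    which <- names(x$counts)[1L]
  }
  tb <- x$counts[[which]]
  if (is.null(tb)) stop("no counts table named '", which, "'", call. = FALSE)
  if (which == "graph" && "count" %in% names(tb)) {
    wide <- as.data.frame(as.list(stats::setNames(
      format_count(tb$count), tb[[1L]])), check.names = FALSE)
    utils::write.table(wide, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    tb <- as.data.frame(tb)
    num <- vapply(tb, is.numeric, logical(1))
    tb[num] <- lapply(tb[num], format_count)
    utils::write.table(tb, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

format_count <- function(x) {
  formatC(x, format = "f", digits = 0)
}
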