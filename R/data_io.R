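#' Plot tables
#'
#' A plot table holds one row per sample plot with aligned covariates and
#' observed stand basal area for the two species strata (\code{P}, \code{B})
#' and the stand total (\code{t}).  Canonical wide-format columns are
#' \code{plot_id} plus, for each stratum suffix \code{_P}, \code{_B},
#' \code{_t}: \code{si} (m), \code{adbh} (years), \code{sdi} (trees/ha),
#' optional \code{dg} (cm) and \code{n_stems} (trees/ha), and \code{sba}
#' (m2/ha).
#'
#' Validation enforces: unique \code{plot_id}; all covariates positive where
#' present; \code{sba_t == sba_P + sba_B} within 1e-6 absolute (basal area is
#' a physical sum, so a larger discrepancy is a data error); where a stratum's
#' \code{sdi} column is absent it is derived from \code{n_stems} and \code{dg}
#' via \code{\link{reineke_sdi}}.
#'
#' @param x a data.frame in canonical wide format.
#' @param provenance free-text source tag.
#' @return an object of classes \code{c("plot_table", "data.frame")}.
#' @seealso \code{\link{read_plot_table}}, \code{\link{write_plot_table}}
#' @export
plot_table <- function(x, provenance = "constructed") {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!"plot_id" %in% names(x)) stop("schema error: missing column `plot_id`")
  for (s in c("P", "B", "t")) {
    sdi_col <- paste0("sdi_", s)
    if (!sdi_col %in% names(x)) {
      ns <- paste0("n_stems_", s); dg <- paste0("dg_", s)
      if (all(c(ns, dg) %in% names(x))) {
        x[[sdi_col]] <- reineke_sdi(x[[ns]], x[[dg]])
      } else {
        stop(sprintf(
          "schema error: missing column `%s` (and no `%s`/`%s` to derive it)",
          sdi_col, ns, dg))
      }
    }
    for (v in c("si_", "adbh_", "sba_")) {
      col <- paste0(v, s)
      if (!col %in% names(x))
        stop("schema error: missing column `", col, "`")
    }
  }
  if (anyDuplicated(x$plot_id))
    stop("validation error: duplicated plot_id: ",
         paste(unique(x$plot_id[duplicated(x$plot_id)]), collapse = ", "))
  required <- as.vector(outer(c("si_", "adbh_", "sdi_", "sba_"),
                              c("P", "B", "t"), paste0))
  num_cols <- setdiff(names(x), "plot_id")
  for (col in num_cols) {
    x[[col]] <- as.numeric(x[[col]])
    if (col %in% required && anyNA(x[[col]]))
      stop(sprintf("validation error: missing `%s` for plot_id %s",
                   col, x$plot_id[which(is.na(x[[col]]))[1]]))
    bad <- !is.na(x[[col]]) & (!is.finite(x[[col]]) | x[[col]] <= 0)
    # observed SBA may legitimately be tiny but must still be positive
    if (any(bad))
      stop(sprintf("validation error: non-positive `%s` for plot_id %s",
                   col, x$plot_id[which(bad)[1]]))
  }
  gap <- abs(x$sba_t - (x$sba_P + x$sba_B))
  if (any(gap > 1e-6))
    stop(sprintf(
      "validation error: sba_t != sba_P + sba_B for plot_id %s (gap %.3g)",
      x$plot_id[which.max(gap)], max(gap)))
  rownames(x) <- NULL
  structure(x, provenance = provenance,
            class = c("plot_table", "data.frame"))
}

#' Read a plot table from delimited text
#'
#' Reads a UTF-8 delimited file (comma default, header row, decimal point)
#' into a validated \code{\link{plot_table}}.  Row order is preserved and
#' missing per-stratum SDI columns are derived from stem count and quadratic
#' mean DBH.
#'
#' @param path path to the file.
#' @param column_map optional named character vector or list mapping
#'   canonical column names (e.g. \code{"sba_P"}) to the names used in the
#'   file.
#' @param delimiter field separator, default \code{","}.
#' @param layout \code{"wide"} (canonical, one row per plot) or
#'   \code{"long"} (columns \code{plot_id}, \code{stratum} in P/B/t, then
#'   unsuffixed variables), converted to wide on ingest.
#' @return a \code{\link{plot_table}}.
#' @export
read_plot_table <- function(path, column_map = NULL, delimiter = ",",
                            layout = c("wide", "long")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.table(path, header = TRUE, sep = delimiter,
                         stringsAsFactors = FALSE, check.names = FALSE,
                         fileEncoding = "UTF-8")
  if (!is.null(column_map)) {
    column_map <- unlist(column_map)
    missing <- setdiff(unname(column_map), names(x))
    if (length(missing))
      stop("schema error: mapped column(s) not in file: ",
           paste(missing, collapse = ", "))
    idx <- match(unname(column_map), names(x))
    names(x)[idx] <- names(column_map)
  }
  if (layout == "long") x <- .long_to_wide(x)
  plot_table(x, provenance = path)
}

.long_to_wide <- function(x) {
  need <- c("plot_id", "stratum")
  if (!all(need %in% names(x)))
    stop("schema error: long layout needs columns `plot_id` and `stratum`")
  vars <- setdiff(names(x), need)
  ids <- unique(x$plot_id)
  out <- data.frame(plot_id = ids, stringsAsFactors = FALSE)
  for (s in unique(x$stratum)) {
    sub <- x[x$stratum == s, , drop = FALSE]
    sub <- sub[match(ids, sub$plot_id), vars, drop = FALSE]
    names(sub) <- paste0(vars, "_", s)
    out <- cbind(out, sub)
  }
  rownames(out) <- NULL
  out
}

#' Write a plot table to delimited text
#'
#' Numeric fields are written with 17 significant digits so that
#' \code{read_plot_table(write_plot_table(x))} reproduces every value to
#' full double precision.
#'
#' @param x a \code{\link{plot_table}}.
#' @param path output path.
#' @param delimiter field separator, default \code{","}.
#' @return \code{path}, invisibly.
#' @export
write_plot_table <- function(x, path, delimiter = ",") {
  stopifnot(inherits(x, "plot_table"))
  out <- as.data.frame(x)
  for (col in names(out))
    if (is.numeric(out[[col]]))
      out[[col]] <- sprintf("%.17g", out[[col]])
  utils::write.table(out, path, sep = delimiter, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.plot_table <- function(x, ...) {
  cat(sprintf("Plot table: %d plots (%s)\n", nrow(x),
              attr(x, "provenance")))
  print.data.frame(utils::head(as.data.frame(x), 6), digits = 4)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

# Pull (y, covariates) for one stratum; species equations use the stratum's
# own (species-partial) covariate columns.
.stratum_data <- function(data, stratum) {
  stopifnot(stratum %in% c("P", "B", "t"))
  list(y = data[[paste0("sba_", stratum)]],
       covariates = data.frame(si = data[[paste0("si_", stratum)]],
                               adbh = data[[paste0("adbh_", stratum)]],
                               sdi = data[[paste0("sdi_", stratum)]]))
}
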