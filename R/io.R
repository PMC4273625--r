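#' Load the packaged 87-ROI parcellation table
#'
#' Returns the region-of-interest table used throughout the pipeline: 87 ROIs
#' drawn from three functional systems of the resting brain (default mode,
#' fronto-parietal task control, cingulo-opercular task control), with MNI
#' coordinates, anatomical (AAL) names, and the reference community
#' assignments obtained in the very-low-frequency (VLF, 0.01-0.03 Hz) and
#' low-frequency (LF, 0.07-0.09 Hz) bands. Community numerals are arbitrary
#' labels, never magnitudes.
#'
#' @return A data.frame with 87 rows and columns `roi_id`, `mni_x`, `mni_y`,
#'   `mni_z`, `dosenbach_label`, `system`, `aal_name`, `community_vlf`,
#'   `community_lf`. Row order matches ROI numbering.
#' @export
#' @examples
#' roi <- load_roi_table()
#' nrow(roi)            # 87
#' table(roi$system)    # three functional systems
load_roi_table <- function() {
  path <- system.file("extdata", "roi_table_87.tsv", package = "freqnet",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  expected <- c("roi_id", "mni_x", "mni_y", "mni_z", "dosenbach_label",
                "system", "aal_name", "community_vlf", "community_lf")
  if (!identical(names(tab), expected)) {
    stop("ROI table fixture is corrupted: unexpected columns", call. = FALSE)
  }
  systems <- c("Default", "Fronto-parietal", "Cingulo-opercular")
  for (r in seq_len(nrow(tab))) {
    row <- tab[r, ]
    bad <- !is.finite(row$mni_x) || !is.finite(row$mni_y) ||
      !is.finite(row$mni_z) ||
      !(row$system %in% systems) ||
      !(row$community_vlf %in% 1:9) || !(row$community_lf %in% 1:9) ||
      row$roi_id != r
    if (bad) {
      stop(sprintf("ROI table fixture is corrupted at row %d", r),
           call. = FALSE)
    }
  }
  if (nrow(tab) != 87L) {
    stop("ROI table fixture is corrupted: expected 87 rows", call. = FALSE)
  }
  tab
}

#' Construct an ROI time-series panel
#'
#' @param values numeric matrix, time points in rows, ROIs in columns.
#' @param dt sampling interval in seconds (> 0).
#' @param subject_id subject identifier.
#' @return An object of class `ts_panel`.
#' @export
ts_panel <- function(values, dt, subject_id = "subject") {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("panel values must be numeric", call. = FALSE)
  if (ncol(values) < 2L) stop("panel needs at least 2 ROI columns", call. = FALSE)
  if (anyNA(values)) stop("panel contains missing values", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    stop("dt must be a single positive number of seconds", call. = FALSE)
  }
  structure(
    list(values = values, dt = dt, subject_id = as.character(subject_id)),
    class = "ts_panel"
  )
}

#' @export
print.ts_panel <- function(x, ...) {
  cat(sprintf("<ts_panel '%s': %d time points x %d ROIs, dt = %g s>\n",
              x$subject_id, nrow(x$values), ncol(x$values), x$dt))
  invisible(x)
}

# Tab or comma only; anything else is an error rather than a silent misparse.
detect_delimiter <- function(line) {
  if (grepl("\t", line)) return("\t")
  if (grepl(",", line)) return(",")
  stop("could not detect delimiter: only tab- and comma-separated panels are supported",
       call. = FALSE)
}

#' Read an ROI time-series panel from a delimited text file
#'
#' One row per time point, one column per ROI. Tab and comma delimiters are
#' auto-detected; an optional single header row supplies ROI names.
#'
#' @param path path to a TSV/CSV file.
#' @param dt sampling interval in seconds.
#' @param subject_id subject identifier (defaults to the file name).
#' @return A [ts_panel()].
#' @export
read_timeseries_panel <- function(path, dt,
                                  subject_id = sub("\\.[^.]*$", "", basename(path))) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) stop("empty panel file: ", path, call. = FALSE)
  delim <- detect_delimiter(lines[[1L]])
  fields <- strsplit(lines, delim, fixed = TRUE)
  widths <- lengths(fields)
  if (any(widths != widths[[1L]])) {
    bad <- which(widths != widths[[1L]])[[1L]]
    stop(sprintf("ragged row in %s at line %d (%d fields, expected %d)",
                 path, bad, widths[[bad]], widths[[1L]]), call. = FALSE)
  }
  first <- suppressWarnings(as.numeric(fields[[1L]]))
  has_header <- anyNA(first)
  col_names <- if (has_header) trimws(fields[[1L]]) else NULL
  data_rows <- if (has_header) fields[-1L] else fields
  if (length(data_rows) == 0L) stop("panel file has a header but no data: ", path, call. = FALSE)
  values <- matrix(NA_real_, nrow = length(data_rows), ncol = widths[[1L]])
  for (r in seq_along(data_rows)) {
    v <- suppressWarnings(as.numeric(data_rows[[r]]))
    if (anyNA(v)) {
      stop(sprintf("non-numeric cell in %s at line %d", path,
                   r + has_header), call. = FALSE)
    }
    values[r, ] <- v
  }
  if (!is.null(col_names)) colnames(values) <- col_names
  ts_panel(values, dt = dt, subject_id = subject_id)
}

#' Write a numeric matrix as TSV
#'
#' Values are written with full double precision so that write/read
#' round-trips are lossless to at least 12 significant digits.
#'
#' @param mat numeric matrix (or an object with a `values` matrix field).
#' @param path output path.
#' @export
write_matrix_tsv <- function(mat, path) {
  if (is.list(mat) && !is.null(mat$values)) mat <- mat$values
  utils::write.table(format(mat, digits = 17, scientific = TRUE, trim = TRUE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a numeric matrix written by [write_matrix_tsv()]
#' @param path input path.
#' @return numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
}

#' Write a binary network as a plain edge list
#'
#' One `i<TAB>j` pair per line with `i < j`, 1-based ROI ids; an empty graph
#' produces an empty file.
#'
#' @param adjacency an adjacency object (see [sparsity_threshold()]) or a
#'   binary symmetric matrix.
#' @param path output path.
#' @export
write_edgelist <- function(adjacency, path) {
  a <- if (is.list(adjacency)) adjacency$values else adjacency
  idx <- which(upper.tri(a) & a != 0, arr.ind = TRUE)
  lines <- if (nrow(idx)) paste(idx[, 1L], idx[, 2L], sep = "\t") else character()
  writeLines(lines, path)
  invisible(path)
}

#' Read an edge list written by [write_edgelist()]
#' @param path input path.
#' @param n number of nodes of the reconstructed matrix.
#' @return binary symmetric matrix with zero diagonal.
#' @export
read_edgelist <- function(path, n) {
  a <- matrix(0L, n, n)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    ij <- as.integer(strsplit(ln, "\t", fixed = TRUE)[[1L]])
    a[ij[1L], ij[2L]] <- 1L
    a[ij[2L], ij[1L]] <- 1L
  }
  a
}

#' Write a pipeline product as JSON
#'
#' Partitions, hub reports, rich-club curves and comparison reports are
#' serialized as JSON; matrices should use [write_matrix_tsv()] and networks
#' [write_edgelist()].
#'
#' @param report a list-like pipeline product.
#' @param path output path.
#' @export
write_json_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}
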