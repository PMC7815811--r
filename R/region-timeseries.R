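#' Region-by-time BOLD series container
#'
#' Bundles a regions x volumes numeric matrix with its repetition time (TR)
#' and region labels. All connectivity operations in the package consume and
#' return this container.
#'
#' @param values Numeric matrix, regions in rows, volumes (time points) in
#'   columns. Arbitrary BOLD-like units.
#' @param tr Repetition time in seconds (sampling interval between volumes).
#' @param region_labels Character vector of unique region identifiers, one per
#'   row of \code{values}. Defaults to \code{R1, R2, ...}.
#' @param subject_id Optional subject identifier.
#' @return An object of class \code{region_ts}.
#' @export
region_ts <- function(values, tr, region_labels = NULL, subject_id = NA_character_) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("'values' must be a numeric matrix")
  if (anyNA(values)) stop("region time series must not contain missing values")
  if (ncol(values) < 1L) stop("at least one volume is required")
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0) stop("'tr' must be a positive scalar (seconds)")
  if (is.null(region_labels)) region_labels <- paste0("R", seq_len(nrow(values)))
  region_labels <- as.character(region_labels)
  if (length(region_labels) != nrow(values)) stop("one label per region is required")
  if (anyDuplicated(region_labels)) stop("region labels must be unique")
  rownames(values) <- region_labels
  structure(
    list(values = values, tr = tr, region_labels = region_labels,
         subject_id = subject_id),
    class = "region_ts"
  )
}

#' @export
print.region_ts <- function(x, ...) {
  cat(sprintf("<region_ts> %d regions x %d volumes, TR = %g s, subject = %s\n",
              nrow(x$values), ncol(x$values), x$tr, x$subject_id))
  invisible(x)
}

#' Number of volumes in a region time series
#' @param ts A \code{region_ts} object.
#' @return Integer volume count.
#' @export
n_volumes <- function(ts) ncol(ts$values)

#' Write / read region time series as TSV
#'
#' Volumes are rows and regions are columns; the header row carries the
#' region labels. TR is stored as a commented first line so a round trip
#' preserves it.
#'
#' @param ts A \code{region_ts}.
#' @param path Output file path.
#' @export
write_region_ts <- function(ts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# tr_seconds=%.10g subject_id=%s", ts$tr, ts$subject_id), con)
  utils::write.table(t(ts$values), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_region_ts
#' @param path Input file path.
#' @return \code{read_region_ts} returns a \code{region_ts}.
#' @export
read_region_ts <- function(path) {
  first <- readLines(path, n = 1L)
  tr <- 1
  subject_id <- NA_character_
  if (startsWith(first, "#")) {
    m <- regmatches(first, regexec("tr_seconds=([0-9.eE+-]+)", first))[[1]]
    if (length(m) == 2L) tr <- as.numeric(m[2])
    m <- regmatches(first, regexec("subject_id=(\\S+)", first))[[1]]
    if (length(m) == 2L) subject_id <- m[2]
  }
  dat <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  region_ts(t(as.matrix(dat)), tr = tr, region_labels = colnames(dat),
            subject_id = subject_id)
}
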