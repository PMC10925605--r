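#' Parcellated BOLD time series
#'
#' Container for a single run of parcellated fMRI: a timepoints-by-regions
#' matrix of BOLD amplitude together with the repetition time and run
#' metadata. All marker computations in the package start from this object.
#'
#' @param data Numeric matrix, timepoints (rows) by regions (columns). All
#'   values must be finite; at least 2 timepoints and 2 regions.
#' @param tr Repetition time in seconds (positive scalar).
#' @param region_labels Character vector of region names, one per column of
#'   `data`. Defaults to the column names of `data`, or `"R1"..."RN"`.
#' @param meta Named list of run metadata (dataset, animal, condition, run).
#'   Free-form; carried through preprocessing unchanged.
#'
#' @return An object of class `parcellated_ts` with elements `data`, `tr`,
#'   `region_labels`, `meta`.
#' @examples
#' ts <- parcellated_ts(matrix(rnorm(200), 50, 4), tr = 1.25)
#' dim(ts$data)
#' @export
parcellated_ts <- function(data, tr, region_labels = NULL, meta = list()) {
  data <- as.matrix(data)
  if (!is.numeric(data) || nrow(data) < 2L || ncol(data) < 2L)
    stop("`data` must be a numeric matrix with >= 2 timepoints and >= 2 regions")
  if (!all(is.finite(data)))
    stop("`data` contains non-finite values")
  if (!is.numeric(tr) || length(tr) != 1L || !is.finite(tr) || tr <= 0)
    stop("`tr` must be a positive scalar (seconds)")
  if (is.null(region_labels)) {
    region_labels <- colnames(data)
    if (is.null(region_labels)) region_labels <- paste0("R", seq_len(ncol(data)))
  }
  region_labels <- as.character(region_labels)
  if (length(region_labels) != ncol(data))
    stop("`region_labels` length (", length(region_labels),
         ") does not match number of regions (", ncol(data), ")")
  colnames(data) <- region_labels
  structure(
    list(data = data, tr = as.numeric(tr), region_labels = region_labels,
         meta = meta),
    class = "parcellated_ts"
  )
}

#' @export
print.parcellated_ts <- function(x, ...) {
  cat("Parcellated time series:", nrow(x$data), "timepoints x",
      ncol(x$data), "regions, TR =", x$tr, "s\n")
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, as.character)),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Read / write a parcellated time-series run
#'
#' A run is stored as a TSV matrix (rows = timepoints, header row = region
#' labels) with a JSON sidecar holding `tr_s` and the run metadata
#' (`dataset`, `animal`, `condition`, `run`, and optionally `seed`).
#'
#' @param path Path to the `.tsv` file; the sidecar is the same path with the
#'   extension replaced by `.json`.
#' @return `read_timeseries()` returns a [parcellated_ts()].
#' @export
read_timeseries <- function(path) {
  sidecar <- sidecar_path(path)
  if (!file.exists(sidecar))
    stop("missing JSON sidecar for run: ", sidecar)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(side$tr_s))
    stop("sidecar ", sidecar, " lacks required field `tr_s`")
  meta <- side[setdiff(names(side), "tr_s")]
  parcellated_ts(as.matrix(tab), tr = side$tr_s,
                 region_labels = colnames(tab), meta = meta)
}

#' @rdname read_timeseries
#' @param ts A [parcellated_ts()].
#' @param digits Significant digits used when serialising the matrix.
#' @return `write_timeseries()` returns `path`, invisibly.
#' @export
write_timeseries <- function(ts, path, digits = 8) {
  stopifnot(inherits(ts, "parcellated_ts"))
  df <- as.data.frame(signif(ts$data, digits))
  names(df) <- ts$region_labels
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- c(list(tr_s = ts$tr), ts$meta)
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.[^.]+$", ".json", path)
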