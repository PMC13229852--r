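#' Binary spike raster
#'
#' The universal input signal: a `T x n` binary matrix, one row per
#' timestep and one column per input channel, plus the timestep duration.
#'
#' @param spikes numeric/logical matrix of 0s and 1s, `T` rows (time) by
#'   `n` columns (channels).
#' @param dt timestep duration in milliseconds.
#' @param label optional 1-based class id attached to the raster.
#' @return An object of class `spike_raster`.
#' @examples
#' r <- spike_raster(matrix(c(0, 1, 0, 0, 0, 1), nrow = 3), dt = 10)
#' n_steps(r); n_channels(r)
#' @export
spike_raster <- function(spikes, dt = 10, label = NULL) {
  spikes <- as.matrix(spikes)
  storage.mode(spikes) <- "double"
  if (!all(spikes %in% c(0, 1)))
    stop("`spikes` must be strictly binary (0/1)")
  structure(list(spikes = spikes, dt = dt, label = label),
            class = "spike_raster")
}

#' @rdname spike_raster
#' @param x a `spike_raster`.
#' @export
n_steps <- function(x) nrow(x$spikes)

#' @rdname spike_raster
#' @export
n_channels <- function(x) ncol(x$spikes)

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("spike_raster: %d steps x %d channels, dt=%g ms, %d spikes%s\n",
              n_steps(x), n_channels(x), x$dt, sum(x$spikes),
              if (is.null(x$label)) "" else sprintf(", label=%d", x$label)))
  invisible(x)
}

#' Write / read a spike raster as a compressed text archive
#'
#' The on-disk format is a gzipped TSV: two header lines (`#dt` and
#' `#label`) followed by the binary matrix, so rasters remain inspectable
#' with standard tools.
#'
#' @param raster a [spike_raster()].
#' @param path file path (conventionally `.tsv.gz`).
#' @export
write_raster <- function(raster, path) {
  con <- gzfile(path, "wt")
  on.exit(close(con))
  writeLines(c(sprintf("#dt\t%.10g", raster$dt),
               sprintf("#label\t%d", raster$label %||% NA_integer_)), con)
  utils::write.table(raster$spikes, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  hdr <- readLines(con, n = 2L)
  dt <- as.numeric(strsplit(hdr[1L], "\t")[[1L]][2L])
  label <- suppressWarnings(as.integer(strsplit(hdr[2L], "\t")[[1L]][2L]))
  m <- as.matrix(utils::read.table(con, sep = "\t"))
  dimnames(m) <- NULL
  spike_raster(m, dt = dt, label = if (is.na(label)) NULL else label)
}
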