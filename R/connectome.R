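#' Fisher-z connectivity matrix from parcellated time series
#'
#' Computes pairwise Pearson correlations between all parcel time series
#' (runs concatenated beforehand, see [concatenateRuns()]) and expresses them
#' as Fisher z-transformed scores, `z = atanh(r)`.  Correlations are clipped
#' to `1 - 1e-7` in magnitude so that perfectly correlated series yield a
#' large finite z rather than infinity; the diagonal is set to zero.
#'
#' @param series numeric matrix, parcels x timepoints; rownames are taken as
#'   parcel ids (generated if absent).
#' @param task,wave labels stored on the result.
#' @return a [ConnectivityMatrix-class] (pre-threshold: entries may be
#'   negative until [zeroNegative()] is applied).
#' @examples
#' ts <- matrix(rnorm(5 * 40), 5, 40)
#' cm <- correlationMatrix(ts, task = "MID", wave = "w1")
#' @export
correlationMatrix <- function(series, task = "task", wave = "wave") {
  series <- as.matrix(series)
  if (ncol(series) < 10)
    stop("at least 10 timepoints required for stable correlations")
  if (any(is.na(series))) stop("NA values in time series")
  sds <- apply(series, 1, sd)
  if (any(sds < .Machine$double.eps)) {
    bad <- rownames(series)[sds < .Machine$double.eps]
    if (is.null(bad)) bad <- which(sds < .Machine$double.eps)
    stop("constant time series for parcel(s): ",
         paste(bad, collapse = ", "))
  }
  ids <- rownames(series)
  if (is.null(ids)) ids <- sprintf("p%03d", seq_len(nrow(series)))
  r <- cor(t(series))
  clip <- 1 - 1e-7
  r[r > clip] <- clip
  r[r < -clip] <- -clip
  z <- atanh(r)
  diag(z) <- 0
  z <- (z + t(z)) / 2   # remove floating asymmetry
  dimnames(z) <- list(ids, ids)
  new("ConnectivityMatrix", values = z, task = task, wave = wave,
      parcel_ids = ids, n_zeroed = NA_real_)
}

#' Zero out negative Fisher-z edges
#'
#' Only positive Fisher z-scores enter the network-level analyses; negative
#' scores are set to zero.  The number of zeroed entries is recorded on the
#' returned object.
#'
#' @param matrix a [ConnectivityMatrix-class].
#' @return the thresholded [ConnectivityMatrix-class] with `n_zeroed` set.
#' @export
zeroNegative <- function(matrix) {
  stopifnot(is(matrix, "ConnectivityMatrix"))
  v <- matrix@values
  n_neg <- sum(v < 0)
  v[v < 0] <- 0
  matrix@values <- v
  matrix@n_zeroed <- n_neg
  matrix
}

#' Concatenate task runs along time
#'
#' All available data from each task are used: runs are joined along the time
#' axis in run-index order before correlation.
#'
#' @param runs list of parcels x timepoints matrices with identical row order.
#' @return one parcels x (sum of timepoints) matrix.
#' @export
concatenateRuns <- function(runs) {
  stopifnot(length(runs) >= 1)
  np <- unique(vapply(runs, nrow, 0L))
  if (length(np) != 1) stop("runs must share the parcel dimension")
  do.call(cbind, runs)
}

#' Write / read a connectivity matrix as TSV
#'
#' The dialect is a square numeric table with parcel ids as header and first
#' column.
#'
#' @param x a [ConnectivityMatrix-class].
#' @param path file path.
#' @return `writeConnectivity` returns `path` invisibly; `readConnectivity`
#'   returns a [ConnectivityMatrix-class].
#' @param task,wave labels for the re-read object.
#' @export
writeConnectivity <- function(x, path) {
  stopifnot(is(x, "ConnectivityMatrix"))
  df <- data.frame(parcel_id = x@parcel_ids, x@values, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeConnectivity
#' @export
readConnectivity <- function(path, task = "task", wave = "wave") {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  ids <- as.character(df[[1]])
  v <- as.matrix(df[, -1, drop = FALSE])
  dimnames(v) <- list(ids, ids)
  v <- (v + t(v)) / 2
  diag(v) <- 0
  new("ConnectivityMatrix", values = v, task = task, wave = wave,
      parcel_ids = ids, n_zeroed = NA_real_)
}
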