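# Plain-text interchange: TSV for raw records, JSON for derived results.

#' Read a bead trajectory from TSV
#'
#' Expects a header line with columns \code{time_s}, \code{x_nm},
#' \code{y_nm}.
#'
#' @param path file path
#' @param sampling_rate Hz; if NULL, inferred from the time stamps
#' @return a \code{\link{bead_trajectory}}
#' @export
read_trajectory_tsv <- function(path, sampling_rate = NULL) {
  d <- read.delim(path, sep = "\t", check.names = FALSE)
  need <- c("time_s", "x_nm", "y_nm")
  if (!all(need %in% names(d))) {
    stop(sprintf("trajectory TSV needs columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  if (is.null(sampling_rate)) {
    sampling_rate <- 1 / stats::median(diff(d$time_s))
  }
  bead_trajectory(d$time_s, d$x_nm, d$y_nm, sampling_rate)
}

#' Write a bead trajectory as TSV
#' @param traj a \code{\link{bead_trajectory}}
#' @param path file path
#' @export
write_trajectory_tsv <- function(traj, path) {
  stopifnot(inherits(traj, "bead_trajectory"))
  d <- data.frame(time_s = traj$time, x_nm = traj$x, y_nm = traj$y)
  write.table(format(d, digits = 10, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a force-distance curve from TSV
#'
#' Expects a header with columns \code{extension_um}, \code{force_pN},
#' \code{direction} ("extension"/"retraction", constant per file).
#'
#' @param path file path
#' @return an \code{\link{fd_curve}}
#' @export
read_fd_tsv <- function(path) {
  d <- read.delim(path, sep = "\t", check.names = FALSE)
  need <- c("extension_um", "force_pN", "direction")
  if (!all(need %in% names(d))) {
    stop(sprintf("FD TSV needs columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  dir <- unique(d$direction)
  if (length(dir) != 1L) {
    stop("FD TSV must contain a single direction", call. = FALSE)
  }
  fd_curve(d$extension_um, d$force_pN, dir)
}

#' Write a force-distance curve as TSV
#' @param curve an \code{\link{fd_curve}}
#' @param path file path
#' @export
write_fd_tsv <- function(curve, path) {
  stopifnot(inherits(curve, "fd_curve"))
  d <- data.frame(extension_um = curve$extension, force_pN = curve$force,
                  direction = curve$direction)
  write.table(format(d, digits = 10, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an RMS concentration sweep as TSV
#' @param sweep a \code{\link{rms_concentration_curve}} result
#' @param path file path
#' @export
write_rms_curve_tsv <- function(sweep, path) {
  write.table(format(as.data.frame(sweep), digits = 8, trim = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# deterministic JSON writer for result payloads
.write_result_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}
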