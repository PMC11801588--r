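#' Read a subgroup matrix from CSV
#'
#' Parses a comma-separated file with one subgroup per row (positive
#' decimals, '.' decimal mark). A single header line is auto-detected and
#' skipped. Ragged rows, non-numeric cells and nonpositive values are
#' rejected with a diagnostic naming the offending row and column.
#'
#' @param path path to the CSV file.
#' @return numeric matrix, one row per subgroup.
#' @export
read_subgroups <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty subgroup file: ", path, call. = FALSE)
  first <- strsplit(lines[1], ",")[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(trimws(first)))))
  if (has_header) {
    lines <- lines[-1]
    if (!length(lines)) stop("subgroup file has a header but no data: ", path,
                             call. = FALSE)
  }
  rows <- strsplit(lines, ",")
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1L)
    stop(sprintf("ragged rows: row %d has %d fields, row 1 has %d",
                 which(ncols != ncols[1])[1], ncols[ncols != ncols[1]][1],
                 ncols[1]), call. = FALSE)
  mat <- matrix(NA_real_, nrow = length(rows), ncol = ncols[1])
  for (i in seq_along(rows)) {
    vals <- suppressWarnings(as.numeric(trimws(rows[[i]])))
    if (anyNA(vals))
      stop(sprintf("non-numeric value at row %d, column %d",
                   i + has_header, which(is.na(vals))[1]), call. = FALSE)
    if (any(vals <= 0))
      stop(sprintf("nonpositive value %g at row %d, column %d",
                   vals[vals <= 0][1], i + has_header,
                   which(vals <= 0)[1]), call. = FALSE)
    mat[i, ] <- vals
  }
  mat
}

# write a file atomically: write to a sibling temp file, then rename
write_atomic <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp))
  writer(tmp)
  if (!file.rename(tmp, path))
    stop("could not move temporary file onto ", path, call. = FALSE)
  invisible(path)
}

#' Write a subgroup matrix to CSV
#'
#' One subgroup per row, comma-separated, no header, full precision
#' (round-trips exactly through \code{\link{read_subgroups}}). The write
#' is atomic: content goes to a temporary file first, which is renamed
#' onto \code{path}, so an interrupted run never leaves a truncated file.
#'
#' @param subgroups numeric matrix of positive values, one row per subgroup.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_subgroups <- function(subgroups, path) {
  subgroups <- check_subgroups(subgroups)
  write_atomic(function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    writeLines(apply(subgroups, 1, function(r)
      paste(format(r, digits = 17, trim = TRUE, scientific = FALSE),
            collapse = ",")), con)
  }, path)
}

#' Simulate subgroups from the Lindley-Geometric distribution
#'
#' Draws \code{m} subgroups of size \code{n} from LG(theta, p) by inverse
#' transform and returns them as a subgroup matrix. With \code{path} set,
#' the matrix is also written as a subgroup CSV -- a reproducible synthetic
#' stand-in for an in-control process stream.
#'
#' @param m number of subgroups; \code{n} subgroup size.
#' @param theta,p LG parameters.
#' @param seed optional integer seed.
#' @param path optional output CSV path.
#' @return numeric m-by-n matrix (invisibly if written to file).
#' @examples
#' sg <- lg_simulate_subgroups(25, 5, theta = 0.25, p = 0.25, seed = 1)
#' dim(sg)
#' @export
lg_simulate_subgroups <- function(m, n, theta, p, seed = NULL, path = NULL) {
  check_lg_params(theta, p)
  stopifnot(m >= 1, n >= 1)
  if (!is.null(seed)) set.seed(seed)
  sg <- matrix(rlgeo(m * n, theta, p), nrow = m, ncol = n)
  if (!is.null(path)) {
    write_subgroups(sg, path)
    return(invisible(sg))
  }
  sg
}

#' Serialize control limits to / from JSON
#'
#' \code{write_limits} stores an \code{\link{lg_limits}} object as a small
#' JSON document (u, alpha, lcl, ucl and, when available, B, n, m and the
#' phase-I parameter estimates); \code{read_limits} restores it. Writing
#' is atomic.
#'
#' @param limits an \code{\link{lg_limits}} object.
#' @param path JSON file path.
#' @return \code{write_limits} returns \code{path} invisibly;
#'   \code{read_limits} returns an \code{lg_limits} object.
#' @export
write_limits <- function(limits, path) {
  stopifnot(inherits(limits, "lg_limits"))
  keep <- c("u", "alpha", "lcl", "ucl", "B", "n", "m", "theta_hat", "p_hat")
  payload <- limits[intersect(keep, names(limits))]
  payload <- payload[!vapply(payload, is.null, logical(1))]
  write_atomic(function(tmp)
    jsonlite::write_json(payload, tmp, auto_unbox = TRUE, digits = NA), path)
}

#' @rdname write_limits
#' @export
read_limits <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lim <- lg_limits(obj$lcl, obj$ucl, u = obj$u, alpha = obj$alpha)
  for (f in c("B", "n", "m", "theta_hat", "p_hat"))
    if (!is.null(obj[[f]])) lim[[f]] <- obj[[f]]
  lim
}

#' Packaged example datasets
#'
#' \code{lg_survival_data()} returns the phase-I reference data: survival
#' times (in years) of 45 gastric-cancer patients, randomized into 9
#' subgroups of size 5. \code{lg_phase2_data()} returns the matching
#' phase-II stream: 30 further survival-time values in 6 subgroups of 5,
#' drawn from a population whose LG parameters differ from the phase-I
#' fit, so a percentile chart built on the phase-I data should eventually
#' signal on them.
#'
#' @return numeric subgroup matrix (9 x 5 and 6 x 5 respectively).
#' @examples
#' fit_lg(as.numeric(lg_survival_data()))
#' @export
lg_survival_data <- function() {
  read_subgroups(system.file("extdata", "gastric_survival_subgroups.csv",
                             package = "lgchart", mustWork = TRUE))
}

#' @rdname lg_survival_data
#' @export
lg_phase2_data <- function() {
  read_subgroups(system.file("extdata", "phase2_subgroups.csv",
                             package = "lgchart", mustWork = TRUE))
}
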