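#' Write an event table as BIDS-style TSV
#'
#' Columns: onset, duration, trial_type, gender, run, task.
#'
#' @param x An `fd_design` or an event data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(x, path) {
  trials <- if (inherits(x, "fd_design")) x$trials else x
  utils::write.table(trials, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a BIDS-style events TSV
#' @param path File path.
#' @return Event data frame.
#' @export
read_event_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write a BOLD run as a plain matrix file with a JSON sidecar
#'
#' The matrix (voxels x volumes) goes to a TSV; TR and run id go to
#' `<path>.json`.
#'
#' @param run An `fd_bold`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_bold_matrix <- function(run, path) {
  utils::write.table(run$data, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(tr = run$tr, run_id = run$run_id),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a BOLD run written by [write_bold_matrix()]
#' @param path TSV path (sidecar `<path>.json` must exist).
#' @return An `fd_bold`.
#' @export
read_bold_matrix <- function(path) {
  data <- as.matrix(utils::read.table(path, header = FALSE, sep = "\t"))
  dimnames(data) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  bold_run(data, tr = meta$tr, run_id = meta$run_id)
}

#' Write a BOLD run as a NIfTI-1 4D volume
#'
#' Serializes the voxel axis along x (y = z = 1) with the TR in the time
#' dimension.  Requires the RNifti package.
#'
#' @param run An `fd_bold`.
#' @param path Output `.nii` path.
#' @return `path`, invisibly.
#' @export
write_bold_nifti <- function(run, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("the RNifti package is required for NIfTI serialization")
  arr <- array(0, dim = c(nrow(run$data), 1, 1, ncol(run$data)))
  arr[, 1, 1, ] <- run$data
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(1, 1, 1, run$tr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 4D volume as a BOLD run
#'
#' Flattens x, y, z to the voxel axis.
#'
#' @param path `.nii` path.
#' @param run_id Run label for the result.
#' @return An `fd_bold`.
#' @export
read_bold_nifti <- function(path, run_id = 1L) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("the RNifti package is required for NIfTI serialization")
  img <- RNifti::readNifti(path)
  d <- dim(img)
  data <- matrix(as.numeric(img), prod(d[1:3]), d[4])
  tr <- RNifti::pixdim(img)[4]
  bold_run(data, tr = if (is.finite(tr) && tr > 0) tr else 1,
           run_id = run_id)
}

#' Serialize a patch of interest as JSON
#' @param x An `fd_poi`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_poi <- function(x, path) {
  jsonlite::write_json(list(name = x$name, indices = x$voxels,
                            threshold = x$threshold,
                            contrast = x$contrast),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a patch of interest from JSON
#' @param path JSON path.
#' @return An `fd_poi`.
#' @export
read_poi <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  poi(j$name, j$indices, j$threshold %||% NA_real_, j$contrast %||% "")
}

#' Write a phase map as TSV
#' @param x An `fd_phasemap`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phase_map <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
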