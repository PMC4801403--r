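# Plain-CSV readers/writers for the pipeline's interchange schemas.
# All files are UTF-8 with a header row; times in seconds from scenario
# start, planar coordinates in km, durations in minutes.

#' Write and read tag records as CSV
#'
#' Columns: \code{t_s}, \code{depth_m}, \code{clicking} (0/1).
#'
#' @param series a \code{\link{generate_tag_series}} result.
#' @param path file path.
#' @return \code{read_tag_csv} returns a \code{"tag_series"} (without a
#'   truth log); \code{write_tag_csv} returns \code{path} invisibly.
#' @export
write_tag_csv <- function(series, path) {
  utils::write.csv(series$samples, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tag_csv
#' @param whale_id label for the animal read from \code{path}.
#' @export
read_tag_csv <- function(path, whale_id = basename(path)) {
  if (!file.exists(path)) stop("tag file not found: ", path)
  structure(list(whale_id = whale_id, samples = utils::read.csv(path),
                 truth = NULL),
            class = "tag_series")
}

#' Write and read phase-duration CSV
#'
#' Long format, columns \code{phase} (\code{"echo"} or \code{"silent"})
#' and \code{duration_min}.
#'
#' @param set a \code{\link{phase_duration_set}}.
#' @param path file path.
#' @export
write_phase_csv <- function(set, path) {
  df <- rbind(data.frame(phase = "echo", duration_min = set$t_e),
              data.frame(phase = "silent", duration_min = set$t_ne))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phase_csv
#' @export
read_phase_csv <- function(path) {
  if (!file.exists(path)) stop("phase file not found: ", path)
  df <- utils::read.csv(path)
  phase_duration_set(df$duration_min[df$phase == "echo"],
                     df$duration_min[df$phase == "silent"])
}

read_required_csv <- function(path, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  utils::read.csv(path)
}
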