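# plain-text serialization of the main artifacts

#' Write a voltage trace as CSV
#'
#' @param trace A `voltage_trace`.
#' @param path Output file. Stimulus times are stored in a `# stim:` header
#'   comment.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  st <- attr(trace, "stim_times")
  if (!is.null(st))
    writeLines(paste0("# stim: ", paste(st, collapse = " ")), con)
  utils::write.csv(as.data.frame(trace[, c("time", "V")]), con,
                   row.names = FALSE)
  invisible(path)
}

#' Read a voltage trace written by [write_trace_csv()]
#'
#' @param path CSV file.
#' @return A `voltage_trace` tibble.
#' @export
read_trace_csv <- function(path) {
  first <- readLines(path, n = 1)
  stim <- NULL
  skip <- 0
  if (startsWith(first, "# stim:")) {
    stim <- as.numeric(strsplit(sub("# stim: *", "", first), " ")[[1]])
    skip <- 1
  }
  d <- utils::read.csv(path, skip = skip)
  out <- as_tibble(d)
  attr(out, "stim_times") <- stim
  class(out) <- c("voltage_trace", class(out))
  out
}

#' Serialize cell parameters to JSON
#'
#' @param params A `cell_params`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_params_json <- function(params, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    abort("jsonlite is required for JSON export")
  jsonlite::write_json(list(g = as.list(params$g), scale = as.list(params$scale),
                            remodeling = params$remodeling),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read cell parameters from JSON
#'
#' @param path JSON file from [write_params_json()].
#' @return A `cell_params`.
#' @export
read_params_json <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    abort("jsonlite is required for JSON import")
  d <- jsonlite::read_json(path)
  out <- structure(list(g = unlist(d$g), scale = unlist(d$scale),
                        remodeling = d$remodeling), class = "cell_params")
  out
}

#' Write biomarker ranges as CSV
#'
#' @param ranges A `biomarker_ranges` tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ranges_csv <- function(ranges, path) {
  utils::write.csv(as.data.frame(ranges), path, row.names = FALSE)
  invisible(path)
}

#' Read biomarker ranges from CSV
#'
#' @param path CSV with columns `biomarker`, `center`, `min`, `max`.
#' @return A `biomarker_ranges` tibble.
#' @export
read_ranges_csv <- function(path) {
  d <- as_tibble(utils::read.csv(path))
  if (!all(c("biomarker", "min", "max") %in% names(d)))
    abort("ranges file needs columns biomarker, min, max")
  class(d) <- c("biomarker_ranges", class(d))
  d
}
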