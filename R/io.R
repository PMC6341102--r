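#' Read a HapMap-format genetic map
#'
#' Three whitespace-separated columns: physical position (bp), local
#' recombination rate (cM/Mb) and cumulative map position (cM), with a
#' header line.
#'
#' @param path file path.
#' @return A data frame with columns `pos`, `rate_cM_Mb`, `cM`.
#' @export
read_genetic_map <- function(path) {
  m <- utils::read.table(path, header = TRUE)
  if (ncol(m) < 3) stop("expected 3 columns: pos, rate (cM/Mb), cM")
  names(m)[1:3] <- c("pos", "rate_cM_Mb", "cM")
  if (is.unsorted(m$pos)) stop("map positions must be sorted")
  m
}

#' Interpolate genetic positions from a map
#'
#' Linear interpolation of cumulative cM at arbitrary physical positions;
#' positions outside the map are extrapolated with the nearest interval's
#' rate.
#'
#' @param positions physical positions (bp).
#' @param map data frame from [read_genetic_map].
#' @return Numeric vector of cM positions.
#' @export
interpolate_cM <- function(positions, map) {
  stats::approx(map$pos, map$cM, xout = positions, rule = 2)$y
}

#' Write a population-environment table
#'
#' Tab-separated with the column layout [generate_pop_env_table] produces
#' (population, lat, lon, n_alleles, solar_kwh_m2_day, derived_freq,
#' region).
#'
#' @param tab data frame.
#' @param path output path.
#' @export
write_pop_env_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a population-environment table written by [write_pop_env_tsv]
#' @param path file path.
#' @return A data frame.
#' @export
read_pop_env_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Read an iris pixel CSV
#'
#' Rows of `r,g,b` values (header optional); optional `white_ref` /
#' `pupil_ref` arguments override the defaults.
#'
#' @param path file path.
#' @param white_ref,pupil_ref reference triples (defaults: pure white /
#'   black).
#' @return A [pixel_set].
#' @export
read_pixel_csv <- function(path, white_ref = c(255, 255, 255),
                           pupil_ref = c(0, 0, 0)) {
  first <- readLines(path, n = 1)
  header <- grepl("[A-Za-z]", first)
  px <- utils::read.csv(path, header = header)
  pixel_set(as.matrix(px[, 1:3]), white_ref, pupil_ref)
}
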