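# Packaged summary-table fixtures: read-only transcriptions of the study's
# printed mean/SD/n tables (text and table numbers only, nothing read off
# figures), each carrying a `source` annotation column. Checksummed so that
# a tampered fixture fails loudly at load time.

.FIXTURE_MD5 <- c(
  capillary_density = "396528fc2ed38b15e6ebe8ec946de960",
  ce_velocity = "8c591cb79fd1e823e53c754661866aef",
  fluorescence = "bf4a9d0221b8586178b5c56c5902b0d4",
  prussian_blue = "cbbedf8f7d81487c9241ae32e8460e7e",
  relative_signal_intensity = "015109e020204fe10ba6b45c2e359ecd")

#' List the packaged fixture tables
#'
#' @return Character vector of fixture names usable with [mc_fixture()].
#' @export
mc_fixtures <- function() names(.FIXTURE_MD5)

#' Load a packaged fixture table
#'
#' Reads one of the packaged summary tables (capture efficiency versus
#' velocity, fluorescence photon counts, Prussian-blue cell counts, relative
#' MRI signal intensities, capillary densities), verifying its checksum
#' first.
#'
#' @param name One of [mc_fixtures()].
#' @return A data frame.
#' @examples
#' mc_fixture("ce_velocity")
#' @export
mc_fixture <- function(name) {
  name <- match.arg(name, mc_fixtures())
  path <- system.file("extdata", paste0(name, ".csv"),
                      package = "magnetocapture", mustWork = TRUE)
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, unname(.FIXTURE_MD5[[name]])))
    stop(sprintf("fixture '%s' failed its checksum (%s): file corrupted or tampered",
                 name, sum))
  read.csv(path, stringsAsFactors = FALSE)
}
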