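# Human- and machine-readable reports.

formatRanges <- function(result) {
  r <- result@ranges
  if (nrow(r) == 0L)
    return("(empty)")
  parts <- sprintf("%s:%d%s..%d%s", r$chain, r$start, trimws(r$startIns),
                   r$end, trimws(r$endIns))
  sprintf("%s (%d residues, RMSD %.2f Å)", paste(parts, collapse = ", "),
          result@nResidues, result@rmsd)
}

#' Format a run report
#'
#' \code{format = "text"} lists, per domain, the inclusive residue ranges,
#' the number of residues therein and the backbone RMSD to the mean
#' coordinates, plus sequence coverage (one decimal percent) and the
#' parameters used.  \code{format = "json"} produces a schema-stable
#' structured report that parses back to equal values.
#'
#' @param report a [RunReport-class].
#' @param format \code{"text"} or \code{"json"}.
#' @return character vector of lines (text) or a JSON string (json).
#' @examples
#' spec <- bundleSpec(regions = data.frame(n = 16, kind = "rigid", sigma = 0.1),
#'                    nConf = 5, seed = 2)
#' cat(formatReport(findResidueRanges(makeBundle(spec))), sep = "\n")
#' @export
formatReport <- function(report, format = c("text", "json")) {
  format <- match.arg(format)
  p <- report@params
  if (format == "text") {
    lines <- c(sprintf("status: %s", report@status))
    if (report@status != "ok" || length(report@domains) == 0L) {
      lines <- c(lines, sprintf("%s", report@status))
    } else {
      for (i in seq_along(report@domains))
        lines <- c(lines, sprintf("domain %d: %s", i,
                                  formatRanges(report@domains[[i]])))
      lines <- c(lines,
        sprintf("domains: %d, selected residues: %d, intra-domain gaps: %d",
                length(report@domains),
                sum(vapply(report@domains, nResidues, integer(1))),
                sum(vapply(report@domains, function(d) d@nGaps, integer(1)))),
        sprintf("sequence coverage: %.1f%%", 100 * report@coverage))
    }
    lines <- c(lines, sprintf(
      "parameters: mu=%d m=%d gamma=%g delta=%g deltaAbs=%g g=%d torsionMode=%s",
      p@mu, p@m, p@gamma, p@delta, p@deltaAbs, p@g, p@torsionMode))
    if (length(report@warnings))
      lines <- c(lines, paste("warning:", report@warnings))
    return(lines)
  }
  obj <- list(
    status = report@status,
    nResidues = report@nResidues,
    coverage = report@coverage,
    nDomains = length(report@domains),
    domains = lapply(report@domains, function(d) list(
      ranges = d@ranges[, c("chain", "start", "end")],
      nResidues = d@nResidues,
      nGaps = d@nGaps,
      rmsd = d@rmsd)),
    parameters = list(mu = p@mu, m = p@m, gamma = p@gamma, delta = p@delta,
                      deltaAbs = p@deltaAbs, g = p@g,
                      torsionMode = p@torsionMode,
                      varianceNorm = p@varianceNorm),
    warnings = report@warnings)
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
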