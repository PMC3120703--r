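# Gap-penalized iterative residue removal: refines an extended domain to its
# final residue ranges.

# gap-opening status per selected residue: removal of a range endpoint (or a
# singleton) opens no new gap; removal of an interior residue does.  Chain
# termini are range endpoints.
gapOpening <- function(selected, neighbors) {
  out <- setNames(logical(length(selected)), selected)
  for (run in residueRuns(selected, neighbors)) {
    if (length(run) > 2L)
      out[as.character(run[-c(1L, length(run))])] <- TRUE
  }
  out
}

#' Remove isolated residues (step 2)
#'
#' Drops every selected residue whose two sequence neighbours are both outside
#' the current selection.  A missing neighbour (chain terminus or numbering
#' break) counts as unselected, so a lone terminal residue is removed.
#'
#' @param selected integer vector of selected residue indices.
#' @param neighbors neighbour structure of the bundle (internal; from the
#'   bundle via [refineDomain()]).
#' @return the selection without isolated residues.
#' @keywords internal
removeIsolated <- function(selected, neighbors) {
  keep <- vapply(selected, function(r) {
    p <- neighbors$prev[r]; n <- neighbors$nxt[r]
    (!is.na(p) && p %in% selected) || (!is.na(n) && n %in% selected)
  }, logical(1))
  selected[keep]
}

#' Removal acceptance test (step 5)
#'
#' A removal with gap-weighted RMSD decrease \code{deltaR} is accepted iff
#' \code{deltaR >= deltaAbs * n/N} and
#' \code{deltaR/r >= (delta + 3.0/M) * n/N}, where \code{n} and \code{N} are
#' the numbers of atoms contributed to the RMSD fit by the candidate residue
#' and by all selected residues, and \code{M} is the number of selected
#' residues.  The relative threshold's inflation at small \code{M} guarantees
#' termination.  \code{r = 0} rejects (nothing can be improved).
#'
#' @param deltaR gap-weighted RMSD decrease (Angstroem).
#' @param r current ensemble RMSD (Angstroem).
#' @param nResAtoms atoms of the candidate residue in the fit (backbone: 3).
#' @param nSelAtoms atoms of the whole selection in the fit.
#' @param M number of selected residues.
#' @param delta,deltaAbs threshold parameters (see [rangeParams()]).
#' @return logical.
#' @export
removalDecision <- function(deltaR, r, nResAtoms, nSelAtoms, M,
                            delta = 1.2, deltaAbs = 1.6) {
  if (!is.finite(deltaR) || r <= 0)
    return(FALSE)
  frac <- nResAtoms / nSelAtoms
  deltaR >= deltaAbs * frac && deltaR / r >= (delta + 3.0 / M) * frac
}

#' Fill small gaps (step 7)
#'
#' Every maximal run of unselected residues strictly shorter than \code{g}
#' residues lying between two selected residues of the same chain is added to
#' the selection.  Gaps spanning a chain break and gaps containing residues
#' with incomplete backbone (which can never be selected) are not filled.
#' Applied once after convergence; does not re-enter the removal loop.
#'
#' @param selected integer vector of selected residue indices.
#' @param g minimal gap width; gaps of width < g are filled.
#' @param neighbors neighbour structure (internal).
#' @param selectable logical per residue: may be selected (complete backbone).
#' @return the augmented selection.
#' @keywords internal
fillGaps <- function(selected, g, neighbors, selectable) {
  runs <- residueRuns(selected, neighbors)
  if (length(runs) < 2L)
    return(selected)
  add <- integer()
  for (i in seq_len(length(runs) - 1L)) {
    from <- runs[[i]][length(runs[[i]])]
    to <- runs[[i + 1L]][1]
    # walk the chain from 'from' towards 'to'; stop at chain breaks
    gap <- integer()
    r <- neighbors$nxt[from]
    ok <- FALSE
    while (!is.na(r)) {
      if (r == to) { ok <- TRUE; break }
      gap <- c(gap, r)
      r <- neighbors$nxt[r]
    }
    if (ok && length(gap) > 0L && length(gap) < g && all(selectable[gap]))
      add <- c(add, gap)
  }
  sort(c(selected, add))
}

# ranges (data.frame) and gap count from a selection
selectionRanges <- function(bundle, selected, neighbors) {
  runs <- residueRuns(selected, neighbors)
  rs <- bundle@residues
  ranges <- do.call(rbind, lapply(runs, function(run) {
    data.frame(chain = rs$chain[run[1]], start = rs$resno[run[1]],
               end = rs$resno[run[length(run)]], startIns = rs$ins[run[1]],
               endIns = rs$ins[run[length(run)]], n = length(run),
               stringsAsFactors = FALSE)
  }))
  if (is.null(ranges))
    ranges <- data.frame(chain = character(), start = integer(),
                         end = integer(), startIns = character(),
                         endIns = character(), n = integer())
  nGaps <- sum(pmax(0L, as.integer(table(ranges$chain)) - 1L))
  list(ranges = ranges, nGaps = nGaps)
}

#' Refine a domain to its final residue ranges
#'
#' Runs the iterative residue-removal procedure on an extended domain:
#' (1) compute the ensemble backbone RMSD r of the current selection;
#' (2) remove isolated residues; (3) find the largest-displacement residues
#' whose removal does or does not open a new gap; (4) compute the
#' gap-weighted RMSD decreases \code{dr_nogap = r - r_nogap} and
#' \code{dr_gap = gamma * (r - r_gap)}; (5) remove the candidate with the
#' larger decrease if it passes [removalDecision()] (ties prefer the no-gap
#' candidate); (6) if nothing was removed, rescan all selected residues for
#' the largest gap-weighted decrease and retry; (7) after convergence, fill
#' gaps shorter than \code{g} residues once and report the RMSD recomputed on
#' the final selection.
#'
#' @param bundle a [StructureBundle-class].
#' @param domain integer vector of the (extended) domain's residue indices,
#'   or a domain as returned by [extractDomains()].
#' @param params a [RangeParams-class]; see [rangeParams()].
#' @param verbose logical; if TRUE, print one line per removal with the
#'   decrease and the thresholds applied.
#' @return A [RangeResult-class].
#' @examples
#' spec <- bundleSpec(regions = data.frame(n = 20, kind = "rigid", sigma = 0.05),
#'                    nConf = 5, seed = 3)
#' b <- makeBundle(spec)
#' refineDomain(b, seq_len(20), rangeParams())
#' @export
refineDomain <- function(bundle, domain, params = rangeParams(),
                         verbose = FALSE) {
  if (is.list(domain)) domain <- domain$residues
  nb <- residueNeighbors(bundle)
  selectable <- completeBackbone(bundle)
  selected <- sort(domain[selectable[domain]])
  history <- data.frame(iteration = integer(), action = character(),
                        residue = integer(), r = numeric(), deltaR = numeric(),
                        absThreshold = numeric(), relThreshold = numeric())
  note <- function(it, action, res, r, dr = NA_real_, at = NA_real_,
                   rt = NA_real_) {
    history[nrow(history) + 1L, ] <<- list(it, action, res, r, dr, at, rt)
    if (verbose)
      message(sprintf("iter %d: %s residue %s (r=%.4f, dr=%.4f, abs>=%.4f, rel dr/r>=%.4f)",
                      it, action, ifelse(is.na(res), "-", res), r, dr, at, rt))
  }
  rmsdOf <- function(sel) {
    if (length(sel) == 0L) return(NA_real_)
    rmsdToMean(bundle, residues = sel)$rmsd
  }
  maxIter <- length(selected) + 10L
  it <- 0L
  r <- NA_real_
  while (length(selected) > 0L) {
    it <- it + 1L
    if (it > maxIter)
      stop("refinement failed to terminate")  # invariant: never reached
    # (1) RMSD of the current set
    fit <- rmsdToMean(bundle, residues = selected)
    r <- fit$rmsd
    # (2) isolated residues
    pruned <- removeIsolated(selected, nb)
    if (length(pruned) < length(selected)) {
      for (res in setdiff(selected, pruned))
        note(it, "isolated", res, r)
      selected <- pruned
      next
    }
    M <- length(selected)
    nSelAtoms <- length(fit$atoms)
    # (3) largest-displacement candidates
    disp <- meanDisplacements(bundle, selected, fit = fit)
    dispOf <- setNames(as.numeric(disp), names(disp))
    opens <- gapOpening(selected, nb)
    ends <- selected[!opens[as.character(selected)]]
    ints <- selected[opens[as.character(selected)]]
    candNogap <- if (length(ends)) ends[which.max(dispOf[as.character(ends)])] else NA_integer_
    candGap <- if (length(ints)) ints[which.max(dispOf[as.character(ints)])] else NA_integer_
    # (4) gap-weighted decreases
    drNogap <- if (!is.na(candNogap) && M > 1L)
      r - rmsdOf(setdiff(selected, candNogap)) else -Inf
    drGap <- if (!is.na(candGap) && M > 1L)
      params@gamma * (r - rmsdOf(setdiff(selected, candGap))) else -Inf
    # (5) removal: larger decrease, ties prefer the no-gap candidate
    if (drNogap >= drGap) {
      dr <- drNogap; cand <- candNogap
    } else {
      dr <- drGap; cand <- candGap
    }
    nResAtoms <- sum(bundle@atoms$residue[fit$atoms] == cand)
    absT <- params@deltaAbs * nResAtoms / nSelAtoms
    relT <- (params@delta + 3.0 / M) * nResAtoms / nSelAtoms
    if (!is.na(cand) &&
        removalDecision(dr, r, nResAtoms, nSelAtoms, M,
                        params@delta, params@deltaAbs)) {
      note(it, "removed", cand, r, dr, absT, relT)
      selected <- setdiff(selected, cand)
      next
    }
    # (6) retry over all selected residues
    if (M > 1L) {
      drAll <- vapply(selected, function(res) {
        w <- if (opens[as.character(res)]) params@gamma else 1
        w * (r - rmsdOf(setdiff(selected, res)))
      }, numeric(1))
      ord <- order(-drAll, opens[as.character(selected)], selected)
      best <- selected[ord[1]]
      if (removalDecision(drAll[ord[1]], r, 3L, nSelAtoms, M,
                          params@delta, params@deltaAbs)) {
        note(it, "removed (rescan)", best, r, drAll[ord[1]], absT, relT)
        selected <- setdiff(selected, best)
        next
      }
    }
    note(it, "converged", NA_integer_, r)
    break
  }
  # (7) fill small gaps once, then recompute the reported RMSD
  filled <- fillGaps(selected, params@g, nb, selectable)
  if (length(filled) > length(selected))
    note(it, "gap fill", NA_integer_, r)
  selected <- filled
  rFinal <- if (length(selected)) rmsdOf(selected) else NA_real_
  sr <- selectionRanges(bundle, selected, nb)
  new("RangeResult", ranges = sr$ranges, residues = as.integer(selected),
      nResidues = length(selected), nGaps = as.integer(sr$nGaps),
      rmsd = rFinal, history = history)
}
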