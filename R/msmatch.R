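# LC-MS peak-list processing: isotope-envelope detection, charge-state
# deconvolution, alkylation-shift confirmation, mass matching and
# abundance binning.

#' Default matching parameters
#'
#' `mass_tol` is the strict (<) tolerance for calling a predicted mass
#' expressed; `neutral_window` is the deconvoluted-mass range for
#' cyclotide-like substances; `alk_tol` is deliberately wider than
#' `mass_tol` because the alkylation shift compounds the mass errors of
#' two independent observations.
#'
#' @return Named list of parameters.
#' @export
match_params <- function() {
  list(mass_tol = 0.40, neutral_window = c(2700, 3300),
       mz_window = c(1000, 2000), alk_delta = alkylation_delta(6L),
       alk_tol = 0.75, spacing_tol = 0.05, spacing_split = 0.02,
       min_isotope_peaks = 3L,
       si_low = 250, si_high = 1000, rt_bin = 0.2, charges = c(2L, 3L))
}

#' Infer the charge state from the mean isotope-peak spacing
#'
#' Adjacent isotope peaks of a z-charged ion are separated by 1.00336/z.
#' Only doubly and triply charged ions are considered (per the default
#' `charges`); anything else returns `NA`.
#'
#' @param mean_spacing Observed mean spacing in Da.
#' @param params Parameters from [match_params()].
#' @return Integer charge or `NA`.
#' @export
charge_from_spacing <- function(mean_spacing, params = match_params()) {
  stopifnot(mean_spacing > 0)
  z <- round(.ISOTOPE_SPACING / mean_spacing)
  if (!(z %in% params$charges)) return(NA_integer_)
  if (abs(.ISOTOPE_SPACING / z - mean_spacing) > params$spacing_tol)
    return(NA_integer_)
  as.integer(z)
}

#' Detect isotope envelopes in a peak table
#'
#' Peaks outside the m/z acquisition window are dropped.  Within each
#' retention-time bin, grouping is greedy: starting from the most intense
#' unassigned peak, the chain is extended left and right at spacings of
#' 1.00336/z (z = 3 tried before z = 2) within `spacing_tol`; chains with
#' at least `min_isotope_peaks` members are accepted, and each peak
#' belongs to at most one envelope.  The monoisotopic peak is taken as the
#' leftmost accepted peak.
#'
#' @param peaks A `peak_table`.
#' @param params Parameters from [match_params()].
#' @return List of envelopes: each has `rt`, `charge`, `mono_mz`,
#'   `n_peaks`, `summed_intensity` and `members` (row indices).
#' @export
detect_envelopes <- function(peaks, params = match_params()) {
  keep <- peaks$mz >= params$mz_window[1] & peaks$mz <= params$mz_window[2]
  pk <- peaks[keep, , drop = FALSE]
  if (nrow(pk) == 0L) return(list())
  bins <- floor(pk$rt / params$rt_bin)
  envelopes <- list()
  for (b in unique(bins)) {
    sel <- which(bins == b)
    mz <- pk$mz[sel]; int <- pk$intensity[sel]
    assigned <- rep(FALSE, length(sel))
    tried <- rep(FALSE, length(sel))
    repeat {
      open <- which(!assigned & !tried)
      if (length(open) == 0L) break
      seed <- open[which.max(int[open])]
      found <- FALSE
      for (z in sort(params$charges, decreasing = TRUE)) {
        d <- .ISOTOPE_SPACING / z
        chain <- seed
        # intensity must climb towards the monoisotopic peak on the left
        # and fall away from it on the right; this keeps two nearby
        # envelopes in the same retention-time bin from coalescing
        repeat {  # extend left
          target <- mz[chain[1]] - d
          cand <- which(!assigned & abs(mz - target) <= params$spacing_tol &
                          int >= int[chain[1]])
          cand <- setdiff(cand, chain)
          if (length(cand) == 0L) break
          chain <- c(cand[which.min(abs(mz[cand] - target))], chain)
        }
        repeat {  # extend right
          target <- mz[chain[length(chain)]] + d
          cand <- which(!assigned & abs(mz - target) <= params$spacing_tol &
                          int <= int[chain[length(chain)]])
          cand <- setdiff(cand, chain)
          if (length(cand) == 0L) break
          chain <- c(chain, cand[which.min(abs(mz[cand] - target))])
        }
        # Split the chain where successive spacings are inconsistent:
        # peaks of one envelope share a single calibration offset, so
        # their spacings match 1.00336/z far more tightly than the
        # absolute matching tolerance; a deviation beyond spacing_split
        # marks the boundary with a different envelope.  Only the run
        # containing the seed is kept; other peaks stay unassigned.
        if (length(chain) >= 2L) {
          dev <- abs(diff(mz[chain]) - d)
          cut <- which(dev > (params$spacing_split %||% 0.02))
          if (length(cut) > 0L) {
            bounds <- c(0L, cut, length(chain))
            seed_at <- which(chain == seed)
            for (bi in seq_len(length(bounds) - 1L)) {
              lo <- bounds[bi] + 1L; hi <- bounds[bi + 1L]
              if (seed_at >= lo && seed_at <= hi) {
                chain <- chain[lo:hi]
                break
              }
            }
          }
        }
        if (length(chain) >= params$min_isotope_peaks) {
          assigned[chain] <- TRUE
          envelopes[[length(envelopes) + 1L]] <- list(
            rt = mean(pk$rt[sel][chain]), charge = z,
            mono_mz = mz[chain[1]], n_peaks = length(chain),
            summed_intensity = sum(int[chain]),
            members = sel[chain])
          found <- TRUE
          break
        }
      }
      if (!found) tried[seed] <- TRUE
    }
  }
  envelopes
}

#' Deconvolute envelopes into neutral-mass observations
#'
#' Each envelope yields a neutral mass M = z * mono_mz - z * proton.
#' Envelopes agreeing within `mass_tol` in the same retention-time bin are
#' merged into one observation (typically the 2+ and 3+ envelopes of the
#' same substance).  Observations outside the neutral window are dropped;
#' the signal intensity SI is the summed intensity of the triply charged
#' envelope (0, flagged, when only 2+ support exists).
#'
#' @param envelopes Output of [detect_envelopes()].
#' @param params Parameters from [match_params()].
#' @param alkylated If `TRUE`, the neutral window's upper bound is raised
#'   by 400 Da to admit carbamidomethylated masses.
#' @return Data frame of observations: `obs_id`, `M`, `rt`, `SI`,
#'   `abundance`, `n_envelopes`, `charges`, `alkylation_confirmed`.
#' @export
deconvolute <- function(envelopes, params = match_params(),
                        alkylated = FALSE) {
  empty <- data.frame(obs_id = character(0), M = numeric(0),
                      rt = numeric(0), SI = numeric(0),
                      abundance = character(0), n_envelopes = integer(0),
                      charges = character(0),
                      alkylation_confirmed = character(0),
                      stringsAsFactors = FALSE)
  if (length(envelopes) == 0L) return(empty)
  cst <- mass_constants()
  M <- vapply(envelopes, function(e) e$charge * e$mono_mz -
                e$charge * cst$proton, numeric(1))
  rtb <- floor(vapply(envelopes, `[[`, numeric(1), "rt") / params$rt_bin)
  ord <- order(rtb, M)
  group <- integer(length(envelopes))
  g <- 0L
  for (i in ord) {
    placed <- FALSE
    # assign to a previous group if same rt bin and within tolerance
    prev <- which(group > 0L & rtb == rtb[i] & abs(M - M[i]) <= params$mass_tol)
    if (length(prev) > 0L) {
      group[i] <- group[prev[1L]]
      placed <- TRUE
    }
    if (!placed) {
      g <- g + 1L
      group[i] <- g
    }
  }
  win_hi <- params$neutral_window[2] + if (alkylated) 400 else 0
  rows <- list()
  for (gg in seq_len(g)) {
    idx <- which(group == gg)
    Mg <- mean(M[idx])
    if (Mg < params$neutral_window[1] || Mg > win_hi) next
    zs <- vapply(envelopes[idx], `[[`, integer(1), "charge")
    si3 <- sum(vapply(envelopes[idx][zs == 3L], `[[`, numeric(1),
                      "summed_intensity"))
    rows[[length(rows) + 1L]] <- data.frame(
      obs_id = sprintf("obs%04d", length(rows) + 1L), M = Mg,
      rt = mean(vapply(envelopes[idx], `[[`, numeric(1), "rt")),
      SI = si3, abundance = abundance_level(si3),
      n_envelopes = length(idx),
      charges = paste(sort(unique(zs)), collapse = "+"),
      alkylation_confirmed = "untested", stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Confirm cyclotide identity by the alkylation mass shift
#'
#' A native observation is confirmed when some observation in the
#' reduced-and-alkylated data set sits `alk_delta` above it within
#' `alk_tol`; it is `"no"` when alkylated data exist but no partner is
#' found, and `"untested"` when no alkylated set is supplied.
#'
#' @param native Observations from [deconvolute()].
#' @param alkylated Observations from the alkylated peak list (or NULL).
#' @param params Parameters from [match_params()].
#' @return `native` with `alkylation_confirmed` filled in.
#' @export
confirm_alkylation <- function(native, alkylated = NULL,
                               params = match_params()) {
  if (is.null(alkylated)) {
    native$alkylation_confirmed <- "untested"
    return(native)
  }
  native$alkylation_confirmed <- vapply(native$M, function(m) {
    if (any(abs(alkylated$M - m - params$alk_delta) <= params$alk_tol))
      "yes" else "no"
  }, character(1))
  native
}

#' Match predicted mature masses against observations
#'
#' Every (candidate, observation) pair with |calc_mass - M| strictly below
#' `mass_tol` is reported (many-to-many); for each observation the
#' minimal-|delta| candidate is flagged `best`.
#'
#' @param candidates Candidate table from [enumerate_matures()].
#' @param observations Observations from [deconvolute()].
#' @param params Parameters from [match_params()].
#' @return Data frame: `obs_id`, `M`, `rt`, `SI`, `abundance`,
#'   `alkylation_confirmed`, `precursor_id`, `cd_index`, `start_offset`,
#'   `calc_mass`, `delta`, `best`.
#' @export
match_predicted <- function(candidates, observations,
                            params = match_params()) {
  empty <- data.frame(obs_id = character(0), M = numeric(0),
                      rt = numeric(0), SI = numeric(0),
                      abundance = character(0),
                      alkylation_confirmed = character(0),
                      precursor_id = character(0), cd_index = integer(0),
                      start_offset = integer(0), calc_mass = numeric(0),
                      delta = numeric(0), best = logical(0),
                      stringsAsFactors = FALSE)
  cand <- candidates[!is.na(candidates$calc_mass), , drop = FALSE]
  if (nrow(cand) == 0L || nrow(observations) == 0L) return(empty)
  rows <- list()
  for (i in seq_len(nrow(observations))) {
    d <- cand$calc_mass - observations$M[i]
    hit <- which(abs(d) < params$mass_tol)
    if (length(hit) == 0L) next
    best <- hit[which.min(abs(d[hit]))]
    for (h in hit) {
      rows[[length(rows) + 1L]] <- data.frame(
        obs_id = observations$obs_id[i], M = observations$M[i],
        rt = observations$rt[i], SI = observations$SI[i],
        abundance = observations$abundance[i],
        alkylation_confirmed = observations$alkylation_confirmed[i],
        precursor_id = cand$precursor_id[h], cd_index = cand$cd_index[h],
        start_offset = cand$start_offset[h],
        calc_mass = cand$calc_mass[h], delta = d[h], best = h == best,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Bin a signal intensity into an abundance level
#'
#' Low below 250, high above 1000, medium otherwise (the boundary values
#' 250 and 1000 fall in the closed middle bin).
#'
#' @param SI Summed signal intensity (vectorised).
#' @param params Parameters from [match_params()].
#' @return Character vector of `"low"`, `"medium"`, `"high"`.
#' @export
abundance_level <- function(SI, params = match_params()) {
  stopifnot(all(SI >= 0))
  ifelse(SI < params$si_low, "low",
         ifelse(SI > params$si_high, "high", "medium"))
}
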