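# Conversions between half-lives and first-order degradation rate
# constants, growth-dilution correction, mRNA copy-number estimation from
# TPM, and steady-state synthesis-rate estimation. All functions are
# vectorized over their first argument; rates are min^-1 and times are
# minutes throughout.

#' Degradation rate constant from half-life
#'
#' First-order decay: k = ln(2) / t_half.
#'
#' @param half_life Half-life in minutes (> 0).
#' @return Rate constant in min^-1.
#' @export
rate_from_halflife <- function(half_life) {
  if (any(half_life <= 0, na.rm = TRUE)) {
    stop("half-life must be positive", call. = FALSE)
  }
  log(2) / half_life
}

#' Half-life from degradation rate constant
#'
#' @param k Rate constant in min^-1 (> 0).
#' @return Half-life in minutes.
#' @export
halflife_from_rate <- function(k) {
  if (any(k <= 0, na.rm = TRUE)) stop("rate must be positive", call. = FALSE)
  log(2) / k
}

#' Correct an observed decay rate for growth dilution
#'
#' In a growing culture the per-cell mRNA level declines through both
#' degradation and dilution by cell division, so an observed loss rate is
#' k_obs = k_deg + ln(2)/doubling_time. This subtracts the dilution term.
#' Corrected rates that are not positive are non-physical; they are set to
#' NA and reported with a warning rather than raising an error, so bulk
#' table assembly is robust.
#'
#' @param k_obs Observed loss rate(s), min^-1.
#' @param doubling_time Culture doubling time in minutes.
#' @return Corrected degradation rate(s), min^-1, NA where non-physical.
#' @export
correct_for_dilution <- function(k_obs, doubling_time) {
  if (any(k_obs <= 0, na.rm = TRUE)) {
    stop("observed rates must be positive", call. = FALSE)
  }
  if (length(doubling_time) != 1L || doubling_time <= 0) {
    stop("doubling_time must be a single positive number", call. = FALSE)
  }
  k_deg <- k_obs - log(2) / doubling_time
  bad <- !is.na(k_deg) & k_deg <= 0
  if (any(bad)) {
    warning(sum(bad), " rate(s) non-positive after dilution correction; set to NA",
            call. = FALSE)
    k_deg[bad] <- NA_real_
  }
  k_deg
}

#' mRNA copies per cell from TPM
#'
#' Scales a transcript's share of the mRNA pool (TPM / 1e6) by the total
#' number of mRNA molecules per cell, by default the commonly assumed
#' ~60,000 mRNAs per yeast cell.
#'
#' @param tpm Transcripts per million (>= 0).
#' @param cell_total Total mRNA molecules per cell (default 60000).
#' @return Estimated molecules per cell.
#' @export
copies_from_tpm <- function(tpm, cell_total = 60000) {
  if (any(tpm < 0, na.rm = TRUE)) stop("TPM must be non-negative", call. = FALSE)
  (tpm / 1e6) * cell_total
}

#' Protein molecules per mRNA molecule
#'
#' @param protein_per_cell Protein molecules per cell.
#' @param copies_per_cell mRNA molecules per cell.
#' @return Ratio; NA (with a warning) where copies are zero.
#' @export
protein_per_mrna <- function(protein_per_cell, copies_per_cell) {
  out <- protein_per_cell / copies_per_cell
  zero <- !is.na(copies_per_cell) & copies_per_cell == 0
  if (any(zero)) {
    warning(sum(zero), " gene(s) with zero mRNA copies; ratio set to NA",
            call. = FALSE)
    out[zero] <- NA_real_
  }
  out
}

#' Synthesis rate from steady state
#'
#' At steady state, synthesis balances first-order loss, so the synthesis
#' rate is abundance times the degradation rate constant.
#'
#' @param steady_state_copies Molecules per cell (> 0).
#' @param k_deg Degradation rate constant, min^-1 (> 0).
#' @return Synthesis rate in molecules per minute.
#' @export
synthesis_rate <- function(steady_state_copies, k_deg) {
  if (any(steady_state_copies <= 0, na.rm = TRUE) ||
      any(k_deg <= 0, na.rm = TRUE)) {
    stop("steady-state abundance and rate must be positive", call. = FALSE)
  }
  steady_state_copies * k_deg
}
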