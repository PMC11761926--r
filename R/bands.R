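#' Neural frequency band definitions
#'
#' Conventional oscillation bands used for EMG-EMG coherence analysis. Band
#' intervals are half-open, `[lo, hi)`, so that shared printed endpoints
#' (e.g. 13 Hz between alpha and beta) assign each frequency bin to exactly
#' one band and the six bands tile `[0, 100)` Hz without overlap.
#'
#' @param names Optional character vector selecting a subset of bands, in the
#'   order given.
#' @return A data.frame with columns `band`, `lo`, `hi` (Hz).
#' @examples
#' band_definitions()
#' band_definitions(c("alpha", "beta"))
#' @export
band_definitions <- function(names = NULL) {
  bands <- data.frame(
    band = c("delta", "theta", "alpha", "beta", "lower_gamma", "upper_gamma"),
    lo   = c(0, 4, 8, 13, 30, 60),
    hi   = c(4, 8, 13, 30, 60, 100),
    stringsAsFactors = FALSE
  )
  if (is.null(names)) {
    return(bands)
  }
  unknown <- setdiff(names, bands$band)
  if (length(unknown) > 0) {
    stop("unknown band name(s): ", paste(unknown, collapse = ", "))
  }
  out <- bands[match(names, bands$band), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bands analyzed by default
#'
#' Alpha, beta, lower gamma and upper gamma. Delta and theta are defined but
#' excluded by default because a 10 Hz acquisition high-pass filter removes
#' most signal power below 10 Hz, masking EMG-EMG coherence there; they can
#' be re-included explicitly via [run_config()].
#'
#' @return Character vector of band names.
#' @export
default_analyzed_bands <- function() {
  c("alpha", "beta", "lower_gamma", "upper_gamma")
}
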