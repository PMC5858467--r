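#' EEG frequency band definitions
#'
#' Returns the ordered band map used for FFT band-power extraction. Two
#' presets are shipped because the source device documentation and the
#' conventional EEG literature disagree on band edges:
#'
#' * `"device"` — the ThinkGear device bands (Delta 0.5--4, Theta 4--7,
#'   LowAlpha 7.5--9, HighAlpha 9.5--12.5, LowBeta 12--15, HighBeta 15--18,
#'   LowGamma 30--80, HighGamma 80--Nyquist). Gamma edges are capped at the
#'   Nyquist frequency of the recording.
#' * `"conventional"` — a conventional reading (Delta 1--3, Theta 4--7,
#'   Alpha I 8--9, Alpha II 10--12, Beta I 13--17, Beta II 18--30,
#'   Gamma I 31--40, Gamma II 41--50), mapped onto the same eight column
#'   names so either preset feeds the same downstream schema.
#'
#' Band powers are accumulated over FFT bins whose frequency lies in
#' `[low, high)`.
#'
#' @param preset `"device"` (default) or `"conventional"`.
#' @param sample_rate sampling rate in Hz; used to cap band edges at Nyquist.
#' @return A `band_definitions` object: a data frame with columns `band`,
#'   `low`, `high` (Hz), ordered by ascending low edge.
#' @examples
#' band_definitions()
#' band_definitions("conventional")
#' @export
band_definitions <- function(preset = c("device", "conventional"),
                             sample_rate = 512) {
  preset <- match.arg(preset)
  nyq <- sample_rate / 2
  defs <- switch(preset,
    device = data.frame(
      band = c("Delta", "Theta", "LowAlpha", "HighAlpha",
               "LowBeta", "HighBeta", "LowGamma", "HighGamma"),
      low  = c(0.5, 4, 7.5, 9.5, 12, 15, 30, 80),
      high = c(4, 7, 9, 12.5, 15, 18, 80, nyq),
      stringsAsFactors = FALSE
    ),
    conventional = data.frame(
      band = c("Delta", "Theta", "LowAlpha", "HighAlpha",
               "LowBeta", "HighBeta", "LowGamma", "HighGamma"),
      low  = c(1, 4, 8, 10, 13, 18, 31, 41),
      high = c(3, 7, 9, 12, 17, 30, 40, 50),
      stringsAsFactors = FALSE
    )
  )
  defs$low <- pmin(defs$low, nyq)
  defs$high <- pmin(defs$high, nyq)
  defs <- defs[defs$low < defs$high, , drop = FALSE]
  validate_band_definitions(defs)
  structure(defs, class = c("band_definitions", "data.frame"),
            preset = preset, sample_rate = sample_rate)
}

validate_band_definitions <- function(defs) {
  stopifnot(is.data.frame(defs),
            all(c("band", "low", "high") %in% names(defs)))
  if (any(defs$low >= defs$high)) {
    stop("each band must satisfy low < high", call. = FALSE)
  }
  if (is.unsorted(defs$low)) {
    stop("bands must be listed in ascending low-edge order", call. = FALSE)
  }
  invisible(defs)
}

#' @export
print.band_definitions <- function(x, ...) {
  cat("EEG band definitions (preset '", attr(x, "preset"), "', fs = ",
      attr(x, "sample_rate"), " Hz)\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
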