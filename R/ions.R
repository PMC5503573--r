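#' Ion labels
#'
#' Untargeted LC-MS features ("spectral ions") are identified by their
#' chromatographic retention time (minutes) and mass-to-charge ratio.  The
#' canonical string form is \code{"(R min: M m/z)"} with the retention time
#' printed to 2 decimal places and the m/z to 3, e.g.
#' \code{"(2.56 min: 314.085 m/z)"}.  At that precision the label is bijective
#' with the (rt, mz) pair.
#'
#' @param rt Retention time in minutes; must be positive.
#' @param mz Mass-to-charge ratio in Thomson; must be positive.
#' @return `ion_label()` returns the canonical label string(s);
#'   `parse_ion_label()` returns a data.frame with columns `rt` and `mz`.
#' @examples
#' ion_label(2.56, 314.085)
#' parse_ion_label("(2.56 min: 314.085 m/z)")
#' @export
ion_label <- function(rt, mz) {
  if (any(rt <= 0) || any(mz <= 0)) {
    ms_stop("retention time and m/z must be positive", "config_error")
  }
  sprintf("(%.2f min: %.3f m/z)", rt, mz)
}

#' @param label Character vector of canonical ion labels.
#' @rdname ion_label
#' @export
parse_ion_label <- function(label) {
  pat <- "^\\(([0-9]+\\.?[0-9]*) min: ([0-9]+\\.?[0-9]*) m/z\\)$"
  ok <- grepl(pat, label)
  if (!all(ok)) {
    ms_stop(sprintf("malformed ion label: '%s'", label[!ok][1L]),
            "format_error")
  }
  data.frame(
    rt = as.numeric(sub(pat, "\\1", label)),
    mz = as.numeric(sub(pat, "\\2", label))
  )
}
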