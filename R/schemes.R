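#' Six-band frequency scheme
#'
#' The canonical six analysis bands covering the 1-40 Hz broadband range:
#' delta \[1,4), theta \[4,8), alpha \[8,12), beta1 \[12,16), beta2 \[16,24)
#' and beta3 \[24,40\]. Band edges are half-open so shared edges are counted
#' once; the final band is closed at 40 Hz. This guarantees the six relative
#' powers always sum to one.
#'
#' @return A tibble with columns `band`, `lo`, `hi` (Hz).
#' @export
band_scheme <- function() {
  tibble::tibble(
    band = c("delta", "theta", "alpha", "beta1", "beta2", "beta3"),
    lo = c(1, 4, 8, 12, 16, 24),
    hi = c(4, 8, 12, 16, 24, 40)
  )
}

#' Ten regions of interest over the 10-20 montage
#'
#' Named list mapping each ROI to its three electrodes. The midline
#' electrodes Fz and Pz are shared between overlapping ROIs.
#'
#' @return Named list of character vectors.
#' @export
roi_scheme <- function() {
  list(
    PFC  = c("Fp1", "Fp2", "Fz"),
    RMFC = c("Fz", "F4", "F8"),
    LMFC = c("Fz", "F3", "F7"),
    CC   = c("C3", "C4", "Cz"),
    PP   = c("P3", "P4", "Pz"),
    LT   = c("F7", "T3", "T5"),
    RT   = c("F8", "T4", "T6"),
    MOC  = c("O1", "Pz", "O2"),
    RMOC = c("P4", "O2", "Pz"),
    LMOC = c("P3", "O1", "Pz")
  )
}

#' Homologous right/left ROI pairs for asymmetry scores
#'
#' @return Named list; each element is `c(right, left)`. Names are the
#'   conventional "R-L" pair labels.
#' @export
roi_pairs <- function() {
  list(
    "RMFC-LMFC" = c("RMFC", "LMFC"),
    "RMOC-LMOC" = c("RMOC", "LMOC"),
    "RT-LT" = c("RT", "LT")
  )
}

# Bands entering asymmetry scores (delta excluded).
.asymmetry_bands <- c("theta", "alpha", "beta1", "beta2", "beta3")
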