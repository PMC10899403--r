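#' Canonical 19-channel 10-20 montage
#'
#' Channel labels of the standard 19-electrode international 10-20 layout, in
#' the fixed order used throughout the package.
#'
#' @format Character vector of length 19.
#' @export
montage_1020 <- c(
  "Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
  "T3", "C3", "Cz", "C4", "T4",
  "T5", "P3", "Pz", "P4", "T6", "O1", "O2"
)

# Modern-nomenclature aliases for the temporal row.
.label_aliases <- c(T7 = "T3", T8 = "T4", P7 = "T5", P8 = "T6")

# Coarse scalp region classes used by the simulator for base amplitudes.
.region_class <- c(
  Fp1 = "frontal", Fp2 = "frontal", F7 = "frontal", F3 = "frontal",
  Fz = "frontal", F4 = "frontal", F8 = "frontal",
  T3 = "central", C3 = "central", Cz = "central", C4 = "central", T4 = "central",
  T5 = "posterior", P3 = "posterior", Pz = "posterior", P4 = "posterior",
  T6 = "posterior", O1 = "posterior", O2 = "posterior"
)

# Channels showing eyes-closed alpha reactivity at full strength.
.posterior_channels <- names(.region_class)[.region_class == "posterior"]

#' Normalize EEG channel labels to the canonical 10-20 set
#'
#' Matching is case-insensitive (`"FP1"` maps to `"Fp1"`) and the modern
#' temporal labels `T7/T8/P7/P8` are accepted as aliases of `T3/T4/T5/T6`.
#'
#' @param labels Character vector of channel labels.
#' @return Character vector of canonical labels.
#' @examples
#' normalize_channel_labels(c("FP1", "t7", "Cz"))
#' @export
normalize_channel_labels <- function(labels) {
  up <- toupper(trimws(labels))
  canon <- montage_1020
  names(canon) <- toupper(canon)
  alias <- .label_aliases
  names(alias) <- toupper(names(alias))
  out <- ifelse(up %in% names(canon), canon[up],
    ifelse(up %in% names(alias), alias[up], NA_character_)
  )
  if (anyNA(out)) {
    stop(
      "Unknown channel label(s): ",
      paste(labels[is.na(out)], collapse = ", ")
    )
  }
  unname(out)
}
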