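#' Synthesize a weighted image from parameter maps
#'
#' Standard spin-echo / inversion-recovery closed forms applied voxelwise
#' to fitted (or ground-truth) maps:
#' without `TI`, `S = PD (1 - exp(-TR/T1)) exp(-TE/T2)`; with `TI`,
#' `S = PD |1 - 2 exp(-TI/T1) + exp(-TR/T1)| exp(-TE/T2)`.
#' Typical settings: T1-weighted `TE = 20, TR = 300`; T2-weighted
#' `TE = 120, TR = 4500`; T2-FLAIR `TE = 120, TR = 15000, TI = 3000` (ms).
#'
#' @param maps Data frame with columns `T1`, `T2`, `PD` (ms, ms, a.u.).
#' @param TE Echo time, ms (`TE < TR`).
#' @param TR Repetition time, ms.
#' @param TI Optional inversion time, ms (`TI < TR`).
#' @return The input with a `signal` column appended; voxels with
#'   non-positive `T1`/`T2` inside the object get `NA`.
#' @export
synthesize_contrast <- function(maps, TE, TR, TI = NULL) {
  stopifnot(TE < TR, is.null(TI) || TI < TR)
  ok <- !is.na(maps$T1) & !is.na(maps$T2) & maps$T1 > 0 & maps$T2 > 0
  s <- rep(NA_real_, nrow(maps))
  t1 <- maps$T1[ok]; t2 <- maps$T2[ok]; pd <- maps$PD[ok]
  if (is.null(TI)) {
    s[ok] <- pd * (1 - exp(-TR / t1)) * exp(-TE / t2)
  } else {
    s[ok] <- pd * abs(1 - 2 * exp(-TI / t1) + exp(-TR / t1)) * exp(-TE / t2)
  }
  s[!is.na(maps$PD) & maps$PD == 0] <- 0
  dplyr::mutate(tibble::as_tibble(maps), signal = s)
}

#' Standard contrast settings
#'
#' @return Tibble of named `ContrastSpec`s (`contrast`, `TE`, `TR`, `TI`).
#' @export
contrast_presets <- function() {
  tibble::tibble(
    contrast = c("T1w", "T2w", "FLAIR"),
    TE = c(20, 120, 120),
    TR = c(300, 4500, 15000),
    TI = c(NA, NA, 3000)
  )
}
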