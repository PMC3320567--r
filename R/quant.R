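#' Relative response ratio of a reporter measurement
#'
#' Expresses a luminescence reading on a 0-100 percent scale between a
#' negative and a positive control:
#' `((sample - negative) * 100) / (positive - negative)`. The result is
#' invariant under adding a constant to, or rescaling, all three signals.
#'
#' @param sample,negative_control,positive_control Luminescence readings
#'   (arbitrary units); vectors are recycled to a common length.
#' @return Relative activity in percent.
#' @export
#' @examples
#' relative_response_ratio(5000, 1000, 5000)  # 100
#' relative_response_ratio(1000, 1000, 5000)  # 0
relative_response_ratio <- function(sample, negative_control,
                                    positive_control) {
  if (any(positive_control == negative_control)) {
    abort("positive and negative control signals are equal; relative response ratio is undefined")
  }
  (sample - negative_control) * 100 / (positive_control - negative_control)
}

#' GAPDH-normalised phospho/total band ratio
#'
#' Immunoblot quantification: the ratio of the phospho-specific band to the
#' total-protein band, normalised to the loading-control (GAPDH) band:
#' `(phospho / total) / loading`. Normalisation divides by the raw loading
#' intensity, not by a loading value relative to a reference lane.
#'
#' @param phospho,total,loading Band intensities; `total` and `loading` must
#'   be positive.
#' @return Dimensionless normalised ratio.
#' @export
#' @examples
#' normalized_phospho_ratio(2, 4, 1)  # 0.5
normalized_phospho_ratio <- function(phospho, total, loading) {
  if (any(total <= 0)) abort("total band intensity must be positive")
  if (any(loading <= 0)) abort("loading band intensity must be positive")
  (phospho / total) / loading
}

#' Firefly/renilla reporter normalisation
#'
#' Normalises firefly luciferase activity to the renilla luciferase
#' transfection control of the same well: `firefly / renilla`.
#'
#' @param firefly,renilla Luminescence readings; `renilla` must be positive.
#' @return Normalised activity ratio.
#' @export
#' @examples
#' reporter_normalize(10, 2)  # 5
reporter_normalize <- function(firefly, renilla) {
  if (any(renilla <= 0)) abort("renilla signal must be positive")
  firefly / renilla
}

#' Mean and standard deviation of replicate values
#'
#' Summary for replicate wells/lanes: arithmetic mean and sample (n-1)
#' standard deviation.
#'
#' @param x Numeric vector of per-replicate values (e.g. per-well normalised
#'   activities).
#' @return Tibble with `mean`, `sd`, `n`.
#' @export
summarize_replicates <- function(x) {
  tibble(mean = mean(x), sd = sd(x), n = length(x))
}
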