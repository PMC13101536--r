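#' Single-factor pollution index
#'
#' P_i = C_i / S_i: measured concentration over the regional background value
#' for the same element. Unitless; P_i > 1 means the element exceeds
#' background. Vectorized over `C` and `S`.
#'
#' @param C measured concentration(s), mg/kg, >= 0.
#' @param S background value(s), mg/kg, > 0.
#' @export
single_factor_index <- function(C, S) {
  if (any(S <= 0)) stop("background value S must be > 0")
  if (any(C < 0)) stop("concentration C must be >= 0")
  C / S
}

#' Nemerow composite pollution index
#'
#' Combines the mean and the maximum of the single-factor indices,
#' Pn = sqrt((mean(P)^2 + max(P)^2) / 2), so the most severe pollutant
#' dominates while the average still contributes. As a quadratic mean of two
#' values, Pn always lies between mean(P) and max(P).
#'
#' @param P non-empty vector of single-factor indices, all >= 0.
#' @export
nemerow_index <- function(P) {
  if (length(P) == 0) stop("P must be non-empty")
  if (any(P < 0)) stop("single-factor indices must be >= 0")
  sqrt((mean(P)^2 + max(P)^2) / 2)
}

#' Classify a sample as polluted
#'
#' An index value strictly exceeding 1 indicates contamination.
#'
#' @param Pn Nemerow index value(s), >= 0.
#' @return logical.
#' @export
classify_pollution <- function(Pn) {
  if (any(Pn < 0)) stop("Pn must be >= 0")
  Pn > 1
}

#' Per-sample pollution indices from metadata
#'
#' Computes the five single-factor indices and the Nemerow composite index
#' for every sample. Background values are a required input: they are
#' region-specific reference concentrations and are never hard-coded for real
#' data.
#'
#' @param metadata data.frame with columns Cd, Zn, Fe, Cu, Pb (mg/kg) and
#'   `sample_id`.
#' @param backgrounds named vector of background concentrations for the same
#'   five elements (mg/kg, > 0).
#' @return data.frame: sample_id, one `P_<element>` column per element,
#'   `Pn`, and logical `polluted`.
#' @export
pollution_indices <- function(metadata, backgrounds) {
  miss <- setdiff(METAL_ELEMENTS, names(metadata))
  if (length(miss)) stop("metadata missing metal column(s): ", paste(miss, collapse = ", "))
  miss_b <- setdiff(METAL_ELEMENTS, names(backgrounds))
  if (length(miss_b)) stop("backgrounds missing element(s): ", paste(miss_b, collapse = ", "))
  P <- sapply(METAL_ELEMENTS, function(el)
    single_factor_index(metadata[[el]], backgrounds[[el]]))
  P <- matrix(P, nrow = nrow(metadata),
              dimnames = list(NULL, paste0("P_", METAL_ELEMENTS)))
  Pn <- apply(P, 1, nemerow_index)
  data.frame(sample_id = metadata$sample_id, P, Pn = Pn,
             polluted = classify_pollution(Pn), stringsAsFactors = FALSE)
}
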