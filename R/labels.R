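#' Admissible disease labels
#'
#' The classifier targets four common neurological diagnoses identified by
#' their ICD codes. The code/name mapping is fixed and bijective; every label
#' travelling through the package must be one of these four codes.
#'
#' @return A named character vector mapping ICD code to display name, in the
#'   canonical class order used for all probability vectors.
#' @export
#' @examples
#' disease_labels()
disease_labels <- function() {
  c(
    G40 = "epilepsy-recurrent seizures",
    R51 = "headache",
    M54 = "dorsalgia",
    I63 = "cerebral infarction"
  )
}

#' Canonical class order
#'
#' @return Character vector of the four ICD codes in the order used for
#'   logits/probability vectors.
#' @export
disease_codes <- function() names(disease_labels())

#' Validate ICD label codes
#'
#' @param code character vector of candidate codes.
#' @return `code`, invisibly, if all admissible.
#' @keywords internal
assert_labels <- function(code) {
  bad <- setdiff(unique(as.character(code)), disease_codes())
  if (length(bad) > 0) {
    stop("inadmissible disease code(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(disease_codes(), collapse = ", "), ")",
         call. = FALSE)
  }
  invisible(code)
}

#' Integer class index of a label code
#'
#' @param code character vector of ICD codes.
#' @return integer vector of 1-based class indices in canonical order.
#' @keywords internal
label_index <- function(code) {
  assert_labels(code)
  match(as.character(code), disease_codes())
}
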