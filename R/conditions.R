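#' Experimental conditions of the reciprocal glucose-shift design
#'
#' The design comprises four culture conditions: cells adapted to low
#' (1.25 g/L) or high (5 g/L) glucose supplementation (\code{LL},
#' \code{HH}) and cells sampled 36 h after a reciprocal medium shift
#' (\code{L2H}: low to high; \code{H2L}: high to low). The transcriptome
#' of a shifted culture is taken to respond to the glucose level it was
#' shifted \emph{into} (its target level), so \code{L2H} pairs with the
#' high level and \code{H2L} with the low level.
#'
#' @param label Character vector of condition labels; each must be one
#'   of \code{"LL"}, \code{"HH"}, \code{"L2H"}, \code{"H2L"}.
#' @return A data.frame with one row per input label and columns
#'   \code{label}, \code{glucose_level} (g/L of the medium the culture
#'   was adapted in before sampling), \code{is_shifted}, and
#'   \code{target_level} (g/L the transcriptome is responding to; for
#'   shifted cultures this is the post-shift level).
#' @examples
#' condition_info(c("LL", "L2H"))
#' @export
condition_info <- function(label) {
  stopifnot(is.character(label))
  bad <- setdiff(label, CONDITION_LABELS)
  if (length(bad) > 0L) {
    stop("unknown condition label(s): ", paste(bad, collapse = ", "),
         "; allowed labels are: ", paste(CONDITION_LABELS, collapse = ", "))
  }
  tab <- data.frame(
    label         = CONDITION_LABELS,
    glucose_level = c(GLUCOSE_LOW, GLUCOSE_HIGH, GLUCOSE_LOW, GLUCOSE_HIGH),
    is_shifted    = c(FALSE, FALSE, TRUE, TRUE),
    target_level  = c(GLUCOSE_LOW, GLUCOSE_HIGH, GLUCOSE_HIGH, GLUCOSE_LOW),
    stringsAsFactors = FALSE
  )
  tab[match(label, tab$label), , drop = FALSE]
}

#' @rdname condition_info
#' @format \code{CONDITION_LABELS} is the character vector of the four
#'   allowed labels in canonical order.
#' @export
CONDITION_LABELS <- c("LL", "HH", "L2H", "H2L")

GLUCOSE_LOW <- 1.25
GLUCOSE_HIGH <- 5
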