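#' Yield classification rule
#'
#' The national-trial thresholds that partition measured grain yield into the
#' three classes: A above `upper`, B between `lower` and `upper` (both
#' inclusive), C below `lower`. Defaults: 750 and 700 kg per mu.
#'
#' @param upper,lower class thresholds in kg per mu; `upper` must exceed
#'   `lower`.
#' @return object of class `yield_class_rule`.
#' @export
yield_class_rule <- function(upper = 750, lower = 700) {
  stopifnot_scalar_number(upper, "upper", lower = 0)
  stopifnot_scalar_number(lower, "lower", lower = 0)
  if (upper <= lower) stop("`upper` must exceed `lower`", call. = FALSE)
  structure(list(upper = upper, lower = lower), class = "yield_class_rule")
}

#' Assign yield classes from measured yield
#'
#' Vectorized threshold rule: class A iff yield > upper threshold, B iff
#' lower <= yield <= upper, C iff yield < lower. Exactly one class for every
#' non-negative yield; boundary values 700 and 750 both fall in class B.
#'
#' @param yield_kg_per_mu numeric vector of non-negative yields (kg per mu).
#' @param rule a [yield_class_rule()].
#' @return factor with levels A, B, C.
#' @examples
#' assign_yield_class(c(760, 725, 690)) # A B C
#' @export
assign_yield_class <- function(yield_kg_per_mu, rule = yield_class_rule()) {
  if (!inherits(rule, "yield_class_rule")) {
    stop("`rule` must be a `yield_class_rule`", call. = FALSE)
  }
  y <- as.numeric(yield_kg_per_mu)
  if (any(!is.finite(y)) || any(y < 0)) {
    stop("yields must be finite and non-negative", call. = FALSE)
  }
  cls <- ifelse(y > rule$upper, "A", ifelse(y >= rule$lower, "B", "C"))
  factor(cls, levels = c("A", "B", "C"))
}

#' Lodging index of a line
#'
#' The count of field replicates of one line in which lodging was observed:
#' the sum of the per-replicate 0/1 lodging flags, an integer from 0 to the
#' replicate count. The index is attached to every sample of the line during
#' feature fusion.
#'
#' @param flags integer vector of 0/1 lodging flags, one per replicate.
#' @param n_replicates expected number of flags (default 3).
#' @return integer in 0..`n_replicates`.
#' @examples
#' lodging_index(c(0, 0, 0)) # 0
#' lodging_index(c(1, 1, 1)) # 3
#' @export
lodging_index <- function(flags, n_replicates = 3) {
  if (length(flags) != n_replicates) {
    stop(sprintf("expected %d replicate flags, got %d", n_replicates,
                 length(flags)), call. = FALSE)
  }
  if (!all(flags %in% c(0, 1))) {
    stop("lodging flags must be 0 or 1", call. = FALSE)
  }
  as.integer(sum(flags))
}
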