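#' Convert methylation Beta values to M values
#'
#' The M value is the base-2 logit of the Beta value,
#' \eqn{M = \log_2(\beta / (1 - \beta))}. Beta values are clamped into
#' \eqn{[\epsilon, 1 - \epsilon]} before the transform so fully methylated or
#' unmethylated probes map to large finite M values rather than infinities.
#' The M scale is the variance-stabilised scale on which all rank-correlation
#' and linear-model screening is performed; Beta values are kept for
#' effect-size reporting because they read directly as methylation fractions.
#'
#' @param beta Numeric vector of methylation fractions in \[0, 1\].
#' @param epsilon_clip Symmetric clamp applied before the logit
#'   (default `1e-6`).
#' @return Numeric vector of M values.
#' @seealso [m_to_beta()] for the inverse.
#' @examples
#' beta_to_m(c(0.2, 0.5, 0.8))  # -2, 0, 2
#' @export
beta_to_m <- function(beta, epsilon_clip = 1e-6) {
  if (!is.numeric(beta)) abort("`beta` must be numeric.")
  bad <- !is.na(beta) & (beta < 0 | beta > 1)
  if (any(bad)) {
    abort(sprintf("Beta values outside [0, 1]: e.g. %.4g", beta[which(bad)[1]]))
  }
  b <- pmin(pmax(beta, epsilon_clip), 1 - epsilon_clip)
  log2(b / (1 - b))
}

#' Convert M values back to Beta values
#'
#' Inverse base-2 logit, \eqn{\beta = 2^M / (1 + 2^M)}. Exact inverse of
#' [beta_to_m()] away from the clamp.
#'
#' @param m Numeric vector of finite M values.
#' @return Numeric vector of Beta values in (0, 1).
#' @examples
#' m_to_beta(c(-2, 0, 2))  # 0.2, 0.5, 0.8
#' @export
m_to_beta <- function(m) {
  if (!is.numeric(m)) abort("`m` must be numeric.")
  # 1 / (1 + 2^-m) is stable for large |m|
  1 / (1 + 2^(-m))
}

.grade_levels <- c(III = 3L, IV = 4L, V = 5L, VI = 6L, VII = 7L)

#' Convert Roman histological grade labels to numerals
#'
#' Maps AHA lesion grades III--VII to the integers 3--7 used as the ordinal
#' axis of the drift screen.
#'
#' @param label Character vector of Roman grade labels (`"III"` .. `"VII"`).
#' @return Integer vector in 3..7.
#' @examples
#' grade_to_numeral(c("III", "VII"))
#' @export
grade_to_numeral <- function(label) {
  out <- .grade_levels[as.character(label)]
  if (anyNA(out)) {
    bad <- unique(as.character(label)[is.na(out)])
    abort(sprintf("Unsupported grade label(s): %s (expected III-VII)",
                  paste(bad, collapse = ", ")))
  }
  unname(out)
}

#' Convert numeric grades 3--7 back to Roman labels
#' @param numeral Integer vector in 3..7.
#' @return Character vector of Roman labels.
#' @export
numeral_to_grade <- function(numeral) {
  idx <- match(as.integer(numeral), .grade_levels)
  if (anyNA(idx)) abort("Numeric grades must lie in 3..7.")
  names(.grade_levels)[idx]
}
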