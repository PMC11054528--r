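#' Round half away from zero
#'
#' Rounding used when reproducing printed tables: 2.675 -> 2.68,
#' -2.675 -> -2.68 (base R's \code{round} rounds half to even).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded vector.
#' @export
round_half_away <- function(x, digits = 2) {
  p <- 10^digits
  # the 1e-8 guard absorbs binary representation error in values that are
  # exact halves in decimal (2.675 * 100 is 267.4999... in double)
  sign(x) * floor(abs(x) * p + 0.5 + 1e-8) / p
}

#' Fit a CHI calibration line
#'
#' Ordinary least-squares fit of literature index values against gradient
#' retention times for a set of calibration standards, giving the linear map
#' used to place analyte retention times on the index scale (CHI or
#' CHI_IAM). The fast-gradient protocol runs a calibration mixture of
#' standards with known index values and converts analyte retention times
#' through this line.
#'
#' @param standards data frame with columns \code{rt_min} (gradient
#'   retention time, minutes) and \code{literature_index} (the standard's
#'   published index value). Extra columns (e.g. \code{id}) are ignored.
#'   An example table with synthetic placeholder values ships at
#'   \code{system.file("extdata", "example_standards_synthetic.csv",
#'   package = "lipochrom")}; it illustrates the format only -- literature
#'   index values must come from the user's own calibration set.
#' @return An object of class \code{"chi_calibration"}: list with
#'   \code{slope} (index units per minute), \code{intercept} (index units),
#'   \code{r_squared}, \code{n_standards}, and the underlying \code{lm} fit.
#' @export
#' @examples
#' std <- data.frame(rt_min = c(1, 2), literature_index = c(10, 30))
#' fit_calibration(std)
fit_calibration <- function(standards) {
  if (!all(c("rt_min", "literature_index") %in% names(standards)))
    stop("standards must have columns 'rt_min' and 'literature_index'")
  rt <- standards$rt_min
  y <- standards$literature_index
  keep <- is.finite(rt) & is.finite(y)
  rt <- rt[keep]; y <- y[keep]
  if (length(rt) < 2)
    stop("calibration failure: need at least 2 standards")
  if (length(unique(rt)) < 2)
    stop("calibration failure: all retention times identical (degenerate design)")
  fit <- stats::lm(y ~ rt)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 n_standards = length(rt),
                 fit = fit),
            class = "chi_calibration")
}

#' @export
print.chi_calibration <- function(x, ...) {
  cat("CHI calibration line (n =", x$n_standards, "standards)\n")
  cat(sprintf("  index = %.4f * rt_min + %.4f   (R^2 = %.4f)\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Apply a calibration line to analyte retention times
#'
#' Maps retention times to the index scale. The CHI scale is nominally
#' 0--100 but extrapolation beyond it is allowed; indices outside [0, 100]
#' are returned and flagged in the \code{"extrapolated"} attribute.
#'
#' @param line a \code{"chi_calibration"} object (or any list with
#'   \code{slope} and \code{intercept}).
#' @param rt_min retention times in minutes (non-negative).
#' @return Numeric index values with logical attribute
#'   \code{"extrapolated"} marking values outside the nominal 0--100 scale.
#' @export
apply_calibration <- function(line, rt_min) {
  if (any(rt_min < 0, na.rm = TRUE))
    stop("negative retention time")
  idx <- line$slope * rt_min + line$intercept
  attr(idx, "extrapolated") <- idx < 0 | idx > 100
  idx
}

#' Convert CHI to CHI LogP
#'
#' Linear conversion of the chromatographic hydrophobicity index measured on
#' the nonionized form to the octanol--water LogP scale:
#' \code{CHI LogP = 0.054 * CHI - 1.467}.
#'
#' @param chi CHI values (dimensionless index).
#' @param round if \code{TRUE}, round half-away-from-zero to 2 decimals as
#'   printed in tabulations.
#' @return CHI LogP values.
#' @export
#' @examples
#' chi_to_chilogp(91.64, round = TRUE)  # 3.48
chi_to_chilogp <- function(chi, round = FALSE) {
  stopifnot(all(is.finite(chi)))
  out <- 0.054 * chi - 1.467
  if (round) round_half_away(out, 2) else out
}

#' Convert percent HSA binding to logK_HSA
#'
#' The chromatographic HSA binding constant and the percent-bound scale are
#' related by \code{logK = log10(pct / (101 - pct))}; the 101 denominator is
#' the convention of biomimetic HSA chromatography and reproduces tabulated
#' logK/percent pairs to 2 decimals (a 100 denominator does not, missing
#' high binders by about 1 percent).
#'
#' @param pct percent HSA binding, strictly between 0 and 101.
#' @param round if \code{TRUE}, round half-away-from-zero to 2 decimals.
#' @return logK_HSA values.
#' @seealso [logk_to_pct_hsa()]
#' @export
#' @examples
#' pct_hsa_to_logk(47.66, round = TRUE)  # -0.05
pct_hsa_to_logk <- function(pct, round = FALSE) {
  if (any(!is.finite(pct)) || any(pct <= 0) || any(pct >= 101))
    stop("pct must lie strictly between 0 and 101")
  out <- log10(pct / (101 - pct))
  if (round) round_half_away(out, 2) else out
}

#' Convert logK_HSA to percent HSA binding
#'
#' Inverse of [pct_hsa_to_logk()]: \code{pct = 101 * 10^logk / (1 + 10^logk)}.
#' Values above 100 percent arise for very strong binders (logK above about
#' 2) and are reported censored as "> 99.8".
#'
#' @param logk finite logK_HSA values.
#' @return Numeric percent values in (0, 101) with logical attribute
#'   \code{"censored"} marking values above 100, which should be reported
#'   as "> 99.8".
#' @export
logk_to_pct_hsa <- function(logk) {
  stopifnot(all(is.finite(logk)))
  k <- 10^logk
  pct <- 101 * k / (1 + k)
  attr(pct, "censored") <- pct > 100
  pct
}

#' Classify acid/base character from a multi-pH CHI profile
#'
#' Bases are suppressed (ionized, hence less retained) at low pH, acids at
#' high pH; a neutral compound retains a flat CHI profile across pH 2.6,
#' 7.4 and 10.6. The call is made from the two successive differences
#' \code{delta_low = chi_neutral - chi_acid} and
#' \code{delta_high = chi_basic - chi_neutral}: upward evidence (CHI rising
#' with pH, basic character) is \code{max(delta_low, delta_high, 0)} and
#' downward evidence (CHI falling with pH, acidic character) is
#' \code{max(-delta_low, -delta_high, 0)}. If only the upward evidence
#' exceeds the threshold the compound is called basic; only downward,
#' acidic; neither, neutral. If both exceed it (rise then fall, e.g. an
#' ampholyte) the dominant direction is reported and the call is flagged
#' ambiguous.
#'
#' @param chi_acid CHI at pH 2.6.
#' @param chi_neutral CHI at pH 7.4.
#' @param chi_basic CHI at pH 10.6.
#' @param threshold CHI units that count as a "significant" shift;
#'   default 10.
#' @return A data frame (one row per compound) with columns \code{call}
#'   (\code{"acidic"}, \code{"basic"} or \code{"neutral"}),
#'   \code{delta_low}, \code{delta_high} and \code{ambiguous}.
#' @export
#' @examples
#' classify_acid_base(48.96, 88.07, 91.64)  # basic
classify_acid_base <- function(chi_acid, chi_neutral, chi_basic,
                               threshold = 10) {
  stopifnot(all(is.finite(chi_acid)), all(is.finite(chi_neutral)),
            all(is.finite(chi_basic)), threshold > 0)
  d_low <- chi_neutral - chi_acid
  d_high <- chi_basic - chi_neutral
  up <- pmax(d_low, d_high, 0)
  down <- pmax(-d_low, -d_high, 0)
  call <- ifelse(up > threshold & down <= threshold, "basic",
          ifelse(down > threshold & up <= threshold, "acidic",
          ifelse(up <= threshold & down <= threshold, "neutral",
                 ifelse(up >= down, "basic", "acidic"))))
  data.frame(call = call, delta_low = d_low, delta_high = d_high,
             ambiguous = up > threshold & down > threshold)
}
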