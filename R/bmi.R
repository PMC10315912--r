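#' BMI distribution (normal model)
#'
#' The device used to translate a population mean-BMI shift into a change
#' in obesity prevalence: BMI is modeled as normal and obesity as the upper
#' tail above the threshold (30 kg/m^2 by the pragmatic survey definition).
#' In scenario runs the stated obesity-prevalence endpoints are consumed
#' directly; this module is an exploratory utility and consistency checker
#' for the printed (BMI shift, endpoint) pairs.
#'
#' @param mean,sd mean and standard deviation of BMI (kg/m^2), `sd > 0`
#' @param threshold obesity threshold (kg/m^2), default 30
#' @return object of class `bmi_distribution`
#' @export
bmi_distribution <- function(mean, sd, threshold = 30) {
  if (!is.finite(sd) || sd <= 0) stop_field("sd", "must be positive")
  if (!is.finite(threshold) || threshold <= 0)
    stop_field("threshold", "must be positive")
  structure(list(mean = mean, sd = sd, threshold = threshold),
            class = "bmi_distribution")
}

#' Obesity prevalence of a BMI distribution
#' @param dist a [bmi_distribution()]
#' @return upper-tail probability above the threshold
#' @export
bmi_obesity_prevalence <- function(dist) {
  pnorm(dist$threshold, dist$mean, dist$sd, lower.tail = FALSE)
}

#' Obesity prevalence after a mean-BMI shift
#'
#' A fraction of the population shifts its BMI down by `delta`; the rest is
#' unchanged. The result is the mixture of the two tails, decreasing in
#' both `delta` and `applied_fraction`.
#'
#' @param dist a [bmi_distribution()]
#' @param delta mean-BMI reduction (kg/m^2), `>= 0`
#' @param applied_fraction fraction of the population shifted, in `[0, 1]`
#' @return obesity prevalence after the shift
#' @export
bmi_prevalence_after_shift <- function(dist, delta, applied_fraction = 1) {
  if (delta < 0) stop_field("delta", "must be non-negative")
  check_fraction(applied_fraction, "applied_fraction")
  shifted <- bmi_distribution(dist$mean - delta, dist$sd, dist$threshold)
  applied_fraction * bmi_obesity_prevalence(shifted) +
    (1 - applied_fraction) * bmi_obesity_prevalence(dist)
}

#' Standard deviation implied by a (shift, prevalence) pair
#'
#' Inverse problem: the normal sd under which a mean-BMI reduction `delta`
#' (applied to `applied_fraction` of the population) moves obesity
#' prevalence from `p0` to `p1`. Solved by bisection on sd in
#' [0.5, 50] kg/m^2. Lets the stated endpoint pairs be audited for mutual
#' consistency under a single distribution-shift model.
#'
#' @param p0,p1 obesity prevalence before/after, `0 < p1 < p0 < 1`
#' @param delta mean-BMI reduction (kg/m^2), `> 0`
#' @param applied_fraction fraction shifted
#' @return implied sd (kg/m^2)
#' @export
bmi_implied_sd <- function(p0, p1, delta, applied_fraction = 1) {
  check_fraction(p0, "p0"); check_fraction(p1, "p1")
  if (p1 >= p0) stop_field("p1", "must be strictly below p0")
  if (delta <= 0) stop_field("delta", "must be positive")
  gap <- function(sd) {
    mean <- 30 - stats::qnorm(p0, lower.tail = FALSE) * sd
    bmi_prevalence_after_shift(bmi_distribution(mean, sd), delta,
                               applied_fraction) - p1
  }
  lo <- 0.5; hi <- 50
  glo <- gap(lo); ghi <- gap(hi)
  if (sign(glo) == sign(ghi))
    stop("no implied sd in [0.5, 50] kg/m^2 for this pair", call. = FALSE)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    g <- gap(mid)
    if (abs(g) < 1e-12 || (hi - lo) < 1e-10) break
    if (sign(g) == sign(glo)) { lo <- mid; glo <- g } else hi <- mid
  }
  (lo + hi) / 2
}

#' Consistency audit of the scenario library's BMI/obesity endpoint pairs
#'
#' For every scenario that states both a mean-BMI reduction and an obesity
#' prevalence endpoint, computes the normal-model sd implied by the pair
#' (starting prevalence 53.3%). Mutually consistent pairs imply similar sd
#' values; the spread is the audit's verdict and is reported, not asserted.
#'
#' @param library a [scenario_library()]
#' @param p0 baseline obesity prevalence the endpoints are stated against
#' @param applied_fraction fraction of the scoped population the BMI shift
#'   applies to (1 reproduces a population-wide shift reading)
#' @return data frame: scenario id, delta, endpoint, implied sd
#' @export
audit_bmi_endpoints <- function(library = scenario_library(), p0 = 0.533,
                                applied_fraction = 1) {
  rows <- list()
  for (sp in library) {
    if (is.na(sp$bmi_shift_info) || is.null(sp$obesity_prev_target)) next
    sd <- tryCatch(bmi_implied_sd(p0, sp$obesity_prev_target,
                                  sp$bmi_shift_info, applied_fraction),
                   error = function(e) NA_real_)
    rows[[length(rows) + 1L]] <- data.frame(
      id = sp$id, bmi_shift = sp$bmi_shift_info,
      endpoint = sp$obesity_prev_target, scope = sp$obesity_scope,
      implied_sd = sd, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
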