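#' Initial model state from a targets table
#'
#' Builds the population lattice at a calendar year from a
#' `calibration_targets` table: counts by sex x age band x risk profile x
#' T2DM status x coverage class (everyone starts uncovered), plus the
#' cumulative-incidence accumulator (zeroed).
#'
#' Within each (sex, band) cell the three risk factors are combined under
#' independence from their marginal prevalences. Diabetics are allocated
#' across profiles proportionally to exposure-weighted risk: per-profile
#' prevalence `min(1, theta * RRprod)` with `theta` solved so the cell's
#' aggregate T2DM prevalence is matched exactly.
#'
#' @param targets `calibration_targets`
#' @param params `nh_params` (supplies the relative risks for allocation)
#' @param year calendar year to initialize at (default: earliest in table)
#' @param n_scenarios number of intervention scenarios the state must carry
#'   coverage classes for (coverage dimension has `2^n_scenarios` classes)
#' @return object of class `model_state`: list with `counts`
#'   (array `[sex, band, profile, status, class]`), `cum_inc`
#'   (array `[sex, band]`), and `year`
#' @export
initial_state <- function(targets, params, year = min(targets$year),
                          n_scenarios = 0L) {
  validate_targets(targets)
  d <- targets[targets$year == year, ]
  if (nrow(d) == 0L) stop("year ", year, " not present in targets", call. = FALSE)
  C <- 2L^n_scenarios
  dims <- c(2L, N_BANDS, 8L, 2L, C)
  counts <- array(0, dims,
                  dimnames = list(sex = SEXES, band = NULL,
                                  profile = rownames(PROFILE_FLAGS),
                                  status = c("susceptible", "diabetic"),
                                  class = NULL))
  rrp <- rr_products(params)
  for (i in seq_len(nrow(d))) {
    s <- match(d$sex[i], SEXES)
    b <- d$age_band[i]
    mix <- profile_mix(d$obesity_prev[i], d$inactivity_prev[i], d$smoking_prev[i])
    pT <- d$t2dm_prev[i]
    # theta s.t. sum_p mix_p * min(1, theta * rrp_p) = pT
    f <- function(th) sum(mix * pmin(1, th * rrp)) - pT
    theta <- if (pT <= 0) 0 else uniroot(f, c(0, 1), extendInt = "upX", tol = 1e-12)$root
    p_prof <- pmin(1, theta * rrp)
    counts[s, b, , 2L, 1L] <- d$population[i] * mix * p_prof
    counts[s, b, , 1L, 1L] <- d$population[i] * mix * (1 - p_prof)
  }
  structure(list(counts = counts,
                 cum_inc = array(0, c(2L, N_BANDS),
                                 dimnames = list(sex = SEXES, band = NULL)),
                 flows = c(entry = 0, deaths = 0, aged_out = 0),
                 year = year),
            class = "model_state")
}

state_dims <- function(state) dim(state$counts)

state_to_vector <- function(state)
  c(as.vector(state$counts), as.vector(state$cum_inc),
    state$flows %||% c(0, 0, 0))

vector_to_state <- function(y, dims, year) {
  n <- prod(dims)
  structure(list(counts = array(y[seq_len(n)], dims),
                 cum_inc = array(y[n + seq_len(2L * N_BANDS)], c(2L, N_BANDS)),
                 flows = setNames(y[n + 2L * N_BANDS + 1:3],
                                  c("entry", "deaths", "aged_out")),
                 year = year),
            class = "model_state")
}

check_state <- function(state) {
  x <- state$counts
  if (any(!is.finite(x))) stop("non-finite count in model state", call. = FALSE)
  tot <- sum(x)
  if (any(x < -1e-9 * tot))
    stop("negative count in model state", call. = FALSE)
  invisible(state)
}

#' @export
print.model_state <- function(x, ...) {
  tot <- sum(x$counts)
  dia <- sum(x$counts[, , , 2L, ])
  cat(sprintf("<model_state> year %s: %.0f persons, %.0f diabetic (%.1f%%)\n",
              x$year, tot, dia, 100 * dia / tot))
  invisible(x)
}
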