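#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' @importFrom stats pnorm setNames uniroot integrate
#' @importFrom utils read.csv write.csv modifyList
NULL

stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

check_fraction <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    stop_field(field, "must be a single number in [0, 1]")
  invisible(x)
}

check_positive <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_field(field, "must be a single positive number")
  invisible(x)
}

# sexes and risk-profile lattice used throughout -------------------------------

SEXES <- c("female", "male")
N_BANDS <- 20L
BAND_WIDTH <- 3
AGE_MIN <- 20

# profile index p = 1 + obese + 2*inactive + 4*smoker
PROFILE_FLAGS <- local({
  m <- as.matrix(expand.grid(obese = 0:1, inactive = 0:1, smoker = 0:1))
  storage.mode(m) <- "double"
  rownames(m) <- apply(m, 1L, function(r) {
    lab <- c("O", "I", "S")[r == 1]
    if (length(lab) == 0) "none" else paste(lab, collapse = "")
  })
  m
})

#' Midpoint ages of the twenty 3-year age bands (20-79)
#' @return numeric vector of length 20
#' @export
band_midpoints <- function() AGE_MIN + BAND_WIDTH * (seq_len(N_BANDS) - 1L) + BAND_WIDTH / 2

#' Lower age of each band
#' @keywords internal
band_lower <- function() AGE_MIN + BAND_WIDTH * (seq_len(N_BANDS) - 1L)

#' First band whose lower bound is at least `age`
#' @keywords internal
band_at_or_above <- function(age) which(band_lower() >= age)[1]
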