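# Internal helpers shared across modules.

#' Stop with a classed input error
#'
#' All user-input validation failures raise condition class
#' "ribotrace_input_error" so callers and tests can distinguish bad input
#' from programming errors.
#' @noRd
stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("ribotrace_input_error", "error")))
}

assert_that <- function(ok, ...) {
  if (!isTRUE(ok)) stop_input(...)
  invisible(TRUE)
}

#' Derive a deterministic child seed from a global seed and a stage name
#'
#' Sub-generators never share a random stream: each stage hashes its name
#' into an offset so that adding or reordering stages does not perturb the
#' draws of the others. Result always fits a 32-bit integer.
#' @noRd
child_seed <- function(seed, stage) {
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes)) %% 99991L
  as.integer((abs(as.integer(seed)) %% 1000003L) * 2017L + h * 13L)
}

#' Multiplicative log-normal noise factors with unit mean and given CV
#' @noRd
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Population standard deviation (divisor n, not n - 1)
#' @noRd
sd_pop <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

#' Round half away from zero (base round() rounds half to even)
#' @noRd
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}
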