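#' @useDynLib reefdiv, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median optim quantile rbinom rexp rgamma rlnorm rnbinom
#'   rnorm runif rpois density acf setNames aggregate complete.cases lm sd
#'   predict coef dexp
#' @importFrom utils read.delim write.table head modifyList
NULL

#' Derive a child seed from a master seed and a stage label
#'
#' All randomness in the package flows from one master seed. Each pipeline
#' stage (and each replicate within a stage) draws its own child seed
#' through this deterministic hash, so stages can be re-run independently
#' yet reproducibly.
#'
#' @param seed Integer master seed.
#' @param label Character stage label (e.g. `"treesim"`, `"mcmc:3"`).
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(label))
  h <- as.numeric(seed) %% 2147483647
  for (ch in utf8ToInt(label)) {
    h <- (h * 131 + ch) %% 2147483647
  }
  as.integer(h + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_reefdiv <- function(fmt, ..., class = "reefdiv_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

## effective sample size from the empirical autocorrelation function,
## truncated at the first non-positive lag (initial positive sequence)
ess <- function(x) {
  n <- length(x)
  if (n < 4 || stats::sd(x) == 0) return(NA_real_)
  rho <- stats::acf(x, lag.max = min(n - 2, 1000), plot = FALSE)$acf[-1]
  pos <- which(rho <= 0)
  if (length(pos)) rho <- rho[seq_len(pos[1] - 1)]
  n / (1 + 2 * sum(rho))
}

## mode of a continuous sample via kernel density maximum
density_mode <- function(x) {
  if (length(unique(x)) == 1) return(x[1])
  d <- stats::density(x)
  d$x[which.max(d$y)]
}
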