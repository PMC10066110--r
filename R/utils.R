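#' @keywords internal
"_PACKAGE"

#' @useDynLib vamorph, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats integrate quantile pchisq pnorm pt qbeta
#'   qwilcox rnorm runif qnorm median sd setNames cor p.adjust
#' @importFrom utils head tail write.csv read.csv
NULL

# Derive a stream-specific 32-bit seed from a master seed. Keeps derived
# seeds in [1, 2^31 - 2] so set.seed() never sees an overflowing value.
derive_seed <- function(master, stream) {
  m <- 2147483647
  x <- (as.double(master) %% m)
  for (k in seq_len(2L)) x <- (x * 48271 + as.double(stream) * 1103 + 12345) %% m
  as.integer(max(1, x))
}

stop_vamorph <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "vamorph_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop_vamorph("cannot normalize a zero vector", class = "vamorph_geometry_error")
  v / n
}
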