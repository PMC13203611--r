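#' @useDynLib sonolite, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm rexp fft setNames aggregate t.test
#' @importFrom utils head tail
NULL

sigmoid <- function(x) 1 / (1 + exp(-x))
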