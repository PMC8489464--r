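#' @useDynLib cardiomark, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif sd setNames
#' @importFrom utils read.csv write.csv
NULL

.onLoad <- function(libname, pkgname) {
  # Many small GEMMs: multithreaded BLAS oversubscribes constrained
  # machines and makes reduction order nondeterministic.
  .set_blas_threads_cpp(1L)
  invisible()
}
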