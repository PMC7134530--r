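#' @useDynLib mvttseg, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats rnorm runif sd var cor kmeans setNames
#' @importFrom utils packageVersion write.csv
NULL
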