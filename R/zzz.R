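#' @importFrom stats rnorm runif rbinom
#' @importFrom utils head tail read.csv write.csv packageVersion
#' @importFrom tools md5sum
NULL
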