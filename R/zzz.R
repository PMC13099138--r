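#' @importFrom stats rnorm runif sd cor aggregate setNames predict glm
#'   binomial
#' @importFrom utils read.csv write.csv read.delim write.table head
#'   modifyList
NULL
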