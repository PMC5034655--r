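#' @importFrom igraph graph_from_adjacency_matrix distances transitivity
#' @importFrom jsonlite toJSON write_json
#' @importFrom yaml read_yaml
#' @importFrom stats dist rnorm runif sd setNames
#' @importFrom utils read.table write.table head tail
NULL
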