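#' Bundled frontal-limbic subnetwork worked example
#'
#' A published frontal-limbic subnetwork in which reduced neonatal structural
#' connectivity was associated with higher toddler externalizing scores:
#' 20 parcellation regions with their core/periphery labels and 25 edges with
#' the t statistics at the primary threshold. Shipped as plain-text tables so
#' the core/feeder/peripheral edge-typing rule ([classify_edges()]) can be
#' exercised on real reported structure without any cohort data.
#'
#' @return List with `nodes` (node table including `partition_label`) and
#'   `edges` (data.frame `node_a`, `node_b`, `t_stat`).
#' @examples
#' ex <- frontal_limbic_example()
#' classify_edges(ex$edges, ex$nodes)$counts
#' @export
frontal_limbic_example <- function() {
  nodes <- read_node_table(system.file("extdata", "frontal_limbic_nodes.tsv",
                                       package = "neoconn", mustWork = TRUE))
  edges <- utils::read.table(
    system.file("extdata", "frontal_limbic_edges.tsv", package = "neoconn",
                mustWork = TRUE),
    sep = "\t", header = TRUE, stringsAsFactors = FALSE, check.names = FALSE)
  list(nodes = nodes, edges = edges)
}
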