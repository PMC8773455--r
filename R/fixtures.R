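#' Load the packaged mini motif tree
#'
#' A synthetic stand-in for a PhyloTree-style haplogroup tree: it covers
#' the 18 macro-haplogroups and the named lineages discussed in the
#' package vignette (HV13b1, U5b1c2, the H1 sub-clades, the traced
#' western-Eurasian lineages), with synthetic branch motifs consistent
#' with the packaged synthetic reference. Real analyses should supply a
#' full tree file in the same dialect.
#'
#' @return a [load_motif_tree()] tree.
#' @export
load_packaged_tree <- function() {
  load_motif_tree(system.file("extdata", "minitree_subset_synthetic.tsv",
                              package = "mtlineage", mustWork = TRUE))
}

#' Load the packaged synthetic ancient-mitogenome table
#'
#' The table realizes [default_ancient_scenario()]: a synthetic narrative
#' fixture, not real archaeological data.
#'
#' @return data frame as from [read_ancient_table()].
#' @export
load_packaged_ancient <- function() {
  read_ancient_table(system.file("extdata", "ancient_records_synthetic.tsv",
                                 package = "mtlineage", mustWork = TRUE))
}
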