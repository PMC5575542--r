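# Shared in-code fixtures.

aln_from_strings <- function(...) {
  s <- c(...)
  protein_alignment(s)
}

# A fixed 4-leaf tree with assorted branch lengths.
tree4 <- function() {
  tr <- ape::read.tree(text = "((A:0.12,B:0.30):0.21,(C:0.08,D:0.45):0.17);")
  paleoenrich:::ensure_node_labels(tr)
}

tree3 <- function() {
  tr <- ape::read.tree(text = "((A:0.2,B:0.35):0.15,C:0.4);")
  paleoenrich:::ensure_node_labels(tr)
}

random_pattern_tree <- function(n_leaves, seed) {
  gen_tree(n_leaves, "yule", 0.3, seed = seed)
}
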