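# Small deterministic fixtures built in code.

cherry <- function() parse_newick("(a:1,b:1);")

# every rooted binary shape for 2-5 tips (one labelling each), ultrametric
tree_shapes <- function() {
  lapply(c(
    "(a:1,b:1);",
    "((a:1,b:1):1,c:2);",
    "((a:1,b:1):1,(c:1,d:1):1);",
    "(((a:1,b:1):1,c:2):1,d:3);",
    "((((a:1,b:1):1,c:2):1,d:3):1,e:4);",
    "(((a:1,b:1):1,(c:1,d:1):1):1,e:3);",
    "((a:1,b:1):2,((c:1,d:1):1,e:2):1);"
  ), parse_newick)
}

# random allowed tip ranges for a tree under an area set
random_tips <- function(tree, aset, widespread = FALSE) {
  ranges <- enumerate_ranges(aset)
  if (!widespread) ranges <- aset$areas
  tip_areas(setNames(sample(ranges, ape::Ntip(tree), replace = TRUE),
                     tree$tip.label), aset)
}

aset3 <- function() area_set(c("A", "B", "C"), adjacency = "full")
aset2 <- function() area_set(c("A", "B"), adjacency = "full")
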