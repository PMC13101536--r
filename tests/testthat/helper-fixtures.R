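# Small in-code fixtures shared across tests.

# 3 samples x 4 OTUs, small integers
tiny_table <- function() {
  m <- matrix(c(5, 0, 2, 1,
                3, 4, 0, 2,
                0, 6, 1, 3), nrow = 3, byrow = TRUE)
  dimnames(m) <- list(paste0("S", 1:3), paste0("OTU_", 1:4))
  m
}

# the worked 3-tip example tree: ((A:1,B:1):1,C:2);
example_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

# metadata frame for n samples with all required columns
tiny_metadata <- function(n = 3, categories = NULL) {
  if (is.null(categories)) categories <- rep("urban", n)
  data.frame(sample_id = paste0("S", seq_len(n)), category = categories,
             distance_km = seq(0, 10, length.out = n),
             SOM = 20, AP = 12, SMC = 15, AK = 100, pH = 7.5, TN = 1.2,
             Cd = 0.1, Zn = 80, Fe = 30000, Cu = 25, Pb = 30,
             stringsAsFactors = FALSE)
}

# naive patristic distance by explicit root-path traversal, independent of
# cophenetic(): d(i,j) = depth(i) + depth(j) - 2 * depth(mrca)
naive_patristic <- function(tree) {
  ntip <- length(tree$tip.label)
  parent <- integer(max(tree$edge)); elen <- numeric(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  path_to_root <- function(node) {
    path <- node
    while (node != root) { node <- parent[node]; path <- c(path, node) }
    path
  }
  depth <- function(node) {
    d <- 0
    while (node != root) { d <- d + elen[node]; node <- parent[node] }
    d
  }
  D <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip)) for (j in seq_len(ntip)) {
    if (i >= j) next
    anc <- intersect(path_to_root(i), path_to_root(j))[1]
    D[i, j] <- D[j, i] <- depth(i) + depth(j) - 2 * depth(anc)
  }
  D
}
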