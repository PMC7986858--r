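# Shared fixtures and independent oracles, built in code at test time.

balanced4 <- function() read_newick(text = "((A:1,B:1):1,(C:1,D:1):1);")
caterpillar3 <- function() read_newick(text = "((A:1,B:1):1,C:2);")
balanced8 <- function() {
  read_newick(text = paste0(
    "(((A:1,B:1):1,(C:1,D:1):1):1,",
    "((E:1,F:1):1,(G:1,H:1):1):1);"
  ))
}

small_scenario <- function(seed = 1L, ...) {
  archipelago_scenario(n_rows = 5L, n_cols = 10L, G = 24L, seed = seed, ...)
}

# Independent spanning-branch oracle: for each edge, the tips below its
# child come from phangorn::Descendants (a different code path from the
# package's own postorder accumulation).
oracle_branch_set <- function(tree, taxa) {
  tips <- match(taxa, tree$tip.label)
  vapply(seq_len(nrow(tree$edge)), function(e) {
    below <- phangorn::Descendants(tree, tree$edge[e, 2L], "tips")[[1L]]
    any(tips %in% below)
  }, logical(1L))
}

oracle_unifrac <- function(tree, set_a, set_b) {
  on_a <- oracle_branch_set(tree, set_a)
  on_b <- oracle_branch_set(tree, set_b)
  len <- tree$edge.length
  sum(len[xor(on_a, on_b)]) / sum(len[on_a | on_b])
}

oracle_pd <- function(tree, taxa) {
  sum(tree$edge.length[oracle_branch_set(tree, taxa)])
}

# Exact richness-matched null moments by subset enumeration (small trees).
oracle_standardized_pd <- function(tree, taxa) {
  ntip <- length(tree$tip.label)
  subs <- utils::combn(tree$tip.label, length(taxa))
  pds <- apply(subs, 2L, function(s) oracle_pd(tree, s))
  (oracle_pd(tree, taxa) - mean(pds)) / stats::sd(pds)
}

# All permutations of 1..n as a list (independent of package internals).
combinat_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in combinat_perms(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

random_ultrametric_tree <- function(ntip, seed) {
  set.seed(seed)
  tr <- ape::rphylo(ntip, birth = 0.2, death = 0)
  tr$tip.label <- paste0("t", seq_len(ntip))
  tr
}
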