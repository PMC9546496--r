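# Shared fixtures and independent oracles, built in code.

# straight south-to-north unit river at lon 0, min age 2.4 Ma
straight_river <- function(name = "R", min_age = 2.4) {
  river_barrier(name, cbind(c(0, 0), c(0, 1)), min_age)
}

# caterpillar tree with 3 well-separated species of n samples each:
# between-species edges long (1/lambda_sp), within short
three_species_tree <- function(within = 0.01, between = 1) {
  txt <- sprintf(
    "(((a1:%g,a2:%g):%g,(b1:%g,b2:%g):%g):%g,(c1:%g,c2:%g):%g);",
    within, within, between, within, within, between, between,
    within, within, between)
  parse_newick(txt)
}

# independent HPD oracle: brute force over all contiguous sorted windows
hpd_brute <- function(samples, level = 0.95) {
  x <- sort(samples)
  n <- length(x)
  k <- ceiling(level * n)
  best <- c(x[1], x[n])
  for (i in seq_len(n - k + 1)) {
    lo <- x[i]; hi <- x[i + k - 1]
    if ((hi - lo) < (best[2] - best[1]) - 1e-15) best <- c(lo, hi)
  }
  best
}

# independent divergence oracle: check every internal node directly
enumerate_divergences_brute <- function(tree, lin) {
  n_tip <- ape::Ntip(tree)
  out <- integer(0)
  for (v in (n_tip + 1):(n_tip + tree$Nnode)) {
    ch <- tree$edge[tree$edge[, 1] == v, 2]
    la <- unique(lin[clade_tips(tree, ch[1])])
    lb <- unique(lin[clade_tips(tree, ch[2])])
    if (!length(intersect(la, lb))) out <- c(out, v)
  }
  out
}

# random binary tree with two-regime branch lengths and planted partition
random_planted_tree <- function(n_species, samples_each, ratio, seed,
                                birth = 0.5) {
  sp <- simulate_species_tree(n_species, birth, 0, seed = seed)
  graft_coalescent_samples(sp, samples_each, lambda_speciation = 1,
                           lambda_coalescent_mean = ratio,
                           lambda_coalescent_spread = 0.25,
                           seed = seed + 10000L)
}

# independent planted-congruence count: a divergence node is river-congruent
# iff all planted banks on one side face all those on the other
planted_congruent_count <- function(sc) {
  lin <- lineage_map(sc$truth)
  plan <- sc$bank_plan
  tr <- sc$dated_tree
  n_tip <- ape::Ntip(tr)
  k <- 0
  for (v in (n_tip + 1):(n_tip + tr$Nnode)) {
    ch <- tr$edge[tr$edge[, 1] == v, 2]
    la <- unique(lin[clade_tips(tr, ch[1])])
    lb <- unique(lin[clade_tips(tr, ch[2])])
    if (length(intersect(la, lb))) next
    ba <- unique(plan[la]); bb <- unique(plan[lb])
    if (length(ba) == 1 && length(bb) == 1 && ba != bb) k <- k + 1
  }
  k
}
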