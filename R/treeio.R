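#' @importFrom ape read.tree write.tree read.nexus write.nexus getMRCA
#'   node.depth.edgelength drop.tip multi2di rphylo Ntip Nnode keep.tip
#'   is.binary
#' @importFrom stats rexp rlnorm rnorm runif setNames
#' @importFrom utils read.delim write.table head tail
NULL

# Trees are represented as ape "phylo" objects throughout: tips are nodes
# 1..Ntip, the root is Ntip+1, edge.length holds branch lengths (expected
# substitutions per site for ML trees, Ma for dated trees -- the package never
# guesses units; each stage documents which kind it needs).

#' Parse a Newick string into a phylo tree
#'
#' Branch lengths are optional and default to 0. Polytomies are preserved
#' as-is; stages that require binary trees say so and
#' [resolve_polytomies()] can be used first.
#'
#' @param text a Newick string (must end in `;`).
#' @return an object of class `phylo`.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
#' ape::Ntip(tr)
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  .check_parens(text)
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("malformed Newick string (could not be parsed)")
  if (is.null(tr$edge.length)) tr$edge.length <- rep(0, nrow(tr$edge))
  if (anyNA(tr$edge.length)) tr$edge.length[is.na(tr$edge.length)] <- 0
  if (any(tr$edge.length < 0)) stop("negative branch lengths are not allowed")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  tr
}

# Balanced-parenthesis precheck so parse errors can name a character offset.
.check_parens <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("unbalanced ')' at character offset ", i)
    }
  }
  if (depth != 0L)
    stop("unclosed '(' (", depth, " open) by character offset ",
         length(chars))
  invisible(TRUE)
}

#' Serialize a phylo tree to a Newick string
#'
#' Branch lengths are written with 10 significant digits so that
#' `parse_newick(write_newick(tree))` round-trips topology and lengths.
#'
#' @param tree a `phylo` object.
#' @return a single Newick string terminated by `;`.
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, digits = 10)
}

#' Read a posterior sample of dated trees from a NEXUS file
#'
#' Reads a NEXUS TREES block (translate table, quoted labels and
#' square-bracket comments -- including sampler-style metadata comments --
#' are tolerated; comments are discarded), checks that all trees share one
#' tip set, and removes `floor(burnin_fraction * N)` initial trees.
#'
#' @param file path to a NEXUS file, or (if `text` given) ignored.
#' @param burnin_fraction fraction in `[0, 1)` of initial trees to discard.
#' @param text optional NEXUS content as a character string, used instead of
#'   `file`.
#' @return an object of class `posterior_trees`: a list with elements
#'   `trees` (a `multiPhylo`), `tip_labels`, `burnin_fraction`,
#'   `n_total`, `n_retained`.
#' @export
parse_nexus_trees <- function(file = NULL, burnin_fraction = 0, text = NULL) {
  stopifnot(is.numeric(burnin_fraction), burnin_fraction >= 0,
            burnin_fraction < 1)
  if (!is.null(text)) {
    file <- tempfile(fileext = ".nex")
    on.exit(unlink(file))
    writeLines(text, file)
  }
  trees <- ape::read.nexus(file)
  if (inherits(trees, "phylo")) trees <- c(trees)  # promote to multiPhylo
  n_total <- length(trees)
  if (n_total == 0L) stop("no trees found in NEXUS file")
  ref <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees)) {
    if (!identical(sort(trees[[i]]$tip.label), ref))
      stop("tree ", i, " has a tip set different from tree 1")
    if (is.null(trees[[i]]$edge.length))
      trees[[i]]$edge.length <- rep(0, nrow(trees[[i]]$edge))
  }
  n_drop <- floor(burnin_fraction * n_total)
  if (n_drop >= n_total) stop("burnin removes every tree")
  kept <- trees[(n_drop + 1L):n_total]
  class(kept) <- "multiPhylo"
  structure(list(trees = kept, tip_labels = ref,
                 burnin_fraction = burnin_fraction,
                 n_total = n_total, n_retained = length(kept)),
            class = "posterior_trees")
}

#' @export
print.posterior_trees <- function(x, ...) {
  cat("posterior_trees:", x$n_retained, "trees retained of", x$n_total,
      sprintf("(burnin %.3g),", x$burnin_fraction),
      length(x$tip_labels), "tips\n")
  invisible(x)
}

#' Write a posterior tree set (or list of trees) to NEXUS
#'
#' @param x a `posterior_trees` object or `multiPhylo`.
#' @param file output path.
#' @export
write_nexus_trees <- function(x, file) {
  trees <- if (inherits(x, "posterior_trees")) x$trees else x
  ape::write.nexus(trees, file = file, translate = TRUE)
  invisible(file)
}

.check_tips <- function(tree, tips) {
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown))
    stop("unknown tip label(s): ", paste(unknown, collapse = ", "))
  invisible(TRUE)
}

#' Most recent common ancestor of a set of tips
#'
#' The MRCA of a single tip is the tip itself.
#'
#' @param tree a `phylo` object.
#' @param tips character vector of tip labels (non-empty).
#' @return the ape node id of the MRCA.
#' @export
mrca_node <- function(tree, tips) {
  stopifnot(inherits(tree, "phylo"), length(tips) >= 1L)
  tips <- unique(tips)
  .check_tips(tree, tips)
  if (length(tips) == 1L) return(match(tips, tree$tip.label))
  ape::getMRCA(tree, tips)
}

#' Tip labels descending from a node
#'
#' @param tree a `phylo` object.
#' @param node an ape node id (a tip id returns that tip's label).
#' @return character vector of descendant tip labels.
#' @export
clade_tips <- function(tree, node) {
  n_tip <- ape::Ntip(tree)
  if (node <= n_tip) return(tree$tip.label[node])
  kids <- .children_list(tree)
  # iterative DFS over internal nodes
  stack <- node
  out <- integer(0)
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    ch <- kids[[v]]
    tips_ch <- ch[ch <= n_tip]
    out <- c(out, tips_ch)
    stack <- c(stack, ch[ch > n_tip])
  }
  tree$tip.label[out]
}

# children of every node as a list indexed by node id
.children_list <- function(tree) {
  n_node <- ape::Ntip(tree) + tree$Nnode
  kids <- vector("list", n_node)
  for (i in seq_len(nrow(tree$edge)))
    kids[[tree$edge[i, 1]]] <- c(kids[[tree$edge[i, 1]]], tree$edge[i, 2])
  kids
}

#' Is a tip set monophyletic?
#'
#' TRUE iff the descendant tip set of the MRCA equals `tips` exactly. A
#' single tip is trivially monophyletic.
#'
#' @inheritParams mrca_node
#' @return logical.
#' @export
is_clade <- function(tree, tips) {
  tips <- unique(tips)
  .check_tips(tree, tips)
  if (length(tips) == 1L) return(TRUE)
  m <- mrca_node(tree, tips)
  setequal(clade_tips(tree, m), tips)
}

#' Age of a node in a dated (ultrametric) tree
#'
#' The tree must be ultrametric within `tolerance` (all root-to-tip path
#' sums within `tolerance * max_path` of each other); dated trees from MCMC
#' samplers carry floating-point jitter, hence the tolerance. The age of a
#' node is the mean over its descendant tips of the node-to-tip path
#' length; tips have age 0.
#'
#' @param tree a dated `phylo` object (branch lengths in Ma).
#' @param node ape node id.
#' @param tolerance relative ultrametricity tolerance (default `1e-4`).
#' @return age in Ma.
#' @export
node_age <- function(tree, node, tolerance = 1e-4) {
  depths <- ape::node.depth.edgelength(tree)
  n_tip <- ape::Ntip(tree)
  tip_paths <- depths[seq_len(n_tip)]
  dev <- (max(tip_paths) - min(tip_paths)) / max(max(tip_paths), .Machine$double.eps)
  if (dev > tolerance)
    stop(sprintf(
      "tree is not ultrametric: max relative tip-path deviation %.3g > tolerance %.3g",
      dev, tolerance))
  if (node <= n_tip) return(0)
  desc <- match(clade_tips(tree, node), tree$tip.label)
  mean(depths[desc]) - depths[node]
}

# Ages of all nodes at once (no per-node tolerance recheck); used by the
# chronology and synthetic modules where the same tree is queried repeatedly.
.node_ages_all <- function(tree) {
  depths <- ape::node.depth.edgelength(tree)
  max(depths[seq_len(ape::Ntip(tree))]) - depths
}

#' Resolve polytomies into a binary tree
#'
#' Arbitrary (seeded) resolution with zero-length branches; logs the number
#' of resolved nodes via `message()`.
#'
#' @param tree a `phylo` object.
#' @param seed integer seed controlling the arbitrary resolution order.
#' @return a binary `phylo` object.
#' @export
resolve_polytomies <- function(tree, seed = 1L) {
  if (ape::is.binary(tree)) return(tree)
  n_before <- tree$Nnode
  set.seed(as.integer(seed))
  out <- ape::multi2di(tree, random = TRUE)
  message("resolved polytomies: ", out$Nnode - n_before,
          " node(s) added with zero-length branches (seed ", seed, ")")
  out
}
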