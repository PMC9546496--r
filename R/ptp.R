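# Poisson Tree Processes (PTP) lineage delimitation.
#
# Model: every edge of a rooted binary ML tree belongs either to the
# between-lineage ("speciation") process or to the within-lineage
# ("coalescent") process of exactly one lineage. Edge lengths within a class
# are i.i.d. exponential. At the per-class maximum-likelihood rate
# lambda_hat = n / sum(b), a class with n edges of total length S contributes
#   n * log(n / S) - n
# to the log-likelihood, so the objective is a function of the partition
# alone (profile likelihood). Single-rate mode pools all coalescent edges
# into one class; multi-rate mode gives each lineage its own class.
#
# A delimitation is represented by its set of "lineage roots": an antichain
# of nodes covering all tips. Edges whose parent lies inside a lineage-root
# subtree are coalescent; all other edges (including the edge subtending
# each lineage root) are speciation. The speciation edges thus form a
# connected subgraph containing the root, and the one-lineage null (lineage
# root = tree root) has an empty speciation class.

.ptp_class_term <- function(n, S) {
  out <- numeric(length(n))
  ok <- n > 0 & S > 0
  out[ok] <- n[ok] * log(n[ok] / S[ok]) - n[ok]
  out
}

# Per-node subtree statistics under a minimum-branch-length filter.
# Returns, for each node v: n_sub / s_sub = count and length-sum of included
# edges strictly inside v's subtree (i.e. edges whose parent is in clade(v)),
# plus inclusion flag and length of v's own parent edge.
.ptp_stats <- function(tree, min_branch_length = 0) {
  n_tip <- ape::Ntip(tree)
  n_node <- n_tip + tree$Nnode
  parent_len <- rep(NA_real_, n_node)
  parent_len[tree$edge[, 2]] <- tree$edge.length
  incl <- !is.na(parent_len) & parent_len >= min_branch_length
  kids <- matrix(0L, n_node, 2)
  slot <- integer(n_node)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]
    slot[p] <- slot[p] + 1L
    if (slot[p] > 2L) stop("tree must be binary for PTP delimitation")
    kids[p, slot[p]] <- tree$edge[i, 2]
  }
  # postorder accumulation of subtree sums
  po <- .postorder_nodes(tree)
  n_sub <- numeric(n_node)
  s_sub <- numeric(n_node)
  for (v in po) {
    if (kids[v, 1] == 0L) next  # tip
    for (c in kids[v, 1:2]) {
      n_sub[v] <- n_sub[v] + n_sub[c] + as.numeric(incl[c])
      s_sub[v] <- s_sub[v] + s_sub[c] + if (incl[c]) parent_len[c] else 0
    }
  }
  list(n_tip = n_tip, n_node = n_node, root = n_tip + 1L, kids = kids,
       parent = .parent_vec(tree), incl = incl, parent_len = parent_len,
       n_sub = n_sub, s_sub = s_sub,
       n_tot = sum(incl), s_tot = sum(parent_len[incl]))
}

.parent_vec <- function(tree) {
  n_node <- ape::Ntip(tree) + tree$Nnode
  par <- rep(0L, n_node)
  par[tree$edge[, 2]] <- tree$edge[, 1]
  par
}

# preorder DFS from the root, reversed: children always precede parents
.postorder_nodes <- function(tree) {
  n_tip <- ape::Ntip(tree)
  kids <- .children_list(tree)
  stack <- n_tip + 1L
  order <- integer(0)
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    order <- c(order, v)
    if (v > n_tip) stack <- c(stack, kids[[v]])
  }
  rev(order)
}

# log-likelihood of a delimitation given lineage roots, from precomputed stats
.ptp_loglik_roots <- function(st, roots, mode) {
  n_coal <- st$n_sub[roots]
  s_coal <- st$s_sub[roots]
  n_sp <- st$n_tot - sum(n_coal)
  s_sp <- st$s_tot - sum(s_coal)
  sp_term <- .ptp_class_term(n_sp, s_sp)
  coal_term <- if (mode == "multi") sum(.ptp_class_term(n_coal, s_coal))
  else .ptp_class_term(sum(n_coal), sum(s_coal))
  degenerate <- (n_sp > 0 && s_sp <= 0) ||
    (mode == "multi" && any(n_coal > 0 & s_coal <= 0)) ||
    (mode == "single" && sum(n_coal) > 0 && sum(s_coal) <= 0)
  list(loglik = sp_term + coal_term, degenerate = degenerate)
}

.ptp_rates <- function(st, roots, mode) {
  n_coal <- st$n_sub[roots]
  s_coal <- st$s_sub[roots]
  n_sp <- st$n_tot - sum(n_coal)
  s_sp <- st$s_tot - sum(s_coal)
  sp_rate <- if (n_sp > 0 && s_sp > 0) n_sp / s_sp else NA_real_
  coal <- if (mode == "multi") {
    ifelse(n_coal > 0 & s_coal > 0, n_coal / s_coal, NA_real_)
  } else {
    if (sum(n_coal) > 0 && sum(s_coal) > 0) sum(n_coal) / sum(s_coal) else NA_real_
  }
  list(speciation_rate = sp_rate, coalescent_rates = coal)
}

.ptp_build <- function(tree, st, roots, mode, min_branch_length) {
  roots <- sort(roots)
  ll <- .ptp_loglik_roots(st, roots, mode)
  lineages <- lapply(roots, function(v) sort(clade_tips(tree, v)))
  names(lineages) <- paste0("L", seq_along(lineages))
  rates <- .ptp_rates(st, roots, mode)
  structure(list(lineages = lineages, lineage_roots = roots,
                 n_lineages = length(roots), mode = mode,
                 min_branch_length = min_branch_length,
                 speciation_rate = rates$speciation_rate,
                 coalescent_rates = rates$coalescent_rates,
                 log_likelihood = ll$loglik, degenerate = ll$degenerate),
            class = "ptp_delimitation")
}

#' @export
print.ptp_delimitation <- function(x, ...) {
  cat("PTP delimitation (", x$mode, "-rate): ", x$n_lineages,
      " lineage(s), logL = ", format(x$log_likelihood, digits = 7), "\n",
      sep = "")
  if (isTRUE(x$degenerate))
    cat("  [degenerate: a non-empty class had zero total length]\n")
  invisible(x)
}

#' Tip-to-lineage map of a delimitation
#'
#' @param delim a `ptp_delimitation` (or any list with a `lineages` element,
#'   e.g. the planted truth from the synthetic generators).
#' @return named character vector: tip label -> lineage id.
#' @export
lineage_map <- function(delim) {
  unlist(lapply(names(delim$lineages), function(nm)
    setNames(rep(nm, length(delim$lineages[[nm]])), delim$lineages[[nm]])))
}

#' PTP log-likelihood of a given delimitation
#'
#' Edges shorter than `min_branch_length` are excluded from every class
#' before computing (but retained in the topology). A class with edges but
#' zero total length is degenerate: it contributes 0 and the result carries
#' a `degenerate` attribute.
#'
#' @param tree a binary `phylo` object (an ML tree).
#' @param lineages list of character vectors partitioning the tip labels, or
#'   a `ptp_delimitation`. Each lineage must be monophyletic.
#' @param mode `"single"` (one pooled coalescent rate) or `"multi"` (one
#'   rate per lineage).
#' @param min_branch_length noise floor; edges below it are ignored.
#' @return log-likelihood (natural log), with attribute `degenerate`.
#' @export
ptp_loglik <- function(tree, lineages, mode = c("multi", "single"),
                       min_branch_length = 0) {
  mode <- match.arg(mode)
  if (inherits(lineages, "ptp_delimitation")) lineages <- lineages$lineages
  all_tips <- sort(unlist(lineages, use.names = FALSE))
  if (!identical(all_tips, sort(tree$tip.label)))
    stop("lineages must partition the tree's tip set exactly")
  roots <- vapply(lineages, function(tp) mrca_node(tree, tp), integer(1))
  for (i in seq_along(lineages))
    if (!setequal(clade_tips(tree, roots[i]), lineages[[i]]))
      stop("lineage ", i, " is not monophyletic in the tree")
  st <- .ptp_stats(tree, min_branch_length)
  ll <- .ptp_loglik_roots(st, roots, mode)
  structure(ll$loglik, degenerate = ll$degenerate)
}

# canonical string for tie-breaking: lineages sorted internally and by first tip
.partition_key <- function(tree, roots) {
  parts <- lapply(roots, function(v) sort(clade_tips(tree, v)))
  parts <- parts[order(vapply(parts, `[`, "", 1L))]
  paste(vapply(parts, paste, "", collapse = ","), collapse = "|")
}

# candidate comparison: higher logL, then fewer lineages, then lexicographic key
.better_than <- function(cand, best) {
  if (is.null(best)) return(TRUE)
  if (cand$loglik != best$loglik) return(cand$loglik > best$loglik)
  if (length(cand$roots) != length(best$roots))
    return(length(cand$roots) < length(best$roots))
  cand$key < best$key
}

#' Exhaustive PTP delimitation (oracle for small trees)
#'
#' Enumerates every valid set of lineage roots (every antichain covering the
#' tips) and returns the maximum-likelihood delimitation. Ties are broken
#' toward fewer lineages, then the lexicographically smallest partition.
#'
#' @inheritParams ptp_loglik
#' @param max_exhaustive_tips refuse larger trees (default 12).
#' @return a `ptp_delimitation`.
#' @export
delimit_exhaustive <- function(tree, mode = c("multi", "single"),
                               min_branch_length = 0,
                               max_exhaustive_tips = 12L) {
  mode <- match.arg(mode)
  if (ape::Ntip(tree) > max_exhaustive_tips)
    stop("tree has ", ape::Ntip(tree), " tips > max_exhaustive_tips (",
         max_exhaustive_tips, "); use delimit_search()")
  st <- .ptp_stats(tree, min_branch_length)
  antichains <- .enumerate_antichains(st, st$root)
  best <- NULL
  for (roots in antichains) {
    ll <- .ptp_loglik_roots(st, roots, mode)
    cand <- list(loglik = ll$loglik, roots = roots,
                 key = .partition_key(tree, roots))
    if (.better_than(cand, best)) best <- cand
  }
  .ptp_build(tree, st, best$roots, mode, min_branch_length)
}

# all antichains covering the tips of the subtree at v:
# either {v}, or a cross product of the children's antichains
.enumerate_antichains <- function(st, v) {
  if (st$kids[v, 1] == 0L) return(list(v))
  left <- .enumerate_antichains(st, st$kids[v, 1])
  right <- .enumerate_antichains(st, st$kids[v, 2])
  out <- vector("list", 1L + length(left) * length(right))
  out[[1L]] <- v
  k <- 1L
  for (a in left) for (b in right) {
    k <- k + 1L
    out[[k]] <- c(a, b)
  }
  out
}

#' Heuristic PTP delimitation by seeded multi-restart hill-climbing
#'
#' Moves are: split a lineage at its root node into its two child subtrees,
#' or merge two sibling lineage roots into their parent. Restarts include
#' the one-lineage null and the all-tips-split states plus seeded random
#' antichains; each restart climbs to a local optimum by best-improvement.
#' Deterministic given `seed`. On small trees this matches
#' [delimit_exhaustive()] (a tested contract, not an a-priori theorem).
#'
#' @inheritParams ptp_loglik
#' @param seed integer seed.
#' @param restarts number of random restarts in addition to the two
#'   deterministic starts (default 10).
#' @return a `ptp_delimitation`; attribute `n_restarts_at_best` reports how
#'   many restarts reached the returned log-likelihood.
#' @export
delimit_search <- function(tree, mode = c("multi", "single"),
                           min_branch_length = 0, seed = 1L, restarts = 10L) {
  mode <- match.arg(mode)
  if (!ape::is.binary(tree))
    stop("delimit_search requires a binary tree; see resolve_polytomies()")
  st <- .ptp_stats(tree, min_branch_length)
  set.seed(as.integer(seed))
  starts <- c(list(st$root, seq_len(st$n_tip)),
              lapply(seq_len(max(0L, restarts)), function(i)
                .random_antichain(st)))
  best <- NULL
  n_at_best <- 0L
  for (s in starts) {
    res <- .hill_climb(st, s, mode)
    cand <- list(loglik = res$loglik, roots = res$roots,
                 key = .partition_key(tree, res$roots))
    if (!is.null(best) && cand$loglik == best$loglik) n_at_best <- n_at_best + 1L
    if (.better_than(cand, best)) {
      if (is.null(best) || cand$loglik > best$loglik) n_at_best <- 1L
      best <- cand
    }
  }
  out <- .ptp_build(tree, st, best$roots, mode, min_branch_length)
  attr(out, "n_restarts_at_best") <- n_at_best
  out
}

# random antichain: descend from the root, stopping at each node with p=0.5
.random_antichain <- function(st) {
  roots <- integer(0)
  stack <- st$root
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (st$kids[v, 1] == 0L || stats::runif(1) < 0.5) {
      roots <- c(roots, v)
    } else {
      stack <- c(stack, st$kids[v, 1:2])
    }
  }
  sort(roots)
}

# Best-improvement hill climb over split/merge moves. Neighbor log-likelihoods
# are evaluated with O(1) class-sum updates, vectorized over all candidate
# moves, so one iteration costs O(k) for k current lineages.
.hill_climb <- function(st, roots, mode) {
  roots <- sort(roots)
  repeat {
    n_coal <- st$n_sub[roots]
    s_coal <- st$s_sub[roots]
    Ns <- sum(n_coal); Ss <- sum(s_coal)
    n_sp <- st$n_tot - Ns; s_sp <- st$s_tot - Ss
    cur_terms <- .ptp_class_term(n_coal, s_coal)
    cur_ll <- .ptp_class_term(n_sp, s_sp) +
      if (mode == "multi") sum(cur_terms) else .ptp_class_term(Ns, Ss)

    best_ll <- cur_ll
    best_roots <- NULL

    # split moves: internal lineage roots only
    splittable <- which(st$kids[roots, 1] != 0L)
    if (length(splittable)) {
      v <- roots[splittable]
      c1 <- st$kids[v, 1]; c2 <- st$kids[v, 2]
      # edges c1,c2 leave the coalescent class of v
      dn <- as.numeric(st$incl[c1]) + as.numeric(st$incl[c2])
      ds <- ifelse(st$incl[c1], st$parent_len[c1], 0) +
        ifelse(st$incl[c2], st$parent_len[c2], 0)
      sp_new <- .ptp_class_term(n_sp + dn, s_sp + ds)
      coal_new <- if (mode == "multi") {
        sum(cur_terms) - cur_terms[splittable] +
          .ptp_class_term(st$n_sub[c1], st$s_sub[c1]) +
          .ptp_class_term(st$n_sub[c2], st$s_sub[c2])
      } else {
        .ptp_class_term(Ns - dn, Ss - ds)
      }
      ll_split <- sp_new + coal_new
      i <- which.max(ll_split)
      if (ll_split[i] > best_ll + 1e-12) {
        best_ll <- ll_split[i]
        best_roots <- sort(c(roots[-splittable[i]], c1[i], c2[i]))
      }
    }

    # merge moves: sibling pairs both currently lineage roots
    if (length(roots) > 1L) {
      par <- st$parent[roots]
      dup <- par[duplicated(par)]
      for (p in unique(dup)) {
        pair_idx <- which(par == p)
        c1 <- roots[pair_idx[1]]; c2 <- roots[pair_idx[2]]
        dn <- as.numeric(st$incl[c1]) + as.numeric(st$incl[c2])
        ds <- ifelse(st$incl[c1], st$parent_len[c1], 0) +
          ifelse(st$incl[c2], st$parent_len[c2], 0)
        sp_new <- .ptp_class_term(n_sp - dn, s_sp - ds)
        coal_new <- if (mode == "multi") {
          sum(cur_terms) - sum(cur_terms[pair_idx]) +
            .ptp_class_term(st$n_sub[p], st$s_sub[p])
        } else {
          .ptp_class_term(Ns + dn, Ss + ds)
        }
        ll_merge <- sp_new + coal_new
        if (ll_merge > best_ll + 1e-12) {
          best_ll <- ll_merge
          best_roots <- sort(c(roots[-pair_idx], p))
        }
      }
    }

    if (is.null(best_roots)) return(list(roots = roots, loglik = cur_ll))
    roots <- best_roots
  }
}

#' Crop an outgroup from a tree
#'
#' Removes the outgroup tips, suppresses resulting degree-2 nodes (branch
#' lengths summed), and returns the subtree induced on the remaining tips.
#' A non-monophyletic outgroup triggers a warning and each outgroup tip is
#' cropped individually.
#'
#' @param tree a `phylo` object.
#' @param outgroup character vector of outgroup tip labels (may be empty; a
#'   proper subset of the tips leaving at least 2).
#' @return a `phylo` object.
#' @export
crop_outgroup <- function(tree, outgroup) {
  if (length(outgroup) == 0L) return(tree)
  .check_tips(tree, outgroup)
  if (length(tree$tip.label) - length(outgroup) < 2L)
    stop("cropping would leave fewer than 2 tips")
  if (length(outgroup) > 1L && !is_clade(tree, outgroup))
    warning("outgroup is not monophyletic; cropping each tip individually")
  ape::drop.tip(tree, outgroup, collapse.singles = TRUE)
}

#' Minimum branch length from an alignment length
#'
#' One substitution across the alignment, `1 / alignment_length`: the floor
#' below which ML branch lengths are treated as numerical noise.
#'
#' @param alignment_length number of sites (> 0).
#' @return the minimum branch length.
#' @export
auto_min_branch_length <- function(alignment_length) {
  stopifnot(is.numeric(alignment_length), alignment_length > 0)
  1 / alignment_length
}
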