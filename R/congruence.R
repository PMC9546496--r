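# Spatial congruence of between-lineage divergences with river barriers
# (condition 1 of the riverine barrier test): a divergence is congruent
# with a river when its two descendant clades hold disjoint lineage sets
# and all determinate bank assignments on one side face all those on the
# other.

#' Enumerate between-lineage divergences
#'
#' Internal nodes of the scope-restricted tree whose two children contain
#' disjoint lineage sets (no single lineage spans the node), ordered by
#' node age descending. On a binary tree where each of the k lineages in
#' scope is monophyletic this yields exactly k - 1 nodes.
#'
#' @param tree a dated binary `phylo` object.
#' @param lineages a tip -> lineage-id named character vector (see
#'   [lineage_map()]), or a `ptp_delimitation`.
#' @param scope character vector of tip labels to restrict to (default all
#'   tips). The tree is pruned to `scope` before enumeration; returned node
#'   ids refer to the original tree (the MRCA of the scoped clade tips).
#' @return a list of divergence records: `node_id`, `age`,
#'   `child_A_tips`, `child_B_tips`, `lineages_A`, `lineages_B`.
#' @export
enumerate_lineage_divergences <- function(tree, lineages, scope = NULL) {
  lin <- if (inherits(lineages, "ptp_delimitation")) lineage_map(lineages)
  else lineages
  if (is.null(scope)) scope <- tree$tip.label
  .check_tips(tree, scope)
  miss <- setdiff(scope, names(lin))
  if (length(miss))
    stop("no lineage assignment for tip(s): ", paste(miss, collapse = ", "))
  sub <- if (setequal(scope, tree$tip.label)) tree
  else ape::keep.tip(tree, scope)
  n_tip <- ape::Ntip(sub)
  kids <- .children_list(sub)
  ages <- .node_ages_all(sub)
  recs <- list()
  for (v in (n_tip + 1L):(n_tip + sub$Nnode)) {
    ch <- kids[[v]]
    if (length(ch) != 2L) stop("tree must be binary within scope")
    a_tips <- clade_tips(sub, ch[1])
    b_tips <- clade_tips(sub, ch[2])
    lin_a <- unique(lin[a_tips])
    lin_b <- unique(lin[b_tips])
    if (length(intersect(lin_a, lin_b)) == 0L) {
      recs[[length(recs) + 1L]] <- list(
        node_id = mrca_node(tree, c(a_tips, b_tips)),
        age = ages[v],
        child_A_tips = sort(a_tips), child_B_tips = sort(b_tips),
        lineages_A = sort(lin_a), lineages_B = sort(lin_b))
    }
  }
  if (!length(recs)) {
    message("no between-lineage divergences found in scope")
    return(list())
  }
  recs[order(vapply(recs, `[[`, 0, "age"), decreasing = TRUE)]
}

#' Classify a divergence as spatially congruent with a river
#'
#' `congruent` iff each child clade's determinate banks are unanimous, the
#' two sides differ, and each side has at least `min_determinate_per_side`
#' determinate tips; `unevaluable` if either side has fewer determinate
#' tips than that; `incongruent` otherwise. Indeterminate-bank tips are
#' treated as missing data. Verdicts based on a single determinate sample
#' on a side are flagged `low_support`.
#'
#' @param record a divergence record from
#'   [enumerate_lineage_divergences()].
#' @param bank_table a bank table from [assign_banks_table()].
#' @param river a `river_barrier` (or river name string).
#' @param min_determinate_per_side minimum determinate tips per side
#'   (default 1, accepting single-sample sides).
#' @return the record extended with `river_name`, `spatial_verdict`,
#'   `n_det_A`, `n_det_B`, `low_support`.
#' @export
classify_spatial_congruence <- function(record, bank_table, river,
                                        min_determinate_per_side = 1L) {
  rname <- if (inherits(river, "river_barrier")) river$name else river
  bt <- bank_table[bank_table$river_name == rname, , drop = FALSE]
  banks <- setNames(bt$bank, bt$sample_id)
  side <- function(tips) {
    b <- banks[intersect(tips, names(banks))]
    b[!is.na(b) & b %in% c("left", "right")]
  }
  a <- side(record$child_A_tips)
  b <- side(record$child_B_tips)
  verdict <- if (length(a) < min_determinate_per_side ||
                 length(b) < min_determinate_per_side) {
    "unevaluable"
  } else if (length(unique(a)) == 1L && length(unique(b)) == 1L &&
             a[1] != b[1]) {
    "congruent"
  } else {
    "incongruent"
  }
  record$river_name <- rname
  record$spatial_verdict <- verdict
  record$n_det_A <- length(a)
  record$n_det_B <- length(b)
  record$low_support <- verdict == "congruent" && min(length(a), length(b)) == 1L
  record
}

#' Lineages found on both sides of a river
#'
#' Flags every lineage with at least one determinate tip on each bank:
#' direct evidence that the river is not a barrier for that lineage.
#'
#' @param lineages tip -> lineage-id named vector or `ptp_delimitation`.
#' @inheritParams classify_spatial_congruence
#' @return character vector of flagged lineage ids (possibly empty).
#' @export
find_barrier_violations <- function(lineages, bank_table, river) {
  lin <- if (inherits(lineages, "ptp_delimitation")) lineage_map(lineages)
  else lineages
  rname <- if (inherits(river, "river_barrier")) river$name else river
  bt <- bank_table[bank_table$river_name == rname &
                     bank_table$bank %in% c("left", "right"), , drop = FALSE]
  banks <- setNames(bt$bank, bt$sample_id)
  flagged <- character(0)
  for (lid in unique(lin)) {
    tips <- names(lin)[lin == lid]
    b <- unique(banks[intersect(tips, names(banks))])
    if (all(c("left", "right") %in% b)) flagged <- c(flagged, lid)
  }
  sort(flagged)
}

#' Summarize spatial-congruence records
#'
#' Per-river congruent / evaluable counts plus the overall divergence
#' total. A divergence counts once per river for which it is evaluable;
#' `n_total_divergences` counts every enumerated divergence once,
#' independent of river evaluability.
#'
#' @param records list of classified records (possibly several rivers per
#'   divergence node).
#' @param rivers list of `river_barrier` objects (for river ordering; may
#'   be empty).
#' @return list with `n_total_divergences`, `per_river` data frame
#'   (`river_name`, `n_congruent`, `n_incongruent`, `n_unevaluable`,
#'   `n_evaluated`), and `n_congruent_any` (divergences congruent for at
#'   least one river).
#' @export
summarize_congruence <- function(records, rivers = list()) {
  if (inherits(rivers, "river_barrier")) rivers <- list(rivers)
  node_ids <- unique(vapply(records, `[[`, 0, "node_id"))
  rnames <- if (length(rivers)) vapply(rivers, `[[`, "", "name")
  else unique(vapply(records, function(r) r$river_name %||% NA_character_,
                     ""))
  rnames <- rnames[!is.na(rnames)]
  per_river <- do.call(rbind, lapply(rnames, function(rn) {
    rr <- Filter(function(r) identical(r$river_name, rn), records)
    v <- vapply(rr, `[[`, "", "spatial_verdict")
    data.frame(river_name = rn,
               n_congruent = sum(v == "congruent"),
               n_incongruent = sum(v == "incongruent"),
               n_unevaluable = sum(v == "unevaluable"),
               n_evaluated = sum(v != "unevaluable"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(per_river))
    per_river <- data.frame(river_name = character(), n_congruent = integer(),
                            n_incongruent = integer(),
                            n_unevaluable = integer(),
                            n_evaluated = integer(), stringsAsFactors = FALSE)
  cong_nodes <- unique(vapply(
    Filter(function(r) identical(r$spatial_verdict, "congruent"), records),
    `[[`, 0, "node_id"))
  list(n_total_divergences = length(node_ids), per_river = per_river,
       n_congruent_any = length(cong_nodes))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
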