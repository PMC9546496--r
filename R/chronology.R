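# Divergence chronology (condition 2 of the riverine barrier test):
# node-age posteriors, highest-posterior-density intervals, synchrony of
# divergences across the same river, and temporal congruence against
# geological river-formation ages.

#' Node ages of a clade across a posterior tree set
#'
#' For every post-burnin tree the age of `mrca(clade_tips)` is recorded,
#' whether or not the clade is monophyletic in that tree; the fraction of
#' trees in which it is monophyletic is reported alongside, exposing
#' topological instability without discarding trees.
#'
#' @param posterior a `posterior_trees` object (trees in Ma).
#' @param clade_tips character vector of tip labels.
#' @param level HPD level (default 0.95).
#' @return an `age_posterior` object: `clade_tips`, `samples` (one age per
#'   tree), `monophyly_fraction`, `hpd_low`, `hpd_high`, `level`.
#' @export
mrca_ages_posterior <- function(posterior, clade_tips, level = 0.95) {
  stopifnot(inherits(posterior, "posterior_trees"))
  trees <- posterior$trees
  if (!length(trees)) stop("empty posterior")
  clade_tips <- unique(clade_tips)
  unknown <- setdiff(clade_tips, posterior$tip_labels)
  if (length(unknown))
    stop("unknown tip label(s): ", paste(unknown, collapse = ", "))
  k <- length(clade_tips)
  ages <- numeric(length(trees))
  mono <- logical(length(trees))
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    idx <- match(clade_tips, tr$tip.label)
    if (k == 1L) {
      ages[i] <- 0
      mono[i] <- TRUE
      next
    }
    m <- ape::getMRCA(tr, idx)
    depths <- ape::node.depth.edgelength(tr)
    n_tip <- length(tr$tip.label)
    desc <- match(clade_tips(tr, m), tr$tip.label)
    ages[i] <- mean(depths[desc]) - depths[m]
    mono[i] <- length(desc) == k
  }
  hp <- hpd(ages, level)
  structure(list(clade_tips = sort(clade_tips), samples = ages,
                 monophyly_fraction = mean(mono),
                 hpd_low = hp[1], hpd_high = hp[2], level = level),
            class = "age_posterior")
}

#' @export
print.age_posterior <- function(x, ...) {
  cat("age_posterior for {", paste(x$clade_tips, collapse = ", "), "}: ",
      length(x$samples), " samples, ", sprintf("%.0f%%", 100 * x$level),
      " HPD [", format(x$hpd_low, digits = 4), ", ",
      format(x$hpd_high, digits = 4), "] Ma, monophyly ",
      sprintf("%.2f", x$monophyly_fraction), "\n", sep = "")
  invisible(x)
}

#' Highest posterior density interval
#'
#' The shortest contiguous window over the sorted samples containing
#' `ceiling(level * n)` points. Width ties are broken toward the earliest
#' (smallest lower bound) window, for determinism.
#'
#' @param samples numeric vector (non-empty).
#' @param level fraction in (0, 1].
#' @return numeric `c(low, high)`.
#' @export
hpd <- function(samples, level = 0.95) {
  stopifnot(length(samples) >= 1L, level > 0, level <= 1)
  x <- sort(samples)
  n <- length(x)
  k <- ceiling(level * n)
  if (k >= n) return(c(x[1], x[n]))
  lows <- x[seq_len(n - k + 1L)]
  highs <- x[k:n]
  i <- which.min(highs - lows)  # which.min takes the first (earliest) tie
  c(lows[i], highs[i])
}

#' Do two closed intervals overlap?
#'
#' Touching intervals count as overlapping: HPDs are continuous summaries
#' and measure-zero distinctions are noise.
#'
#' @param a,b numeric `c(low, high)` with `low <= high`.
#' @return logical.
#' @export
intervals_overlap <- function(a, b) {
  stopifnot(a[1] <= a[2], b[1] <= b[2])
  a[1] <= b[2] && b[1] <= a[2]
}

#' Group intervals into synchrony groups
#'
#' Connected components of the pairwise-overlap graph, each annotated with
#' whether it is a clique (all members mutually overlap — the stricter
#' statement of synchrony) or merely chained together.
#'
#' @param intervals named list of numeric `c(low, high)` intervals, or a
#'   two-column matrix with rownames.
#' @return list of groups, each a list with `members` (names) and `clique`
#'   (logical). Groups are disjoint and cover the input.
#' @export
synchrony_groups <- function(intervals) {
  if (is.matrix(intervals))
    intervals <- setNames(lapply(seq_len(nrow(intervals)),
                                 function(i) intervals[i, ]),
                          rownames(intervals))
  n <- length(intervals)
  stopifnot(n >= 1L)
  nms <- names(intervals)
  if (is.null(nms)) nms <- paste0("interval_", seq_len(n))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    adj[i, j] <- intervals_overlap(intervals[[i]], intervals[[j]])
  comp <- rep(0L, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  lapply(seq_len(cid), function(g) {
    mem <- which(comp == g)
    list(members = nms[mem],
         clique = all(adj[mem, mem, drop = FALSE]))
  })
}

#' Temporal congruence of a divergence with a river's formation age
#'
#' Default rule `"not_postdate"`: congruent iff `hpd_high >= min_age_ma` —
#' the divergence is not demonstrably younger than the river (the
#' condition is phrased negatively: timing must not postdate river
#' formation). The boundary is inclusive. The optional strict rule
#' `"strictly_older"` requires `hpd_low >= min_age_ma` (the entire HPD
#' predates river formation).
#'
#' @param interval numeric `c(hpd_low, hpd_high)` in Ma.
#' @param river a `river_barrier` with `min_age_ma` set.
#' @param rule `"not_postdate"` (default) or `"strictly_older"`.
#' @return list with `river_name`, `congruent`, `rule`.
#' @export
temporal_congruence <- function(interval, river,
                                rule = c("not_postdate", "strictly_older")) {
  rule <- match.arg(rule)
  stopifnot(inherits(river, "river_barrier"), is.finite(river$min_age_ma))
  congruent <- if (rule == "not_postdate") interval[2] >= river$min_age_ma
  else interval[1] >= river$min_age_ma
  list(river_name = river$name, congruent = congruent, rule = rule)
}

#' Mean of an offset-exponential calibration prior
#'
#' For a fossil calibration with a hard minimum (`offset`) and a soft
#' maximum, the exponential mean that places `max_age` at the given
#' quantile is `(max_age - offset) / (-log(1 - quantile))`.
#'
#' @param offset minimum age (Ma), the distribution's offset.
#' @param max_age age (Ma) to place at `quantile`; must exceed `offset`.
#' @param quantile fraction in (0, 1), default 0.95.
#' @return the exponential mean in Ma.
#' @examples
#' exp_calibration_mean(55.935, 66.1)  # ~3.393 Ma
#' @export
exp_calibration_mean <- function(offset, max_age, quantile = 0.95) {
  stopifnot(quantile > 0, quantile < 1)
  if (max_age <= offset) stop("max_age must exceed offset")
  (max_age - offset) / (-log(1 - quantile))
}
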