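# Seeded synthetic-data generators mirroring the statistical structure the
# analysis assumes: dated birth-death species trees, two-regime
# branch-length trees with a planted delimitation, planted river
# geography, and pseudo-posterior dated tree sets. All generators are
# reproducible bitwise per seed.

#' Simulate a dated species tree
#'
#' Constant-rate birth-death tree conditioned on `n_species` surviving
#' tips, branch lengths in Ma.
#'
#' @param n_species number of extant tips (>= 2).
#' @param birth_rate,death_rate events per Ma; `death_rate < birth_rate`.
#' @param seed integer seed.
#' @return an ultrametric `phylo` with tips `sp1..spN`.
#' @export
simulate_species_tree <- function(n_species, birth_rate = 1,
                                  death_rate = 0, seed = 1L) {
  stopifnot(n_species >= 2, birth_rate > 0, death_rate >= 0,
            death_rate < birth_rate)
  set.seed(as.integer(seed))
  tr <- ape::rphylo(n_species, birth = birth_rate, death = death_rate,
                    fossils = FALSE)
  tr$tip.label <- paste0("sp", seq_len(n_species))
  tr
}

#' Graft coalescent sample subtrees onto a species tree
#'
#' Replaces the species tree's branch lengths with draws from the
#' between-lineage regime `Exp(lambda_speciation)` and each species tip
#' with a random sample subtree (sequential pairwise joins) whose edges are
#' drawn from that species' within-lineage regime `Exp(lambda_coalescent_i)`.
#' Per-species coalescent rates are drawn lognormally around
#' `lambda_coalescent_mean` with coefficient of variation
#' `lambda_coalescent_spread` (0 gives identical rates). The result is the
#' kind of two-regime ML tree the PTP model assumes, with the true
#' delimitation known.
#'
#' @param species_tree a `phylo` (only its topology is used).
#' @param samples_per_species single integer or length-2 range
#'   `c(min, max)` sampled uniformly per species.
#' @param lambda_speciation between-lineage exponential rate.
#' @param lambda_coalescent_mean mean within-lineage rate (typically >>
#'   `lambda_speciation`: within-species branches are shorter).
#' @param lambda_coalescent_spread coefficient of variation of per-species
#'   rates (default 0.25).
#' @param seed integer seed.
#' @return list with `tree` (binary `phylo`, tips `sp<i>_s<j>`), `truth`
#'   (list with `lineages`, a tip partition named by species), and
#'   `lambda_coalescent` (per-species rates).
#' @export
graft_coalescent_samples <- function(species_tree, samples_per_species = 5L,
                                     lambda_speciation = 1,
                                     lambda_coalescent_mean = 20,
                                     lambda_coalescent_spread = 0.25,
                                     seed = 1L) {
  stopifnot(lambda_speciation > 0, lambda_coalescent_mean > 0,
            lambda_coalescent_spread >= 0)
  set.seed(as.integer(seed))
  sp <- species_tree$tip.label
  n_sp <- length(sp)
  m <- if (length(samples_per_species) == 2L)
    sample(samples_per_species[1]:samples_per_species[2], n_sp, replace = TRUE)
  else rep(as.integer(samples_per_species), n_sp)
  lam <- if (lambda_coalescent_spread > 0) {
    sdlog <- sqrt(log(1 + lambda_coalescent_spread^2))
    stats::rlnorm(n_sp, log(lambda_coalescent_mean) - sdlog^2 / 2, sdlog)
  } else rep(lambda_coalescent_mean, n_sp)

  # random sequential pairwise joins -> Newick fragment for one species
  join_subtree <- function(labels, rate) {
    frags <- labels
    while (length(frags) > 1L) {
      pick <- sample(length(frags), 2L)
      b <- stats::rexp(2L, rate)
      merged <- sprintf("(%s:%.10g,%s:%.10g)", frags[pick[1]], b[1],
                        frags[pick[2]], b[2])
      frags <- c(frags[-pick], merged)
    }
    frags
  }

  # build Newick bottom-up on the species-tree topology with Exp(lambda_sp)
  # internal/pendant speciation edges
  kids <- .children_list(species_tree)
  n_tip <- ape::Ntip(species_tree)
  frag <- character(n_tip + species_tree$Nnode)
  lineages <- vector("list", n_sp)
  names(lineages) <- sp
  for (v in .postorder_nodes(species_tree)) {
    if (v <= n_tip) {
      labs <- sprintf("%s_s%d", sp[v], seq_len(m[v]))
      lineages[[sp[v]]] <- labs
      frag[v] <- if (m[v] == 1L) labs else join_subtree(labs, lam[v])
    } else {
      ch <- kids[[v]]
      parts <- vapply(ch, function(c)
        sprintf("%s:%.10g", frag[c], stats::rexp(1L, lambda_speciation)), "")
      frag[v] <- sprintf("(%s)", paste(parts, collapse = ","))
    }
  }
  tree <- parse_newick(paste0(frag[n_tip + 1L], ";"))
  list(tree = tree,
       truth = list(lineages = lapply(lineages, sort), n_lineages = n_sp),
       lambda_coalescent = setNames(lam, sp))
}

#' Synthetic river geometry
#'
#' A straight meridian polyline by default (runs south to north at
#' `lon0`), or a meandering sine-wave polyline for geometry edge cases.
#'
#' @param name river name.
#' @param min_age_ma,max_age_ma formation-age window (Ma).
#' @param lon0 river longitude (degrees).
#' @param lat_range latitude extent `c(from, to)`, orientation downstream.
#' @param meander_amplitude_deg sine amplitude in degrees longitude (0 =
#'   straight).
#' @param n_vertices vertices along the polyline.
#' @return a `river_barrier`.
#' @export
synthetic_river <- function(name = "SynthRiver", min_age_ma = 2.4,
                            max_age_ma = NA_real_, lon0 = -60,
                            lat_range = c(-6, 2),
                            meander_amplitude_deg = 0, n_vertices = 9L) {
  lat <- seq(lat_range[1], lat_range[2], length.out = n_vertices)
  lon <- lon0 + meander_amplitude_deg *
    sin(2 * pi * seq(0, 1, length.out = n_vertices))
  river_barrier(name, cbind(lon, lat), min_age_ma, max_age_ma)
}

#' Plant sample coordinates on river banks
#'
#' Places every lineage's samples around a centroid on its planned side of
#' the river, jittered by about `spread_km`; a seeded `violation_rate`
#' fraction of samples is reflected to the opposite bank (across the
#' nearest river segment). The planted bank of every sample is recorded so
#' recovery can be checked against truth.
#'
#' @param lineages tip -> lineage named vector, list of tip sets, or
#'   `ptp_delimitation`.
#' @param river a `river_barrier` (use [synthetic_river()] for the default
#'   straight meridian).
#' @param bank_plan named character vector lineage -> `"left"`/`"right"`;
#'   must cover all lineages.
#' @param spread_km within-lineage scatter (s.d. of the jitter), km.
#' @param offset_km distance of lineage centroids from the river, km
#'   (default 100, the order of the real sampling distances from banks).
#' @param violation_rate fraction in `[0, 1]` of samples reflected to the
#'   wrong bank (rounded to a count; seeded choice).
#' @param seed integer seed.
#' @return a `data.frame` with `sample_id`, `taxon` (lineage id),
#'   `latitude`, `longitude`, `planted_bank`.
#' @export
simulate_river_geography <- function(lineages, river, bank_plan,
                                     spread_km = 20, offset_km = 100,
                                     violation_rate = 0, seed = 1L) {
  stopifnot(violation_rate >= 0, violation_rate <= 1)
  lin <- if (inherits(lineages, "ptp_delimitation")) lineage_map(lineages)
  else if (is.list(lineages) && !is.null(lineages$lineages))
    lineage_map(lineages)
  else if (is.list(lineages)) lineage_map(list(lineages = lineages))
  else lineages
  lids <- unique(lin)
  miss <- setdiff(lids, names(bank_plan))
  if (length(miss))
    stop("bank_plan missing lineage(s): ", paste(miss, collapse = ", "))
  set.seed(as.integer(seed))
  co <- river$coords
  lat_mid <- mean(range(co[, 2]))
  rows <- list()
  for (lid in lids) {
    tips <- names(lin)[lin == lid]
    side <- bank_plan[[lid]]
    # centroid: a random point along the river's middle half, offset
    # perpendicular on the planned side
    t0 <- stats::runif(1, 0.25, 0.75)
    base <- .polyline_point(co, t0)
    sgn <- if (side == "left") 1 else -1
    cf <- cos(base[2] * pi / 180)
    perp <- .polyline_normal(co, t0)  # unit left-normal in local plane
    cen_x <- base[1] * cf + sgn * perp[1] * offset_km / .KM_PER_DEG
    cen_y <- base[2] + sgn * perp[2] * offset_km / .KM_PER_DEG
    for (tp in tips) {
      jx <- stats::rnorm(1, 0, spread_km / .KM_PER_DEG)
      jy <- stats::rnorm(1, 0, spread_km / .KM_PER_DEG)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = tp, taxon = lid,
        latitude = cen_y + jy, longitude = (cen_x + jx) / cf,
        planted_bank = side, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  n_viol <- round(violation_rate * nrow(df))
  if (n_viol > 0L) {
    idx <- sample(nrow(df), n_viol)
    for (i in idx) {
      refl <- .reflect_across_river(c(df$longitude[i], df$latitude[i]),
                                    river)
      df$longitude[i] <- refl[1]
      df$latitude[i] <- refl[2]
      df$planted_bank[i] <- if (df$planted_bank[i] == "left") "right"
      else "left"
    }
  }
  rownames(df) <- NULL
  df
}

# point at fractional arc-length t along a polyline (lon/lat, planar approx)
.polyline_point <- function(co, t) {
  seg_len <- sqrt(diff(co[, 1])^2 + diff(co[, 2])^2)
  cum <- c(0, cumsum(seg_len))
  target <- t * cum[length(cum)]
  i <- max(which(cum <= target + 1e-15))
  i <- min(i, nrow(co) - 1L)
  f <- if (seg_len[i] > 0) (target - cum[i]) / seg_len[i] else 0
  c(co[i, 1] + f * (co[i + 1L, 1] - co[i, 1]),
    co[i, 2] + f * (co[i + 1L, 2] - co[i, 2]))
}

# unit left-normal (relative to downstream direction) of the segment at t
.polyline_normal <- function(co, t) {
  seg_len <- sqrt(diff(co[, 1])^2 + diff(co[, 2])^2)
  cum <- c(0, cumsum(seg_len))
  target <- t * cum[length(cum)]
  i <- max(which(cum <= target + 1e-15))
  i <- min(i, nrow(co) - 1L)
  d <- c(co[i + 1L, 1] - co[i, 1], co[i + 1L, 2] - co[i, 2])
  d <- d / sqrt(sum(d^2))
  c(-d[2], d[1])  # rotate +90 degrees: left of downstream
}

# mirror a point across the nearest river segment (local planar metric)
.reflect_across_river <- function(point, river) {
  lon <- point[1]; lat <- point[2]
  cf <- cos(lat * pi / 180)
  px <- lon * cf; py <- lat
  co <- river$coords
  vx <- co[, 1] * cf; vy <- co[, 2]
  best <- list(d2 = Inf)
  for (i in seq_len(nrow(co) - 1L)) {
    ax <- vx[i]; ay <- vy[i]
    dx <- vx[i + 1L] - ax; dy <- vy[i + 1L] - ay
    len2 <- dx * dx + dy * dy
    t_cl <- if (len2 > 0)
      min(1, max(0, ((px - ax) * dx + (py - ay) * dy) / len2)) else 0
    nx <- ax + t_cl * dx; ny <- ay + t_cl * dy
    d2 <- (px - nx)^2 + (py - ny)^2
    if (d2 < best$d2) best <- list(d2 = d2, nx = nx, ny = ny)
  }
  c((2 * best$nx - px) / cf, 2 * best$ny - py)
}

#' Pseudo-posterior tree set by perturbing node ages
#'
#' Each draw rescales every internal-node age of a dated tree with
#' independent multiplicative lognormal noise of mean 1 and coefficient of
#' variation `age_noise_cv`, preserving topology; parent-older-than-child
#' ordering is restored by clamping a child to its parent's age (minus a
#' tiny epsilon) where violated. Tips stay at age 0, so every draw remains
#' ultrametric.
#'
#' @param dated_tree an ultrametric `phylo` in Ma.
#' @param n_draws number of trees to generate (>= 1).
#' @param age_noise_cv coefficient of variation of the noise (0 =
#'   noiseless copies).
#' @param seed integer seed.
#' @return a `posterior_trees` object with `n_draws` trees (burnin 0).
#' @export
perturb_posterior <- function(dated_tree, n_draws = 1000L,
                              age_noise_cv = 0.1, seed = 1L) {
  stopifnot(n_draws >= 1L, age_noise_cv >= 0)
  set.seed(as.integer(seed))
  n_tip <- ape::Ntip(dated_tree)
  n_node <- n_tip + dated_tree$Nnode
  ages0 <- .node_ages_all(dated_tree)
  ages0[seq_len(n_tip)] <- 0
  parent <- .parent_vec(dated_tree)
  # preorder over internals (parents before children) for clamping
  pre <- rev(.postorder_nodes(dated_tree))
  internals <- pre[pre > n_tip]
  edge_child <- dated_tree$edge[, 2]
  edge_parent <- dated_tree$edge[, 1]
  sdlog <- if (age_noise_cv > 0) sqrt(log(1 + age_noise_cv^2)) else 0
  meanlog <- -sdlog^2 / 2
  eps <- 1e-9 * max(ages0)
  trees <- vector("list", n_draws)
  for (d in seq_len(n_draws)) {
    ages <- ages0
    if (sdlog > 0) {
      fac <- stats::rlnorm(length(internals), meanlog, sdlog)
      ages[internals] <- ages0[internals] * fac
      for (v in internals) {
        p <- parent[v]
        if (p != 0L && ages[v] > ages[p] - eps)
          ages[v] <- ages[p] - eps
      }
    }
    tr <- dated_tree
    tr$edge.length <- ages[edge_parent] - ages[edge_child]
    trees[[d]] <- tr
  }
  class(trees) <- "multiPhylo"
  structure(list(trees = trees, tip_labels = sort(dated_tree$tip.label),
                 burnin_fraction = 0, n_total = n_draws,
                 n_retained = n_draws),
            class = "posterior_trees")
}

#' Write a full synthetic scenario to disk
#'
#' Convenience wrapper producing the file kinds the pipeline consumes:
#' `ml.nwk` (two-regime ML tree), `dated.nwk` (species tree in Ma),
#' `posterior.nex` (pseudo-posterior), `samples.tsv`, `rivers.geojson`,
#' `truth.json`.
#'
#' @param outdir output directory (created if needed).
#' @param n_species,samples_per_species,birth_rate,death_rate see the
#'   individual generators.
#' @param lambda_speciation,lambda_coalescent_mean,lambda_coalescent_spread
#'   branch-length regimes for the ML tree.
#' @param violation_rate,spread_km,offset_km geography controls.
#' @param age_noise_cv,n_posterior_draws pseudo-posterior controls.
#' @param river_min_age_ma formation age given to the synthetic river.
#' @param species_tree optional fixed ultrametric species tree (topology
#'   control for planted-congruence scenarios); simulated when NULL.
#' @param bank_plan optional named lineage -> side plan; defaults to
#'   alternating left/right over the species.
#' @param seed integer seed.
#' @return invisibly, a list of the generated objects and file paths.
#' @export
synthesize_scenario <- function(outdir, n_species = 10L,
                                samples_per_species = 5L,
                                birth_rate = 0.3, death_rate = 0,
                                lambda_speciation = 1,
                                lambda_coalescent_mean = 20,
                                lambda_coalescent_spread = 0.25,
                                violation_rate = 0, spread_km = 20,
                                offset_km = 100, age_noise_cv = 0.1,
                                n_posterior_draws = 500L,
                                river_min_age_ma = 2.4,
                                species_tree = NULL, bank_plan = NULL,
                                seed = 1L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  sp_tree <- if (is.null(species_tree))
    simulate_species_tree(n_species, birth_rate, death_rate, seed)
  else species_tree
  gr <- graft_coalescent_samples(sp_tree, samples_per_species,
                                 lambda_speciation, lambda_coalescent_mean,
                                 lambda_coalescent_spread, seed + 1L)
  # dated tree over the samples: species tree with each species' samples
  # attached at age 0 (a star below the species tip would not be binary;
  # instead scale a copy of the ML-tree topology is unnecessary -- the
  # dated tree here is the species tree with one representative per
  # species replaced by the sample clade at small heights)
  dated <- .dated_sample_tree(sp_tree, gr$truth$lineages, seed + 2L)
  river <- synthetic_river(min_age_ma = river_min_age_ma)
  lids <- names(gr$truth$lineages)
  if (is.null(bank_plan))
    bank_plan <- setNames(rep(c("left", "right"), length.out = length(lids)),
                          lids)
  samples <- simulate_river_geography(gr$truth, river, bank_plan, spread_km,
                                      offset_km, violation_rate, seed + 3L)
  post <- perturb_posterior(dated, n_posterior_draws, age_noise_cv,
                            seed + 4L)
  paths <- list(
    ml = file.path(outdir, "ml.nwk"),
    dated = file.path(outdir, "dated.nwk"),
    posterior = file.path(outdir, "posterior.nex"),
    samples = file.path(outdir, "samples.tsv"),
    rivers = file.path(outdir, "rivers.geojson"),
    truth = file.path(outdir, "truth.json"))
  writeLines(write_newick(gr$tree), paths$ml)
  writeLines(write_newick(dated), paths$dated)
  write_nexus_trees(post, paths$posterior)
  utils::write.table(samples, paths$samples, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  writeLines(.river_geojson(river), paths$rivers)
  truth <- list(n_lineages = gr$truth$n_lineages,
                lineages = gr$truth$lineages, bank_plan = as.list(bank_plan),
                violation_rate = violation_rate, seed = seed)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(list(species_tree = sp_tree, ml_tree = gr$tree,
                 dated_tree = dated, truth = gr$truth, river = river,
                 bank_plan = bank_plan, samples = samples, posterior = post,
                 paths = paths))
}

# dated tree over all samples: species-tree ages in Ma for between-species
# nodes, small coalescent heights (uniform in (0, 0.05 * youngest
# species-tree node) ) within species; ultrametric by construction
.dated_sample_tree <- function(sp_tree, lineages, seed = 1L) {
  set.seed(as.integer(seed))
  ages <- .node_ages_all(sp_tree)
  min_internal <- min(ages[ages > 0])
  cap <- 0.05 * min_internal
  kids <- .children_list(sp_tree)
  n_tip <- ape::Ntip(sp_tree)
  frag <- character(n_tip + sp_tree$Nnode)
  height <- numeric(n_tip + sp_tree$Nnode)
  join_dated <- function(labels) {
    frags <- labels
    h <- rep(0, length(labels))
    while (length(frags) > 1L) {
      pick <- sample(length(frags), 2L)
      hn <- stats::runif(1, max(h[pick]), cap)
      merged <- sprintf("(%s:%.10g,%s:%.10g)", frags[pick[1]],
                        hn - h[pick[1]], frags[pick[2]], hn - h[pick[2]])
      frags <- c(frags[-pick], merged)
      h <- c(h[-pick], hn)
    }
    list(frag = frags, h = h)
  }
  for (v in .postorder_nodes(sp_tree)) {
    if (v <= n_tip) {
      labs <- lineages[[sp_tree$tip.label[v]]]
      if (length(labs) == 1L) {
        frag[v] <- labs
        height[v] <- 0
      } else {
        jd <- join_dated(labs)
        frag[v] <- jd$frag
        height[v] <- jd$h
      }
    } else {
      ch <- kids[[v]]
      parts <- vapply(ch, function(c)
        sprintf("%s:%.10g", frag[c], ages[v] - height[c]), "")
      frag[v] <- sprintf("(%s)", paste(parts, collapse = ","))
      height[v] <- ages[v]
    }
  }
  parse_newick(paste0(frag[n_tip + 1L], ";"))
}

.river_geojson <- function(river) {
  feature <- list(type = "Feature",
                  properties = list(name = river$name,
                                    min_age_ma = river$min_age_ma),
                  geometry = list(type = "LineString",
                                  coordinates = lapply(
                                    seq_len(nrow(river$coords)),
                                    function(i) river$coords[i, ])))
  if (is.finite(river$max_age_ma))
    feature$properties$max_age_ma <- river$max_age_ma
  jsonlite::toJSON(list(type = "FeatureCollection", features = list(feature)),
                   auto_unbox = TRUE, digits = NA)
}
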