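#' Build per-site imbalance profiles
#'
#' Turns per-modification binomial results into one signed vector per site:
#' magnitude is -log10 of the binomial p-value (0 when untested, capped for
#' underflow), sign says which allele the modification favors. The
#' reference ("A") allele of each site is the allele favored by the site's
#' most significant modification, so the strongest signal is positive by
#' construction; flipping the reference negates the vector and leaves
#' squared correlations unchanged.
#'
#' @param per_modification Long table from [call_ashm()]
#'   (`site_id`, `modification`, `binomial_p`, `favored_allele`).
#' @param site_ids Sites to include (default: all in the table); rows are
#'   ordered by this argument, giving deterministic tie-breaks downstream.
#' @param modifications Column order (default: the 23-modification panel
#'   restricted to modifications present).
#' @return Numeric matrix sites x modifications with a `ref_allele`
#'   attribute naming each site's reference allele.
#' @export
build_imbalance_profiles <- function(per_modification,
                                     site_ids = NULL,
                                     modifications = NULL) {
  pm <- as.data.table(per_modification)
  if (is.null(site_ids)) site_ids <- unique(pm$site_id)
  if (is.null(modifications)) {
    modifications <- intersect(histone_modifications(),
                               unique(pm$modification))
    if (length(modifications) == 0) {
      modifications <- sort(unique(pm$modification))
    }
  }
  pm <- pm[site_id %chin% site_ids & modification %chin% modifications]
  prof <- matrix(0, length(site_ids), length(modifications),
                 dimnames = list(site_ids, modifications))
  ref <- setNames(rep(NA_character_, length(site_ids)), site_ids)
  for (sid in site_ids) {
    x <- pm[site_id == sid]
    if (nrow(x) == 0) next
    # reference allele: the allele favored by the most significant
    # modification (ties broken by panel order)
    x <- x[order(binomial_p, match(modification, modifications))]
    ref_allele <- x$favored_allele[!is.na(x$favored_allele)][1]
    ref[sid] <- ref_allele
    mag <- -log10(pmax(x$binomial_p, 1e-300))
    sgn <- fifelse(is.na(x$favored_allele), 0,
                   fifelse(x$favored_allele == ref_allele, 1, -1))
    prof[sid, x$modification] <- mag * sgn
  }
  attr(prof, "ref_allele") <- ref
  prof
}

# pairwise 1 - r^2 distance; zero-variance profiles get correlation 0
.profile_distance <- function(profiles) {
  v <- apply(profiles, 1, function(x) stats::sd(x))
  r <- suppressWarnings(cor(t(profiles)))
  r[is.na(r)] <- 0
  if (any(v == 0)) {
    message(sum(v == 0), " constant profile(s): correlations set to 0")
  }
  d <- 1 - r^2
  diag(d) <- 0
  as.dist(d)
}

#' Cluster ASHM sites by their imbalance profiles
#'
#' Agglomerative hierarchical clustering of sites with pairwise
#' dissimilarity `1 - r^2`, where `r` is the Pearson correlation of the
#' signed log-p profiles across modifications. Squaring makes the measure
#' blind to each site's arbitrary reference-allele orientation. Average
#' linkage by default.
#'
#' @param profiles Matrix from [build_imbalance_profiles()].
#' @param linkage Linkage method passed to [stats::hclust()].
#' @return An object of class `hclust`.
#' @export
cluster_sites <- function(profiles, linkage = "average") {
  if (nrow(profiles) < 2) {
    stop("need at least 2 profiles to cluster", call. = FALSE)
  }
  hclust(.profile_distance(profiles), method = linkage)
}

# canonical signed driver pattern, invariant to a global sign flip:
# orientation chosen so the first driver in sorted modification order is +
.canonical_pattern <- function(mods, sides) {
  if (length(mods) == 0) return("")
  o <- order(mods)
  mods <- mods[o]; sides <- sides[o]
  if (sides[1] < 0) sides <- -sides
  paste(paste0(mods, ifelse(sides > 0, "+", "-")), collapse = ",")
}

# driver set of one cluster: sign-align member profiles to the anchor
# (largest absolute entry), then keep modifications significant with a
# consistent side in at least half the member sites
.cluster_drivers <- function(profiles, members, driver_p_threshold) {
  sub <- profiles[members, , drop = FALSE]
  anchor <- which.max(apply(abs(sub), 1, max))
  av <- sub[anchor, ]
  flip <- apply(sub, 1, function(x) {
    s <- suppressWarnings(cor(x, av))
    !is.na(s) && s < 0
  })
  sub[flip, ] <- -sub[flip, , drop = FALSE]
  thr <- -log10(driver_p_threshold)
  n <- nrow(sub)
  hit_pos <- colSums(sub > thr)
  hit_neg <- colSums(sub < -thr)
  mods <- colnames(sub)
  driver_pos <- hit_pos >= n / 2 & hit_pos > hit_neg
  driver_neg <- hit_neg >= n / 2 & hit_neg > hit_pos
  data.table(
    modification = c(mods[driver_pos], mods[driver_neg]),
    side = c(rep(1L, sum(driver_pos)), rep(-1L, sum(driver_neg)))
  )
}

#' Choose the dendrogram cut and identify cluster drivers
#'
#' Progressively lowers the cut (increasing the number of clusters from the
#' top of the dendrogram) until lowering it further would produce multiple
#' clusters driven primarily by the same modification(s). A cluster's
#' drivers are the modifications with binomial p below
#' `driver_p_threshold` on a consistent allele side in at least half of the
#' cluster's sites (profiles are sign-aligned within the cluster first, and
#' driver patterns compared up to a global flip, since the per-site
#' reference allele is arbitrary). If no cut with more than one cluster has
#' pairwise-distinct driver sets, a single cluster is returned with a
#' warning.
#'
#' @param dendrogram `hclust` object from [cluster_sites()].
#' @param profiles The profile matrix the dendrogram was built from.
#' @param driver_p_threshold Binomial-p threshold defining a driver
#'   (default 0.01).
#' @param max_clusters Upper bound on the number of clusters scanned.
#' @return List of class `cluster_result`: `n_clusters`, `labels` (named
#'   integer vector), `drivers` (table `cluster`, `modification`, `side`),
#'   `cut_height`.
#' @export
choose_cut_and_drivers <- function(dendrogram, profiles,
                                   driver_p_threshold = 0.01,
                                   max_clusters = nrow(profiles)) {
  n <- nrow(profiles)
  stopifnot(n >= 2)
  best_k <- 1L
  for (k in 2:min(max_clusters, n)) {
    labels <- cutree(dendrogram, k = k)
    pats <- vapply(seq_len(k), function(cl) {
      d <- .cluster_drivers(profiles, which(labels == cl),
                            driver_p_threshold)
      .canonical_pattern(d$modification, d$side)
    }, character(1))
    if (anyDuplicated(pats)) break
    best_k <- k
  }
  if (best_k == 1L && n >= 2) {
    warning("no cut separates clusters with distinct driver sets; ",
            "returning a single cluster", call. = FALSE)
  }
  labels <- if (best_k == 1L) {
    setNames(rep(1L, n), rownames(profiles))
  } else {
    cutree(dendrogram, k = best_k)
  }
  drivers <- rbindlist(lapply(seq_len(best_k), function(cl) {
    d <- .cluster_drivers(profiles, which(labels == cl),
                          driver_p_threshold)
    if (nrow(d)) d[, cluster := cl]
    d
  }), fill = TRUE)
  heights <- sort(dendrogram$height, decreasing = TRUE)
  cut_height <- if (best_k <= 1L || best_k > length(heights)) {
    max(dendrogram$height)
  } else {
    mean(heights[c(best_k - 1L, best_k)])
  }
  structure(list(
    n_clusters = best_k,
    labels = labels,
    drivers = drivers,
    cut_height = cut_height
  ), class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("cluster result:", x$n_clusters, "cluster(s), cut height",
      signif(x$cut_height, 3), "\n")
  if (nrow(x$drivers)) {
    for (cl in sort(unique(x$drivers$cluster))) {
      d <- x$drivers[cluster == cl]
      cat(sprintf("  cluster %d (%d sites): %s\n", cl,
                  sum(x$labels == cl),
                  .canonical_pattern(d$modification, d$side)))
    }
  }
  invisible(x)
}

#' Serialise a dendrogram as nested (Newick-style) text
#'
#' @param dendrogram An `hclust` object.
#' @return A single string in nested parenthesis format with merge heights.
#' @export
serialize_dendrogram <- function(dendrogram) {
  lab <- dendrogram$labels
  if (is.null(lab)) lab <- as.character(seq_len(nrow(dendrogram$merge) + 1))
  node <- function(i) {
    if (i < 0) lab[-i]
    else sprintf("(%s,%s):%.6g", node(dendrogram$merge[i, 1]),
                 node(dendrogram$merge[i, 2]), dendrogram$height[i])
  }
  paste0(node(nrow(dendrogram$merge)), ";")
}
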