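#' Distance from sites to the nearest target
#'
#' Edge distance: 0 inside a region, otherwise bp to the nearest region
#' edge; for point targets, the absolute position difference. Computed per
#' chromosome.
#'
#' @param sites Table with `chrom`, `pos`.
#' @param targets Either a region table (`chrom`, `start`, `end`, 1-based
#'   inclusive) or a site table (`chrom`, `pos`).
#' @return Numeric vector of distances aligned with `sites` rows (`Inf`
#'   where the chromosome has no target).
#' @export
distance_to_targets <- function(sites, targets) {
  sites <- as.data.table(sites)
  targets <- as.data.table(targets)
  is_region <- all(c("start", "end") %in% names(targets))
  d <- rep(Inf, nrow(sites))
  for (cn in unique(sites$chrom)) {
    si <- which(sites$chrom == cn)
    tg <- targets[chrom == cn]
    if (nrow(tg) == 0) next
    pos <- sites$pos[si]
    if (is_region) {
      dm <- rep(Inf, length(pos))
      for (r in seq_len(nrow(tg))) {
        dm <- pmin(dm, pmax(0, pmax(tg$start[r] - pos,
                                    pos - tg$end[r])))
      }
      d[si] <- dm
    } else {
      tp <- sort(tg$pos)
      i <- findInterval(pos, tp)
      d[si] <- pmin(abs(pos - tp[pmax(i, 1L)]),
                    abs(pos - tp[pmin(i + 1L, length(tp))]))
    }
  }
  d
}

#' Fraction of sites within a window of a target set
#'
#' A site is counted when its distance to the nearest target (edge
#' distance for regions, position difference for sites) is at most
#' `window` (inclusive).
#'
#' @param sites Table with `chrom`, `pos`.
#' @param targets Region or site table (see [distance_to_targets()]).
#' @param window Distance in bp.
#' @return List `count_in`, `total`, `proportion`.
#' @export
proximity_fraction <- function(sites, targets, window) {
  sites <- as.data.table(sites)
  if (nrow(as.data.table(targets)) == 0) {
    warning("empty target set: proportion is 0", call. = FALSE)
    return(list(count_in = 0L, total = nrow(sites), proportion = 0))
  }
  d <- distance_to_targets(sites, targets)
  list(count_in = sum(d <= window), total = nrow(sites),
       proportion = if (nrow(sites) > 0) mean(d <= window) else 0)
}

#' Test enrichment of a foreground proportion over a background
#'
#' 2x2 test of in-window membership for foreground versus background
#' sites: Yates-corrected chi-squared by default, Fisher exact where
#' expected counts are tiny. Fold enrichment is the ratio of proportions.
#'
#' @param fg_in,fg_total Foreground in-window count and total.
#' @param bg_in,bg_total Background in-window count and total.
#' @param method `"chi2"` or `"fisher"`.
#' @param window Optional window annotation carried into the result.
#' @param correct Continuity correction for the chi-squared variant.
#' @return One-row `data.table` of class `enrichment_result`: counts,
#'   proportions, `fold`, `p_value`, `test`, `window`.
#' @export
#' @examples
#' enrichment_test(9, 51, 486, 81029)      # ~29-fold
enrichment_test <- function(fg_in, fg_total, bg_in, bg_total,
                            method = c("chi2", "fisher"), window = NA,
                            correct = TRUE) {
  method <- match.arg(method)
  stopifnot(fg_total >= 1, bg_total >= 1, fg_in <= fg_total,
            bg_in <= bg_total)
  tab <- matrix(c(fg_in, fg_total - fg_in, bg_in, bg_total - bg_in),
                2, 2, byrow = TRUE)
  p <- if (method == "fisher") {
    fisher.test(tab)$p.value
  } else {
    suppressWarnings(chisq.test(tab, correct = correct)$p.value)
  }
  fg_prop <- fg_in / fg_total
  bg_prop <- bg_in / bg_total
  out <- data.table(
    window = window, fg_in = fg_in, fg_total = fg_total, bg_in = bg_in,
    bg_total = bg_total, fg_prop = fg_prop, bg_prop = bg_prop,
    fold = if (bg_prop > 0) fg_prop / bg_prop else NA_real_,
    p_value = if (is.na(p)) 1 else p, test = method
  )
  setattr(out, "class", c("enrichment_result", class(out)))
  out
}

#' Posterior odds of a significant call being a true association
#'
#' Calibration of a significance threshold: with a prior fraction of truly
#' associated sites, detection power, and per-test alpha, the posterior
#' odds that a site exceeding the threshold is a true association are
#' `[prior/(1-prior)] * power / alpha`.
#'
#' @param prior_fraction Prior fraction of true associations, in (0,1).
#' @param power Detection power, in (0,1).
#' @param alpha Per-test significance threshold, in (0,1).
#' @return Posterior odds (true : false).
#' @export
#' @examples
#' posterior_odds(1e-5, 0.1, 1e-7)   # ~10
posterior_odds <- function(prior_fraction, power, alpha) {
  for (v in list(prior_fraction = prior_fraction, power = power,
                 alpha = alpha)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0 || v >= 1) {
      stop("all arguments must lie in (0,1)", call. = FALSE)
    }
  }
  (prior_fraction / (1 - prior_fraction)) * power / alpha
}

#' Bonferroni per-test threshold
#'
#' @param alpha_fw Family-wise error rate.
#' @param n_tests Number of tests (>= 1).
#' @return `alpha_fw / n_tests`.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 3410426)   # order 1e-8
bonferroni_threshold <- function(alpha_fw, n_tests) {
  if (!is.numeric(n_tests) || length(n_tests) != 1L || is.na(n_tests) ||
      n_tests < 1) {
    stop("n_tests must be >= 1", call. = FALSE)
  }
  alpha_fw / n_tests
}

#' Clopper-Pearson exact confidence interval for a proportion
#'
#' @param k Successes (0 <= k <= n).
#' @param n Trials (>= 1).
#' @param confidence Coverage (default 0.95).
#' @return `c(low, high)`.
#' @export
#' @examples
#' proportion_ci(5, 100)
proportion_ci <- function(k, n, confidence = 0.95) {
  stopifnot(n >= 1, k >= 0, k <= n)
  ci <- binom.test(k, n, conf.level = confidence)$conf.int
  c(low = ci[1], high = ci[2])
}

#' Expected chance colocalisations under independence
#'
#' Independence expectation for how many of `n_sites` calls would fall
#' near an annotation purely by chance, given the background proportion of
#' comparable sites near it.
#'
#' @param n_sites Number of called sites.
#' @param bg_prop Background in-window proportion.
#' @return Expected count `n_sites * bg_prop`.
#' @export
#' @examples
#' expected_colocalisation(51, 0.005)   # at most one by chance
expected_colocalisation <- function(n_sites, bg_prop) {
  stopifnot(n_sites >= 0, bg_prop >= 0, bg_prop <= 1)
  n_sites * bg_prop
}

#' Composable proximity filter over sites
#'
#' Returns the subset of `sites` whose distance to the nearest target is
#' at most `window`; filters compose by chaining calls (for example, sites
#' with significant ASE within 10 kb *and* a deletion-syndrome region
#' within 250 kb).
#'
#' @param sites Table with `chrom`, `pos`.
#' @param targets Region or site table.
#' @param window Distance in bp (inclusive).
#' @return The filtered subset of `sites`.
#' @export
sites_within <- function(sites, targets, window) {
  sites <- as.data.table(sites)
  if (nrow(as.data.table(targets)) == 0) {
    return(sites[0])
  }
  sites[distance_to_targets(sites, targets) <= window]
}
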