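#' Design of a read-subsampling limit-of-detection experiment
#'
#' The in-silico titration used to pick a minimum sequencing depth for
#' methylation quantification: mixtures at the given methylation `levels` are
#' assembled by subsampling reads from a fully methylated and a fully
#' unmethylated standard, at each `depth`, `n_replicates` times, and the
#' levels are tested for pairwise distinguishability.
#'
#' @param levels Mixture methylation fractions (default
#'   `c(0, 0.10, 0.25, 0.50, 0.75, 1)`).
#' @param depths Per-site read depths to titrate (default
#'   `c(5, 10, 15, 20, 25, 50)`).
#' @param n_replicates Independent mixtures per (level, depth) cell
#'   (default 100).
#' @param alpha Significance level for the distinguishability call
#'   (default 0.05, applied to Bonferroni-adjusted p-values).
#' @param claim_levels The levels over which full pairwise distinguishability
#'   is claimed; defaults to the canonical five `{0, 25, 50, 75, 100}%`
#'   subset of `levels`. The 10% mixture is titrated but excluded from the
#'   claim.
#' @param seed Master seed; every replicate draws from an independent child
#'   stream derived from it.
#' @return A list of class `mixture_scenario`.
#' @export
mixture_scenario <- function(levels = c(0, 0.10, 0.25, 0.50, 0.75, 1),
                             depths = c(5L, 10L, 15L, 20L, 25L, 50L),
                             n_replicates = 100L, alpha = 0.05,
                             claim_levels = NULL, seed = 1L) {
  stopifnot(all(levels >= 0 & levels <= 1), all(depths >= 1L),
            n_replicates >= 2L, alpha > 0, alpha < 1)
  if (is.null(claim_levels)) {
    claim_levels <- intersect(c(0, 0.25, 0.50, 0.75, 1), levels)
  }
  stopifnot(all(claim_levels %in% levels), length(claim_levels) >= 2L)
  structure(list(levels = as.numeric(levels),
                 depths = as.integer(depths),
                 n_replicates = as.integer(n_replicates), alpha = alpha,
                 claim_levels = as.numeric(claim_levels),
                 seed = as.integer(seed)),
            class = "mixture_scenario")
}

# Split a call table into per-site LLR pools keyed by chromosome:start:end.
split_pool <- function(calls) {
  split(seq_len(nrow(calls)),
        paste(calls$chromosome, calls$start, calls$end, sep = "\r"))
}

#' Assemble an in-silico methylation mixture by read subsampling
#'
#' Per CpG site, draws `round(p * depth)` calls without replacement from the
#' fully methylated pool and the remaining `depth - round(p * depth)` from
#' the unmethylated pool, emulating a sample whose CpGs are methylated in a
#' fraction `p` of molecules.
#'
#' @param pool0,pool100 Methylation-call tibbles for the 0% and 100%
#'   standards; every site must carry at least the required number of calls.
#' @param p Target methylation fraction in \[0, 1\].
#' @param depth Total calls drawn per site.
#' @param seed Optional integer seed.
#' @return A methylation-call tibble with `depth` calls per site.
#' @export
make_mixture <- function(pool0, pool100, p, depth, seed = NULL) {
  stopifnot_scalar_fraction(p, "p")
  depth <- as.integer(depth)
  stopifnot(depth >= 1L)
  n100 <- as.integer(round(p * depth))
  n0 <- depth - n100
  idx0 <- split_pool(pool0)
  idx100 <- split_pool(pool100)
  sites <- names(idx0)
  if (!setequal(sites, names(idx100))) {
    stop("pools cover different CpG sites", call. = FALSE)
  }
  for (s in sites) {
    if (length(idx0[[s]]) < n0 || length(idx100[[s]]) < n100) {
      stop(sprintf(
        "insufficient pool depth at site %s: need %d/%d calls, have %d/%d",
        gsub("\r", ":", s), n0, n100, length(idx0[[s]]),
        length(idx100[[s]])), call. = FALSE)
    }
  }
  with_seed(seed, {
    picked0 <- unlist(lapply(idx0[sites], function(a) {
      if (n0 > 0L) a[sample.int(length(a), n0)] else integer(0)
    }), use.names = FALSE)
    picked100 <- unlist(lapply(idx100[sites], function(b) {
      if (n100 > 0L) b[sample.int(length(b), n100)] else integer(0)
    }), use.names = FALSE)
    out <- rbind(pool0[picked0, , drop = FALSE],
                 pool100[picked100, , drop = FALSE])
    out[order(out$chromosome, out$start, out$read_name), , drop = FALSE]
  })
}

#' Run the depth-titration limit-of-detection experiment
#'
#' For every (level, depth) cell, builds `n_replicates` independent mixtures
#' with [make_mixture()], aggregates each with
#' [aggregate_site_frequency()], and records the replicate statistic: the
#' mean methylation frequency across all reported CpGs. Per cell it reports
#' mean, SD and CV (SD/mean; undefined when the mean is 0 or the cell is
#' unusable); per depth it runs two-sided Welch t-tests between all level
#' pairs, Bonferroni-adjusting pairs of the claim set over the number of
#' claim pairs. `lod_depth` is the smallest depth at which every claim pair
#' is significant at `alpha`.
#'
#' A replicate whose sites are all removed by the read filter (e.g. depth
#' below `min_reads`) yields `NA`; a cell with fewer than 2 usable
#' replicates is marked unusable rather than silently skipped.
#'
#' @param scenario A [mixture_scenario()].
#' @param pool0,pool100 Call tables for the 0% and 100% standards, deep
#'   enough for the largest depth in the scenario.
#' @param params A [meth_filter_params()] used for aggregation.
#' @return A list of class `lod_result` with `replicates`, `summary`,
#'   `tests`, `lod_depth` and `scenario`.
#' @export
titrate <- function(scenario, pool0, pool100,
                    params = meth_filter_params()) {
  stopifnot(inherits(scenario, "mixture_scenario"))
  grid <- expand.grid(level = scenario$levels, depth = scenario$depths,
                      rep = seq_len(scenario$n_replicates),
                      KEEP.OUT.ATTRS = FALSE)
  seeds <- derive_seeds(scenario$seed, nrow(grid))
  stat <- numeric(nrow(grid))
  nsit <- integer(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    mix <- make_mixture(pool0, pool100, grid$level[i], grid$depth[i],
                        seed = seeds[i])
    agg <- aggregate_site_frequency(mix, params)
    nsit[i] <- nrow(agg)
    stat[i] <- if (nrow(agg) > 0L) mean(agg$methylated_frequency) else NA_real_
  }
  replicates <- tibble::tibble(level = grid$level, depth = grid$depth,
                               replicate = grid$rep, mean_frequency = stat,
                               n_sites = nsit)
  cells <- split(seq_len(nrow(replicates)),
                 paste(replicates$level, replicates$depth, sep = "\r"))
  summary <- do.call(rbind, lapply(cells, function(idx) {
    x <- replicates$mean_frequency[idx]
    usable <- sum(!is.na(x)) >= 2L
    m <- if (usable) mean(x, na.rm = TRUE) else NA_real_
    s <- if (usable) stats::sd(x, na.rm = TRUE) else NA_real_
    data.frame(level = replicates$level[idx[1]],
               depth = replicates$depth[idx[1]],
               n_usable = sum(!is.na(x)), mean = m, sd = s,
               cv = if (usable && !is.na(m) && m > 0) s / m else NA_real_,
               usable = usable)
  }))
  summary <- tibble::as_tibble(summary[order(summary$level, summary$depth), ])
  claim <- scenario$claim_levels
  n_claim_pairs <- choose(length(claim), 2L)
  pairs <- utils::combn(sort(scenario$levels), 2L)
  tests <- list()
  for (d in scenario$depths) {
    for (j in seq_len(ncol(pairs))) {
      la <- pairs[1, j]; lb <- pairs[2, j]
      xa <- replicates$mean_frequency[replicates$level == la &
                                        replicates$depth == d]
      xb <- replicates$mean_frequency[replicates$level == lb &
                                        replicates$depth == d]
      xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
      p_raw <- if (length(xa) >= 2L && length(xb) >= 2L &&
                   (stats::sd(xa) > 0 || stats::sd(xb) > 0)) {
        stats::t.test(xa, xb)$p.value
      } else if (length(xa) >= 2L && length(xb) >= 2L) {
        # zero variance in both groups: identical -> 1, disjoint -> 0
        if (isTRUE(all.equal(mean(xa), mean(xb)))) 1 else 0
      } else {
        NA_real_
      }
      in_claim <- la %in% claim && lb %in% claim
      tests[[length(tests) + 1L]] <- data.frame(
        depth = d, level_a = la, level_b = lb, p = p_raw,
        in_claim_family = in_claim,
        p_adj = if (in_claim) pmin(1, p_raw * n_claim_pairs) else NA_real_)
    }
  }
  tests <- tibble::as_tibble(do.call(rbind, tests))
  lod_depth <- NA_integer_
  for (d in sort(scenario$depths)) {
    tt <- tests[tests$depth == d & tests$in_claim_family, ]
    if (nrow(tt) == n_claim_pairs && all(!is.na(tt$p_adj)) &&
        all(tt$p_adj < scenario$alpha)) {
      lod_depth <- d
      break
    }
  }
  structure(list(replicates = replicates, summary = summary, tests = tests,
                 lod_depth = lod_depth, scenario = scenario),
            class = "lod_result")
}
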