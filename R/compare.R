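#' Condense recombination intervals across maps
#'
#' Restricts a multi-map comparison to physical spans bounded by markers
#' placed at (nearly) the same reference position in every map. Marker
#' boundaries are matched greedily left to right within `tolerance` base
#' pairs; events of a map's sub-intervals falling between two matched
#' boundaries are summed, and the informative cohort of the merged span is
#' the minimum of the sub-interval cohorts. Spans that cannot be matched in
#' every map are dropped and logged.
#'
#' @param maps named list (>= 2) of per-map interval tables (data frames
#'   with `chrom`, `left`, `right`, `events`, `n_scored`, as in
#'   `build_map()$intervals`) or `"recmap"` objects.
#' @param tolerance maximum marker-placement difference in bp (default
#'   10000; matched markers typically differ by far less).
#' @return A data frame of class `"condensed_intervals"`, long format: one
#'   row per condensed interval per map with columns `interval`, `chrom`,
#'   `start`, `end` (reference-map coordinates), `map`, `events`,
#'   `n_scored`, `offset_left`, `offset_right`. Attribute `"dropped"` logs
#'   unmatched reference boundaries.
#' @export
condense_intervals <- function(maps, tolerance = 10000) {
  if (length(maps) < 2L) stop("need at least 2 maps")
  if (is.null(names(maps)) || any(names(maps) == ""))
    names(maps) <- paste0("map", seq_along(maps))
  tabs <- lapply(maps, function(m) if (inherits(m, "recmap")) m$intervals else m)
  chrs <- unique(unlist(lapply(tabs, function(t) unique(t$chrom))))
  if (length(chrs) != 1L)
    stop("maps must be on a single shared chromosome (got: ",
         paste(chrs, collapse = ", "), ")")
  bounds <- lapply(tabs, function(t) c(t$left[1L], t$right))
  ref <- bounds[[1L]]
  nm <- length(tabs)
  ptr <- rep(1L, nm)
  matched <- vector("list", 0L)
  dropped <- numeric(0)
  for (b in ref) {
    idx <- integer(nm); idx[1L] <- match(b, ref)
    ok <- TRUE
    save_ptr <- ptr
    for (m in 2:nm) {
      bm <- bounds[[m]]
      while (ptr[m] <= length(bm) && bm[ptr[m]] < b - tolerance)
        ptr[m] <- ptr[m] + 1L
      if (ptr[m] > length(bm) || abs(bm[ptr[m]] - b) > tolerance) {
        ok <- FALSE; break
      }
      idx[m] <- ptr[m]
      ptr[m] <- ptr[m] + 1L
    }
    if (ok) matched[[length(matched) + 1L]] <- idx
    else { ptr <- save_ptr; dropped <- c(dropped, b) }
  }
  if (length(matched) < 2L)
    stop("fewer than two boundaries matched across maps; nothing to condense")
  mt <- do.call(rbind, matched)
  rows <- list()
  for (k in seq_len(nrow(mt) - 1L)) {
    start <- ref[mt[k, 1L]]; end <- ref[mt[k + 1L, 1L]]
    for (m in seq_len(nm)) {
      i0 <- mt[k, m]; i1 <- mt[k + 1L, m]
      sub <- seq.int(i0, i1 - 1L)          # sub-intervals of map m in the span
      rows[[length(rows) + 1L]] <- data.frame(
        interval = k, chrom = chrs, start = start, end = end,
        map = names(tabs)[m],
        events = sum(tabs[[m]]$events[sub]),
        n_scored = min(tabs[[m]]$n_scored[sub]),
        offset_left = bounds[[m]][i0] - start,
        offset_right = bounds[[m]][i1] - end,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$map <- factor(out$map, levels = names(tabs))
  attr(out, "dropped") <- dropped
  attr(out, "tolerance") <- tolerance
  class(out) <- c("condensed_intervals", "data.frame")
  out
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted q-values (wraps [stats::p.adjust()]).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values of the same length.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Fit rare-events logistic comparisons between condensed maps
#'
#' For every pair of maps: a bias-corrected (Firth) logistic regression of
#' crossover events conditioned on observations, with map and interval as
#' factors, yields the global map-effect odds ratio; per-interval odds
#' ratios come from interval-wise 2x2 Firth fits and are reported after
#' removing the global map effect, with a Wald test of the interaction
#' (deviation of the interval's map effect from the global one). Intervals
#' with zero events in every map are flagged and excluded from per-interval
#' testing but retained in the global fit. q-values are
#' Benjamini-Hochberg-adjusted within each map pair.
#'
#' @param condensed output of [condense_intervals()].
#' @return An object of class `"recmap_comparison"`: list with `global`
#'   (per pair: `or`, `ci_low`, `ci_high`, `z`, `p`, and the derived
#'   `multiplier = 1/or` that rescales the second map onto the first),
#'   `per_interval` (per interval x pair: adjusted `or`, Wald CI, `p`,
#'   `q`), `separated` (interval ids excluded from per-interval testing),
#'   and `maps`.
#' @export
fit_rare_events_model <- function(condensed) {
  stopifnot(inherits(condensed, "condensed_intervals"))
  maps <- levels(condensed$map)
  ints <- sort(unique(condensed$interval))
  if (length(maps) < 2L || length(ints) < 2L)
    stop("need at least 2 maps and 2 intervals")
  ev <- function(m, i) {
    r <- condensed[condensed$map == m & condensed$interval == i, ]
    c(r$events[1L], r$n_scored[1L])
  }
  tot_events <- tapply(condensed$events, condensed$interval, sum)
  separated <- as.integer(names(tot_events)[tot_events == 0])
  pairs <- utils::combn(maps, 2L, simplify = FALSE)
  glob <- list(); per <- list()
  for (pr in pairs) {
    sub <- condensed[condensed$map %in% pr, ]
    sub$map <- factor(as.character(sub$map), levels = pr)
    X <- model.matrix(~ map + factor(interval), data = sub)
    fit <- firth_logit(X, sub$events, sub$n_scored)
    j <- paste0("map", pr[2L])
    lor <- fit$coef[[j]]; se <- sqrt(fit$vcov[j, j])
    glob[[length(glob) + 1L]] <- data.frame(
      map1 = pr[1L], map2 = pr[2L],
      or = exp(lor), ci_low = exp(lor - 1.96 * se),
      ci_high = exp(lor + 1.96 * se),
      z = lor / se, p = 2 * pnorm(-abs(lor / se)),
      multiplier = exp(-lor), stringsAsFactors = FALSE)
    test_ints <- setdiff(ints, separated)
    res <- lapply(test_ints, function(i) {
      a <- ev(pr[1L], i); b <- ev(pr[2L], i)
      f <- firth_2x2(c(a[1L], b[1L]), c(a[2L], b[2L]))
      adj <- f$log_or - lor
      z <- adj / f$se
      data.frame(interval = i, map1 = pr[1L], map2 = pr[2L],
                 or = exp(adj), ci_low = exp(adj - 1.96 * f$se),
                 ci_high = exp(adj + 1.96 * f$se),
                 p = 2 * pnorm(-abs(z)), stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    res$q <- bh_fdr(res$p)
    per[[length(per) + 1L]] <- res
  }
  structure(list(global = do.call(rbind, glob),
                 per_interval = do.call(rbind, per),
                 separated = separated, maps = maps,
                 intervals = unique(condensed[, c("interval", "chrom",
                                                  "start", "end")])),
            class = "recmap_comparison")
}

#' Classify condensed intervals as conserved, divergent or undetermined
#'
#' An interval is *divergent* when any pairwise test has q < 0.05 (after
#' false-discovery-rate correction); *conserved* when every pairwise test
#' has uncorrected p >= 0.05 **and** every adjusted pairwise odds ratio
#' lies in \[0.62, 1.615\] (no multiple-test correction in defining
#' conserved intervals); otherwise *undetermined*. Intervals without an
#' odds ratio (e.g. excluded for separation) are undetermined.
#'
#' @param comparison a `"recmap_comparison"` from
#'   [fit_rare_events_model()].
#' @param or_window odds-ratio window for conservation; the asymmetric
#'   default `c(0.62, 1.615)` is used verbatim.
#' @return Data frame: `interval`, `class`, with the per-pair evidence kept
#'   as attribute `"records"`.
#' @export
classify_intervals <- function(comparison, or_window = c(0.62, 1.615)) {
  stopifnot(inherits(comparison, "recmap_comparison"))
  ints <- comparison$intervals$interval
  pi <- comparison$per_interval
  cls <- vapply(ints, function(i) {
    rec <- pi[pi$interval == i, ]
    if (nrow(rec) == 0L || any(is.na(rec$or))) return("undetermined")
    if (any(rec$q < 0.05)) return("divergent")
    if (all(rec$p >= 0.05) &&
        all(rec$or >= or_window[1L] & rec$or <= or_window[2L]))
      return("conserved")
    "undetermined"
  }, character(1L))
  out <- data.frame(interval = ints, class = cls, stringsAsFactors = FALSE)
  attr(out, "records") <- pi
  out
}

#' Rescale a map's rates by the fitted global modifier
#'
#' Multiplies the non-reference map's recombination rates by the global
#' factor estimated by the rare-events model (e.g. a factor of 0.763 maps a
#' globally elevated map onto the reference scale). The adjustment is
#' recorded in the result's `"modifier"` attribute.
#'
#' @param rates numeric vector of cM/Mb values.
#' @param factor global multiplier (the pair's `multiplier`, i.e. 1/OR of
#'   the second map vs the first, or the OR itself depending on which map
#'   is being rescaled).
#' @return Adjusted rates with attribute `"modifier"`.
#' @export
apply_global_modifier <- function(rates, factor) {
  out <- rates * factor
  attr(out, "modifier") <- factor
  out
}

#' Compare recombination maps end to end
#'
#' Condenses the maps to shared marker boundaries, fits the global and
#' per-interval rare-events logistic comparisons for every map pair, and
#' classifies each condensed interval as conserved, divergent or
#' undetermined.
#'
#' @inheritParams condense_intervals
#' @return The `"recmap_comparison"` object with an added `classification`
#'   element and the condensed table as `condensed`.
#' @export
compare_maps <- function(maps, tolerance = 10000) {
  cnd <- condense_intervals(maps, tolerance = tolerance)
  fit <- fit_rare_events_model(cnd)
  fit$classification <- classify_intervals(fit)
  fit$condensed <- cnd
  fit
}

#' @export
print.recmap_comparison <- function(x, ...) {
  cat("Rare-events logistic comparison of", length(x$maps), "maps,",
      nrow(x$intervals), "condensed intervals\n")
  g <- x$global
  for (k in seq_len(nrow(g)))
    cat(sprintf("  %s vs %s: OR = %.4f (%.4f, %.4f), p = %.3g\n",
                g$map2[k], g$map1[k], g$or[k], g$ci_low[k], g$ci_high[k], g$p[k]))
  if (!is.null(x$classification)) {
    tb <- table(factor(x$classification$class,
                       levels = c("conserved", "divergent", "undetermined")))
    cat(sprintf("  classes: %d conserved / %d divergent / %d undetermined\n",
                tb["conserved"], tb["divergent"], tb["undetermined"]))
  }
  invisible(x)
}
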