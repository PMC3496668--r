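#' Marker map constructor
#'
#' A marker map gives the physical anchor of every genotyped marker:
#' chromosome, marker name, and 1-based position on the reference assembly.
#' Positions must be strictly increasing within a chromosome and marker
#' names unique; map distances are later expressed per physical megabase.
#'
#' @param chrom character vector of chromosome names.
#' @param marker character vector of unique marker names.
#' @param pos integer vector of 1-based physical positions (bp).
#' @return A `data.frame` with columns `chrom`, `marker`, `pos` and class
#'   `"marker_map"`.
#' @examples
#' marker_map("2", paste0("m", 1:4), c(1e5, 5e5, 9e5, 1.6e6))
#' @export
marker_map <- function(chrom, marker, pos) {
  chrom <- as.character(chrom)
  marker <- as.character(marker)
  pos <- as.numeric(pos)
  if (length(marker) != length(pos) || length(chrom) %in% c(1L, length(marker)) == FALSE)
    stop("chrom, marker and pos must have matching lengths")
  if (length(chrom) == 1L) chrom <- rep(chrom, length(marker))
  if (anyDuplicated(marker)) stop("marker names must be unique")
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (any(diff(p) <= 0)) {
      bad <- which(diff(p) <= 0)[1L]
      stop(sprintf("positions not strictly increasing on %s: markers '%s' and '%s'",
                   ch, marker[chrom == ch][bad], marker[chrom == ch][bad + 1L]))
    }
  }
  structure(data.frame(chrom = chrom, marker = marker, pos = pos,
                       stringsAsFactors = FALSE),
            class = c("marker_map", "data.frame"))
}

#' Backcross genotype matrix constructor
#'
#' Two-state backcross calls per individual and marker: `0` homozygous (for
#' the backcross parent), `1` heterozygous, `NA` missing. X-chromosome
#' backcross calls are assumed recoded upstream to the same two-state
#' alphabet, so one code path serves autosomes and sex-chromosome arms.
#'
#' @param x integer matrix (individuals x markers) with values 0, 1, NA.
#' @param markers a [marker_map()] whose rows match the columns of `x` in
#'   order.
#' @return `x` as an integer matrix of class `"genotype_matrix"` with the
#'   marker map attached as attribute `"markers"`.
#' @export
genotype_matrix <- function(x, markers) {
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  if (!inherits(markers, "marker_map")) stop("markers must be a marker_map")
  if (ncol(x) != nrow(markers))
    stop(sprintf("genotype matrix has %d columns but marker map has %d markers",
                 ncol(x), nrow(markers)))
  vals <- x[!is.na(x)]
  if (length(vals) && !all(vals %in% c(0L, 1L)))
    stop("genotype codes must be 0 (homozygous), 1 (heterozygous) or NA")
  colnames(x) <- markers$marker
  structure(x, markers = markers, class = c("genotype_matrix", class(x)))
}

markers_of <- function(genotypes) attr(genotypes, "markers")

#' Remove putative genotyping errors (apparent double crossovers)
#'
#' An apparent double crossover is a single call whose nearest non-missing
#' neighbours on both sides agree with each other and disagree with it
#' (e.g. one homozygous call nested in a heterozygous tract). Because
#' crossover interference makes two genuine exchanges within a short
#' physical span very unlikely, such calls are treated as genotyping errors
#' and set to missing. The rule is applied once, simultaneously over the
#' original matrix (no iteration to a fixed point), and regardless of
#' physical distance between the flanking markers. Runs of two or more
#' discordant calls, and flips at chromosome ends, are left untouched.
#'
#' @param genotypes a [genotype_matrix()].
#' @return A list with elements `genotypes` (the filtered matrix, flagged as
#'   filtered) and `removals` (data frame of `individual`, `marker` for each
#'   call set to missing).
#' @examples
#' mm <- marker_map("2", paste0("m", 1:5), c(1, 2, 3, 4, 5) * 1e5)
#' g <- genotype_matrix(rbind(c(1, 1, 0, 1, 1)), mm)
#' filter_double_crossovers(g)$removals
#' @export
filter_double_crossovers <- function(genotypes) {
  if (!inherits(genotypes, "genotype_matrix")) stop("need a genotype_matrix")
  g <- unclass(genotypes)
  n <- nrow(g); m <- ncol(g)
  if (n == 0L || m == 0L) {
    out <- genotypes
    attr(out, "dc_filtered") <- TRUE
    return(list(genotypes = out,
                removals = data.frame(individual = integer(), marker = character(),
                                      stringsAsFactors = FALSE)))
  }
  # nearest non-missing value strictly before / after each call (column passes)
  prevv <- matrix(NA_integer_, n, m)
  lastv <- rep(NA_integer_, n)
  for (j in seq_len(m)) {
    prevv[, j] <- lastv
    have <- !is.na(g[, j])
    lastv[have] <- g[have, j]
  }
  nextv <- matrix(NA_integer_, n, m)
  lastv <- rep(NA_integer_, n)
  for (j in rev(seq_len(m))) {
    nextv[, j] <- lastv
    have <- !is.na(g[, j])
    lastv[have] <- g[have, j]
  }
  drop <- !is.na(g) & !is.na(prevv) & !is.na(nextv) &
    prevv == nextv & g != prevv
  out <- g
  out[drop] <- NA_integer_
  idx <- which(drop, arr.ind = TRUE)
  removals <- data.frame(individual = as.integer(idx[, 1L]),
                         marker = colnames(g)[idx[, 2L]],
                         stringsAsFactors = FALSE)
  removals <- removals[order(removals$individual), , drop = FALSE]
  rownames(removals) <- NULL
  out <- structure(out, markers = markers_of(genotypes),
                   class = class(genotypes), dc_filtered = TRUE)
  list(genotypes = out, removals = removals)
}

#' Score crossovers per marker interval
#'
#' A crossover is scored whenever an individual's genotype changes between
#' consecutive non-missing calls (heterozygous to homozygous for the
#' backcross parent, or vice versa). An event whose flanking non-missing
#' calls are adjacent markers is attributed to that interval; an event that
#' skips missing calls is attributed to the merged span and reported in a
#' separate log rather than to any single interval. `n_scored` for an
#' interval counts the individuals with non-missing calls at both flanking
#' markers.
#'
#' @param genotypes a [genotype_matrix()] that has been through
#'   [filter_double_crossovers()] (or pass `filtered = TRUE` to assert the
#'   filter is intentionally skipped).
#' @param markers marker map; must match the matrix's attached map.
#' @param filtered logical; set `TRUE` to override the filter check.
#' @return A list:
#'   \describe{
#'     \item{intervals}{data frame per adjacent-marker interval: `chrom`,
#'       `left`, `right` (bp of flanking markers), `events`, `n_scored`,
#'       `r` (= events / n_scored).}
#'     \item{per_individual}{data frame of total crossovers per individual
#'       (merged-span events included).}
#'     \item{merged_events}{log of events attributed to merged spans:
#'       `individual`, `left_marker`, `right_marker`.}
#'     \item{summary}{mean and median crossovers per individual.}
#'   }
#' @export
count_crossovers <- function(genotypes, markers = markers_of(genotypes),
                             filtered = FALSE) {
  if (!inherits(genotypes, "genotype_matrix")) stop("need a genotype_matrix")
  mm <- markers_of(genotypes)
  if (!identical(mm$marker, markers$marker) || !identical(mm$pos, markers$pos))
    stop("marker map does not match the map attached to the genotype matrix")
  if (!isTRUE(attr(genotypes, "dc_filtered")) && !filtered)
    stop("apply filter_double_crossovers() first (or pass filtered = TRUE)")
  g <- unclass(genotypes)
  n <- nrow(g); m <- ncol(g)
  events <- integer(max(m - 1L, 0L))
  n_scored <- integer(max(m - 1L, 0L))
  per_ind <- integer(n)
  mi <- integer(0); ml <- integer(0); mr <- integer(0)
  lastv <- rep(NA_integer_, n)
  lasti <- rep(NA_integer_, n)
  for (j in seq_len(m)) {
    cur <- g[, j]
    have <- !is.na(cur)
    cmp <- have & !is.na(lastv)
    flip <- cmp & cur != lastv
    adj <- flip & lasti == j - 1L
    if (j > 1L) {
      events[j - 1L] <- sum(adj, na.rm = TRUE)
      n_scored[j - 1L] <- sum(!is.na(g[, j - 1L]) & have)
    }
    mrg <- which(flip & lasti < j - 1L)
    if (length(mrg)) {
      mi <- c(mi, mrg); ml <- c(ml, lasti[mrg]); mr <- c(mr, rep(j, length(mrg)))
    }
    per_ind <- per_ind + ifelse(is.na(flip), 0L, as.integer(flip))
    lastv[have] <- cur[have]
    lasti[have] <- j
  }
  iv <- data.frame(chrom = mm$chrom[-nrow(mm)],
                   left = mm$pos[-nrow(mm)], right = mm$pos[-1L],
                   events = events, n_scored = n_scored,
                   r = ifelse(n_scored > 0L, events / n_scored, NA_real_),
                   stringsAsFactors = FALSE)
  list(intervals = iv,
       per_individual = data.frame(individual = seq_len(n), crossovers = per_ind),
       merged_events = data.frame(individual = mi,
                                  left_marker = mm$marker[ml],
                                  right_marker = mm$marker[mr],
                                  stringsAsFactors = FALSE),
       summary = c(mean = if (n) mean(per_ind) else NA_real_,
                   median = if (n) stats::median(per_ind) else NA_real_))
}

#' Kosambi map distance
#'
#' Converts a recombination fraction to centiMorgans with the Kosambi
#' mapping function, `cM = 25 * ln((1 + 2r) / (1 - 2r))`, which corrects the
#' raw fraction for crossover interference. Strictly increasing in `r` and
#' always at least `100 * r`; undefined at `r >= 0.5`.
#'
#' @param r recombination fraction(s) in `[0, 0.5)`.
#' @return Map distance(s) in centiMorgans.
#' @examples
#' kosambi_cm(0.10) # 10.1366
#' @export
kosambi_cm <- function(r) {
  if (any(!is.finite(r)) || any(r < 0) || any(r >= 0.5))
    stop("recombination fraction must lie in [0, 0.5)")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

## Kosambi with r >= 0.5 mapped to Inf instead of an error (bootstrap internals)
kosambi_cm_inf <- function(r) {
  out <- rep(Inf, length(r))
  ok <- r < 0.5
  out[ok] <- 25 * log((1 + 2 * r[ok]) / (1 - 2 * r[ok]))
  out
}

#' Recombination rate in cM/Mb
#'
#' Kosambi map distance divided by the physical span in megabases.
#' Intervals with no observed recombinants are reported as 0 cM/Mb.
#'
#' @param cm Kosambi map distance (cM).
#' @param length_bp physical interval length in bp; must be positive.
#' @return Rate(s) in cM/Mb.
#' @export
rate_cm_per_mb <- function(cm, length_bp) {
  if (any(length_bp <= 0)) stop("interval physical length must be positive")
  cm / (length_bp / 1e6)
}

#' Permutation (bootstrap) confidence interval for an interval's rate
#'
#' Resamples the individuals' per-interval event indicators with
#' replacement, recomputes Kosambi cM/Mb for each replicate, and returns
#' the 2.5th and 97.5th percentiles. The lower bound is truncated at 0, and
#' intervals with zero events return `c(0, 0)` (their upper bound should
#' come from [zero_event_upper_bound()] instead).
#'
#' @param events crossover count for the interval.
#' @param n_scored individuals informative for the interval (>= 1).
#' @param length_bp physical interval length (bp).
#' @param replicates number of resampling replicates (default 10000; fewer
#'   than 100 triggers a warning).
#' @param level confidence level (default 0.95).
#' @return Named numeric `c(ci_low, ci_high)` in cM/Mb.
#' @export
permutation_ci <- function(events, n_scored, length_bp, replicates = 10000L,
                           level = 0.95) {
  if (n_scored < 1L) stop("n_scored must be at least 1")
  if (replicates < 100L) warning("fewer than 100 replicates; interval will be unstable")
  sims <- rbinom(replicates, n_scored, events / n_scored)
  rates <- rate_cm_per_mb(kosambi_cm_inf(sims / n_scored), length_bp)
  qs <- quantile(rates, probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                 names = FALSE, type = 7)
  c(ci_low = max(0, qs[1L]), ci_high = qs[2L])
}

#' Binomial upper bound for intervals with no recombinants
#'
#' When no recombinant is observed among `N` scored individuals the
#' permutation interval degenerates to zero width; the 95% upper bound on
#' the recombination fraction is instead taken from the binomial sampling
#' distribution by solving `(1 - x)^N = 0.05`, i.e. `x = 1 - 0.05^(1/N)`.
#'
#' @param n_scored number of individuals surveyed (>= 1).
#' @return Upper bound on the recombination fraction.
#' @examples
#' zero_event_upper_bound(1)    # 0.95
#' zero_event_upper_bound(1158) # 0.0025837
#' @export
zero_event_upper_bound <- function(n_scored) {
  if (any(n_scored < 1)) stop("n_scored must be at least 1")
  1 - 0.05^(1 / n_scored)
}

#' Test for heterogeneity of recombination rate among intervals
#'
#' Likelihood-ratio test from a binomial GLM of per-interval event counts:
#' the model with interval identity as a factor is compared against the
#' model with only log interval size as a covariate. Returns the deviance
#' chi-square, its degrees of freedom (number of intervals minus two), and
#' the p value.
#'
#' @param intervals data frame with columns `events`, `n_scored`, `left`,
#'   `right` (as produced by [count_crossovers()] or [build_map()]).
#' @return List with `chisq`, `df`, `p`.
#' @export
heterogeneity_test <- function(intervals) {
  if (nrow(intervals) < 2L) stop("need at least 2 intervals")
  size <- intervals$right - intervals$left
  y <- cbind(intervals$events, intervals$n_scored - intervals$events)
  id <- factor(seq_len(nrow(intervals)))
  fit0 <- glm(y ~ log(size), family = binomial())
  fit1 <- glm(y ~ id, family = binomial())
  dev <- fit0$deviance - fit1$deviance
  df <- fit0$df.residual - fit1$df.residual
  list(chisq = dev, df = df, p = pchisq(dev, df, lower.tail = FALSE))
}

#' Build a recombination map from backcross genotypes
#'
#' The full map-construction pipeline: remove apparent double crossovers as
#' genotyping errors, score crossovers per marker interval, convert event
#' fractions to Kosambi cM/Mb, and attach 95% confidence bounds (bootstrap
#' percentile interval; binomial upper bound for zero-event intervals).
#'
#' @param genotypes a [genotype_matrix()].
#' @param replicates bootstrap replicates for the interval CIs.
#' @param seed integer seed for the resampling.
#' @param level confidence level.
#' @return An object of class `"recmap"`: a list with `intervals` (one row
#'   per marker interval: `chrom`, `left`, `right`, `events`, `n_scored`,
#'   `r`, `cM`, `rate`, `ci_low`, `ci_high`), `per_individual`,
#'   `merged_events`, `removals`, `crossover_summary`, and the call.
#' @examples
#' sc <- cross_scenario(r = c(0.05, 0.1), individuals = 500, seed = 1)
#' mm <- marker_map("2", c("a", "b", "c"), c(1e5, 6e5, 13e5))
#' sim <- simulate_backcross(sc, mm)
#' m <- build_map(sim$genotypes, replicates = 1000, seed = 1)
#' m
#' @export
build_map <- function(genotypes, replicates = 10000L, seed = NULL, level = 0.95) {
  if (!is.null(seed)) set.seed(seed)
  flt <- filter_double_crossovers(genotypes)
  cc <- count_crossovers(flt$genotypes)
  iv <- cc$intervals
  iv$cM <- ifelse(iv$n_scored > 0L, kosambi_cm(pmin(iv$r, 0.499999)), NA_real_)
  iv$rate <- rate_cm_per_mb(iv$cM, iv$right - iv$left)
  ci <- matrix(NA_real_, nrow(iv), 2L)
  for (k in seq_len(nrow(iv))) {
    if (iv$n_scored[k] < 1L) next
    if (iv$events[k] == 0L) {
      ub <- zero_event_upper_bound(iv$n_scored[k])
      ci[k, ] <- c(0, rate_cm_per_mb(kosambi_cm(ub), iv$right[k] - iv$left[k]))
    } else {
      ci[k, ] <- permutation_ci(iv$events[k], iv$n_scored[k],
                                iv$right[k] - iv$left[k],
                                replicates = replicates, level = level)
    }
  }
  iv$ci_low <- ci[, 1L]; iv$ci_high <- ci[, 2L]
  structure(list(intervals = iv,
                 per_individual = cc$per_individual,
                 merged_events = cc$merged_events,
                 removals = flt$removals,
                 crossover_summary = cc$summary,
                 replicates = replicates, level = level,
                 call = match.call()),
            class = "recmap")
}

#' @export
print.recmap <- function(x, ...) {
  iv <- x$intervals
  cat("Recombination map:", nrow(iv), "intervals on",
      paste(unique(iv$chrom), collapse = ", "), "\n")
  cat(sprintf("  individuals scored (max): %d; removals (double-crossover filter): %d\n",
              max(iv$n_scored), nrow(x$removals)))
  cat(sprintf("  crossovers per individual: mean %.3f, median %s\n",
              x$crossover_summary["mean"], format(x$crossover_summary["median"])))
  cat(sprintf("  rate range: %.3f-%.3f cM/Mb\n", min(iv$rate), max(iv$rate)))
  invisible(x)
}

#' @export
summary.recmap <- function(object, ...) {
  iv <- object$intervals
  out <- list(intervals = iv,
              total_events = sum(iv$events),
              crossover_summary = object$crossover_summary,
              heterogeneity = if (nrow(iv) >= 2L) heterogeneity_test(iv) else NULL)
  class(out) <- "summary.recmap"
  out
}

#' @export
print.summary.recmap <- function(x, ...) {
  print(head(x$intervals, 10L))
  if (nrow(x$intervals) > 10L) cat("  ...", nrow(x$intervals), "intervals total\n")
  cat(sprintf("Total crossovers: %d\n", x$total_events))
  if (!is.null(x$heterogeneity))
    cat(sprintf("Rate heterogeneity among intervals: chi-square = %.2f, df = %d, p = %.3g\n",
                x$heterogeneity$chisq, x$heterogeneity$df, x$heterogeneity$p))
  invisible(x)
}

#' @export
plot.recmap <- function(x, ...) {
  iv <- x$intervals
  mid <- (iv$left + iv$right) / 2 / 1e6
  plot(mid, iv$rate, type = "n", xlab = "Position (Mb)",
       ylab = "Recombination rate (cM/Mb)",
       ylim = c(0, max(iv$ci_high, iv$rate, na.rm = TRUE)), ...)
  segments(mid, iv$ci_low, mid, iv$ci_high, col = "grey60")
  segments(iv$left / 1e6, iv$rate, iv$right / 1e6, iv$rate, lwd = 2)
  invisible(x)
}
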