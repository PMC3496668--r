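#' Per-site table for footprint windowing
#'
#' Precomputes the site-level quantities the window builder aggregates:
#' eligibility and polymorphism of 4-fold degenerate sites (all 4-fold
#' sites, not only unpreferred codons, are used around substitutions), GC
#' identity, coding status, and the per-site neutral-proxy divergence.
#'
#' @param aln alignment (reference sample first).
#' @param species species label per sequence.
#' @param cds CDS annotation data frame.
#' @param focal species providing the polymorphism counts.
#' @param proxy_pair two species whose per-site divergence is the neutral
#'   proxy.
#' @param preference codon preference table (used only for classification
#'   bookkeeping; the footprint stream ignores preference).
#' @return Data frame, one row per position: `pos`, `eligible`,
#'   `polymorphic`, `gc_base`, `coding`, `proxy_diff`.
#' @export
site_table <- function(aln, species, cds, focal, proxy_pair,
                       preference = default_preference_table()) {
  m <- aln_matrix(aln)
  species <- as.character(species)
  cls <- classify_sites(aln, cds, preference)
  foc <- m[species == focal, , drop = FALSE]
  elig <- eligible_mask(foc, cls, stream = "all4fold")
  poly <- apply(foc, 2L, function(col) length(unique(col)) >= 2L)
  prx <- m[species %in% proxy_pair, , drop = FALSE]
  pd <- rep(NA_real_, ncol(m))
  if (nrow(prx) >= 2L) {
    idx <- which(eligible_mask(prx, cls, stream = "all4fold"))
    if (length(idx))
      pd[idx] <- pairwise_divergence(prx[1L, , drop = FALSE],
                                     prx[-1L, , drop = FALSE],
                                     seq_len(ncol(m)) %in% idx)$per_site
  }
  refb <- m[1L, ]
  data.frame(pos = seq_len(ncol(m)),
             eligible = elig, polymorphic = elig & poly,
             gc_base = ifelse(refb %in% c("A", "C", "G", "T"),
                              refb %in% c("G", "C"), NA),
             coding = cls$coding, proxy_diff = pd)
}

local_rate <- function(pos, map_intervals) {
  hit <- which(map_intervals$left <= pos & pos <= map_intervals$right)
  if (!length(hit)) return(NA_real_)
  map_intervals$rate[hit[1L]]
}

#' Build substitution-centred windows
#'
#' Tiles non-overlapping windows of `bin` bp outward from each substitution
#' across `span` bp on either side (up to `2 * span / bin` windows per
#' substitution), anchored immediately adjacent to the substitution
#' position. Distance is the absolute distance from the window midpoint to
#' the substitution, so the two innermost windows sit at `bin / 2`.
#' Windows that would extend past the sequence ends are dropped and the
#' truncation logged.
#'
#' @param substitutions data frame with `pos`, `type`
#'   (`"nonsynonymous"`/`"synonymous"`), sorted by position.
#' @param sites per-site table from [site_table()] (or an equivalent
#'   synthetic table).
#' @param map_intervals map table (`left`, `right`, `rate`) giving each
#'   substitution its local recombination rate; may be `NULL` if
#'   `substitutions` carries a `rate` column.
#' @param span half-width of the region (default 60000 bp; the 5 kb / 15 kb
#'   sensitivity re-runs just pass a smaller value).
#' @param bin window length (default 1000 bp).
#' @return Data frame, one row per window: `sub_id`, `type`, `rate`,
#'   `side`, `window`, `distance`, `eligible`, `polymorphic`, `gc`,
#'   `neutral`, `prop_coding`, `prop_nonsyn`. Attribute `"truncated"`
#'   lists substitutions with dropped windows.
#' @export
build_windows <- function(substitutions, sites, map_intervals = NULL,
                          span = 60000L, bin = 1000L) {
  stopifnot(all(c("pos", "type") %in% names(substitutions)))
  if (is.unsorted(substitutions$pos)) stop("substitutions must be sorted by position")
  L <- max(sites$pos)
  k <- span %/% bin
  nonsyn_pos <- substitutions$pos[substitutions$type == "nonsynonymous"]
  rows <- list(); truncated <- integer(0)
  for (i in seq_len(nrow(substitutions))) {
    p <- substitutions$pos[i]
    rate <- if (!is.null(substitutions$rate)) substitutions$rate[i]
            else local_rate(p, map_intervals)
    for (side in c(-1L, 1L)) {
      for (j in seq_len(k)) {
        if (side < 0L) { lo <- p - j * bin; hi <- p - (j - 1L) * bin - 1L }
        else { lo <- p + (j - 1L) * bin + 1L; hi <- p + j * bin }
        if (lo < 1L || hi > L) { truncated <- c(truncated, i); next }
        ss <- sites[sites$pos >= lo & sites$pos <= hi, , drop = FALSE]
        rows[[length(rows) + 1L]] <- data.frame(
          sub_id = i, type = substitutions$type[i], rate = rate,
          side = side, window = j, distance = (j - 0.5) * bin,
          eligible = sum(ss$eligible),
          polymorphic = sum(ss$polymorphic),
          gc = mean(ss$gc_base, na.rm = TRUE),
          neutral = mean(ss$proxy_diff[ss$eligible], na.rm = TRUE),
          prop_coding = mean(ss$coding),
          prop_nonsyn = sum(nonsyn_pos >= lo & nonsyn_pos <= hi) / bin,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "truncated") <- unique(truncated)
  out
}

#' Drop windows with too few eligible sites
#'
#' Any window with fewer than `min_eligible` eligible 4-fold degenerate
#' sites is excluded (strictly: a window with exactly `min_eligible` sites
#' is retained).
#'
#' @param windows window table.
#' @param min_eligible threshold (default 75 per 1,000 bp window).
#' @return Filtered table; attribute `"removed"` holds the removal count.
#' @export
filter_windows <- function(windows, min_eligible = 75L) {
  keep <- windows$eligible >= min_eligible
  out <- windows[keep, , drop = FALSE]
  attr(out, "removed") <- sum(!keep)
  out
}

#' Drop substitutions with too few surviving windows
#'
#' Applied after [filter_windows()]: substitutions retaining fewer than
#' `min_windows` windows are removed entirely (both nonsynonymous and
#' synonymous streams).
#'
#' @param windows window table (already window-filtered).
#' @param min_windows threshold (default 10).
#' @return Filtered table; attribute `"removed_subs"` lists dropped ids.
#' @export
filter_substitutions <- function(windows, min_windows = 10L) {
  if (nrow(windows) == 0L) {
    attr(windows, "removed_subs") <- integer(0)
    return(windows)
  }
  cnt <- table(windows$sub_id)
  bad <- as.integer(names(cnt)[cnt < min_windows])
  out <- windows[!windows$sub_id %in% bad, , drop = FALSE]
  attr(out, "removed_subs") <- bad
  out
}

#' Standardize model covariates to mean zero and unit variance
#'
#' Transforms each listed covariate to z-scores over the retained records
#' and emits the (mean, sd) reference table needed to interpret or
#' back-transform the standardized estimates. Zero-variance covariates are
#' left unstandardized and flagged.
#'
#' @param records window (or gene) table with >= 2 rows.
#' @param covariates character vector of column names to standardize.
#' @return The table with standardized columns; attribute
#'   `"standardization"` is a data frame of `covariate`, `mean`, `sd`,
#'   `constant`.
#' @export
standardize_covariates <- function(records,
                                   covariates = c("eligible", "gc", "neutral",
                                                  "prop_coding", "prop_nonsyn",
                                                  "distance", "rate")) {
  if (nrow(records) < 2L) stop("need at least 2 records")
  ref <- data.frame(covariate = covariates, mean = NA_real_, sd = NA_real_,
                    constant = FALSE, stringsAsFactors = FALSE)
  for (k in seq_along(covariates)) {
    v <- records[[covariates[k]]]
    mu <- mean(v); s <- sd(v)
    ref$mean[k] <- mu; ref$sd[k] <- s
    if (is.na(s) || s == 0) {
      ref$constant[k] <- TRUE
    } else {
      records[[covariates[k]]] <- (v - mu) / s
    }
  }
  attr(records, "standardization") <- ref
  records
}
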