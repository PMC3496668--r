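#' Backcross simulation scenario
#'
#' Defines the ground truth for a simulated backcross: one true
#' recombination fraction per marker interval (proportion of meioses with
#' an exchange in that interval), the number of backcross progeny, and the
#' per-call genotyping-error and missing rates.
#'
#' @param r numeric vector of true per-interval recombination fractions,
#'   each in `[0, 0.5)`.
#' @param individuals number of backcross progeny (>= 1).
#' @param error_rate probability that a single call is flipped, in `[0, 1)`.
#' @param missing_rate probability that a single call is masked, in `[0, 1)`.
#' @param interference if `TRUE`, suppress double crossovers whose interval
#'   midpoints lie within 2 Mb of each other (crossover interference is
#'   strong at that scale; the default model draws intervals independently).
#' @param seed integer seed; identical scenario + seed gives identical data.
#' @return A list of class `"cross_scenario"`.
#' @export
cross_scenario <- function(r, individuals, error_rate = 0, missing_rate = 0,
                           interference = FALSE, seed = NULL) {
  if (any(r < 0) || any(r >= 0.5)) stop("recombination fractions must lie in [0, 0.5)")
  if (individuals < 1) stop("individuals must be >= 1")
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must lie in [0, 1)")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must lie in [0, 1)")
  structure(list(r = r, individuals = as.integer(individuals),
                 error_rate = error_rate, missing_rate = missing_rate,
                 interference = isTRUE(interference), seed = seed),
            class = "cross_scenario")
}

#' Simulate backcross genotypes with known crossovers
#'
#' Each individual starts in a random parental state; the state flips
#' between adjacent markers with the interval's true recombination
#' fraction, independently across intervals (optionally suppressing double
#' crossovers within 2 Mb). Genotyping errors then flip single calls and
#' missing calls are masked. The true crossover indicators are returned
#' alongside the observed matrix so downstream estimates can be checked
#' against ground truth.
#'
#' @param scenario a [cross_scenario()].
#' @param markers a [marker_map()] with `length(scenario$r) + 1` markers.
#' @return A list with `genotypes` (a [genotype_matrix()] of observed
#'   calls), `truth` (list: `states` error-free matrix, `crossovers`
#'   individuals x intervals 0/1 matrix, `events` per-interval totals), and
#'   the scenario.
#' @export
simulate_backcross <- function(scenario, markers) {
  stopifnot(inherits(scenario, "cross_scenario"))
  if (!inherits(markers, "marker_map"))
    markers <- marker_map(markers$chrom, markers$marker, markers$pos)
  k <- length(scenario$r)
  if (nrow(markers) != k + 1L)
    stop(sprintf("marker count (%d) must equal interval count + 1 (%d)",
                 nrow(markers), k + 1L))
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  n <- scenario$individuals
  flips <- matrix(0L, n, k)
  for (j in seq_len(k)) flips[, j] <- rbinom(n, 1L, scenario$r[j])
  if (scenario$interference && k > 1L) {
    mids <- (markers$pos[-1L] + markers$pos[-nrow(markers)]) / 2
    last_mid <- rep(-Inf, n)
    for (j in seq_len(k)) {
      hit <- flips[, j] == 1L
      too_close <- hit & (mids[j] - last_mid) < 2e6
      flips[too_close, j] <- 0L
      last_mid[hit & !too_close] <- mids[j]
    }
  }
  start <- rbinom(n, 1L, 0.5)
  states <- matrix(0L, n, k + 1L)
  states[, 1L] <- start
  for (j in seq_len(k)) states[, j + 1L] <- (states[, j] + flips[, j]) %% 2L
  storage.mode(states) <- "integer"
  obs <- states
  if (scenario$error_rate > 0) {
    err <- matrix(rbinom(length(obs), 1L, scenario$error_rate), n)
    obs <- (obs + err) %% 2L
  }
  if (scenario$missing_rate > 0) {
    miss <- matrix(rbinom(length(obs), 1L, scenario$missing_rate), n) == 1L
    obs[miss] <- NA_integer_
  }
  storage.mode(obs) <- "integer"
  list(genotypes = genotype_matrix(obs, markers),
       truth = list(states = states, crossovers = flips,
                    events = colSums(flips)),
       scenario = scenario)
}

#' Interval-table simulation scenario
#'
#' Defines the causal structure used to emulate interval-level diversity
#' and divergence: covariates per recombination interval and two sets of
#' linear-predictor coefficients on the logit scale, one for the diversity
#' stream and one for the divergence stream. The default plants a positive
#' recombination effect on diversity and none on divergence, the pattern
#' expected when recombination shapes diversity through selection at linked
#' sites rather than through mutagenesis.
#'
#' @param n_intervals number of intervals (default 27, the conserved-interval
#'   set size used in the downstream model).
#' @param intervals optional data frame with columns `rate` (cM/Mb), `gc`,
#'   `gene_density`, `mu` (neutral-mutation proxy), `eligible`; generated if
#'   omitted.
#' @param beta_div named coefficients `(intercept, recombination, gc,
#'   gene_density, mutation)` for the diversity stream.
#' @param beta_dvg same for the divergence stream (recombination defaults
#'   to 0).
#' @param dispersion overdispersion factor `phi >= 1`; 1 is pure binomial.
#'   Counts are drawn beta-binomially so the Pearson dispersion of a
#'   binomial GLM fitted to the output is approximately `phi`.
#' @param seed integer seed.
#' @return A list of class `"diversity_scenario"`.
#' @export
diversity_scenario <- function(n_intervals = 27L, intervals = NULL,
                               beta_div = c(intercept = qlogis(0.10),
                                            recombination = 0.10,
                                            gc = 1.0, gene_density = -0.3,
                                            mutation = 5),
                               beta_dvg = c(intercept = qlogis(0.04),
                                            recombination = 0,
                                            gc = 0.5, gene_density = -0.2,
                                            mutation = 8),
                               dispersion = 3, seed = NULL) {
  if (!all(is.finite(beta_div)) || !all(is.finite(beta_dvg)))
    stop("coefficients must be finite")
  if (dispersion < 1) stop("dispersion must be >= 1 (1 = pure binomial)")
  if (!is.null(intervals)) {
    stopifnot(all(c("rate", "gc", "gene_density", "mu", "eligible") %in%
                    names(intervals)))
    if (any(intervals$eligible < 1)) stop("eligible counts must be >= 1")
    if (any(intervals$gc < 0 | intervals$gc > 1) ||
        any(intervals$gene_density < 0 | intervals$gene_density > 1))
      stop("proportions must lie in [0, 1]")
  }
  structure(list(n_intervals = as.integer(n_intervals), intervals = intervals,
                 beta_div = beta_div, beta_dvg = beta_dvg,
                 dispersion = dispersion, seed = seed),
            class = "diversity_scenario")
}

## beta-binomial draw; phi parameterized so that phi = 1 is pure binomial
rbetabinom <- function(n, size, prob, phi) {
  rho <- (phi - 1) / pmax(size - 1, 1)
  out <- integer(n)
  plain <- rho <= 0 | prob <= 0 | prob >= 1
  if (any(plain)) out[plain] <- rbinom(sum(plain), size[plain], prob[plain])
  if (any(!plain)) {
    s <- 1 / rho[!plain] - 1
    p <- rbeta(sum(!plain), prob[!plain] * s, (1 - prob[!plain]) * s)
    out[!plain] <- rbinom(sum(!plain), size[!plain], p)
  }
  out
}

#' Simulate an interval-level diversity/divergence table
#'
#' Draws per-interval polymorphic-site counts around the inverse-logit of
#' the scenario's diversity linear predictor times the eligible-site count
#' (beta-binomially, with the stated overdispersion), and divergence counts
#' analogously from the divergence coefficients. The generating
#' coefficients are attached so model fits can be checked for recovery.
#'
#' @param scenario a [diversity_scenario()].
#' @return Data frame with one row per interval: `interval`, `rate`, `gc`,
#'   `gene_density`, `mu`, `eligible`, `polymorphic`, `divergence`;
#'   attribute `"truth"` holds the coefficient vectors.
#' @export
simulate_interval_table <- function(scenario) {
  stopifnot(inherits(scenario, "diversity_scenario"))
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  iv <- scenario$intervals
  if (is.null(iv)) {
    n <- scenario$n_intervals
    iv <- data.frame(rate = runif(n, 0, 8),
                     gc = runif(n, 0.35, 0.55),
                     gene_density = runif(n, 0.2, 0.8),
                     mu = runif(n, 0.02, 0.08),
                     eligible = as.integer(round(runif(n, 1500, 2500))))
  }
  n <- nrow(iv)
  lp <- function(b) {
    eta <- b[["intercept"]] + b[["recombination"]] * iv$rate + b[["gc"]] * iv$gc +
      b[["gene_density"]] * iv$gene_density + b[["mutation"]] * iv$mu
    if (any(!is.finite(eta))) stop("non-finite linear predictor")
    eta
  }
  p_div <- plogis(lp(scenario$beta_div))
  p_dvg <- plogis(lp(scenario$beta_dvg))
  out <- data.frame(interval = seq_len(n), iv,
                    polymorphic = rbetabinom(n, iv$eligible, p_div,
                                             scenario$dispersion),
                    divergence = rbetabinom(n, iv$eligible, p_dvg,
                                            scenario$dispersion))
  attr(out, "truth") <- list(beta_div = scenario$beta_div,
                             beta_dvg = scenario$beta_dvg,
                             dispersion = scenario$dispersion)
  out
}

#' Sweep-footprint simulation scenario
#'
#' Stand-in generative model for the dip in diversity around a fixed
#' substitution: the expected polymorphic fraction at distance `d` from a
#' substitution with local recombination rate `rho` is
#' `pi0 * (1 - c * exp(-d / L(rho)))` with trough length scale
#' `L(rho) = L0 / max(rho, rho_min)`, so troughs are deeper near the site
#' and wider where recombination is low. Synonymous-type substitutions use
#' their own (default zero) trough depth, giving a flat control stream.
#'
#' @param substitutions data frame with columns `pos` (bp), `type`
#'   (`"nonsynonymous"` or `"synonymous"`), `rate` (local cM/Mb); generated
#'   if omitted.
#' @param n_subs number of substitutions to generate when `substitutions`
#'   is omitted (half of each type).
#' @param pi0 baseline polymorphic fraction among eligible 4-fold sites.
#' @param depth trough depth `c` in `[0, 1]` for nonsynonymous sites.
#' @param syn_depth trough depth for synonymous sites (default 0).
#' @param L0 trough length scale in bp at 1 cM/Mb (> 0).
#' @param rho_min floor on the rate entering `L(rho)` (> 0).
#' @param eligible_mean mean eligible 4-fold sites per 1,000 bp window
#'   (Poisson-distributed per window).
#' @param span,bin half-width of the region and window length in bp.
#' @param seed integer seed.
#' @return A list of class `"footprint_scenario"`.
#' @export
footprint_scenario <- function(substitutions = NULL, n_subs = 30L, pi0 = 0.25,
                               depth = 0.5, syn_depth = 0, L0 = 20000,
                               rho_min = 0.1, eligible_mean = 200,
                               span = 60000, bin = 1000, seed = NULL) {
  if (depth < 0 || depth > 1 || syn_depth < 0 || syn_depth > 1)
    stop("trough depth must lie in [0, 1]")
  if (pi0 * (1 - depth) < 0 || pi0 < 0 || pi0 > 1) stop("invalid pi0")
  if (L0 <= 0) stop("L0 must be positive")
  if (rho_min <= 0) stop("rho_min must be positive")
  if (!is.null(substitutions))
    stopifnot(all(c("pos", "type", "rate") %in% names(substitutions)),
              all(substitutions$type %in% c("nonsynonymous", "synonymous")))
  structure(list(substitutions = substitutions, n_subs = as.integer(n_subs),
                 pi0 = pi0, depth = depth, syn_depth = syn_depth, L0 = L0,
                 rho_min = rho_min, eligible_mean = eligible_mean,
                 span = span, bin = bin, seed = seed),
            class = "footprint_scenario")
}

#' Expected polymorphic fraction of the footprint kernel
#'
#' @param d distance from the substitution (bp).
#' @param rate local recombination rate (cM/Mb).
#' @param scenario a [footprint_scenario()].
#' @param depth trough depth to use (defaults to the scenario's
#'   nonsynonymous depth).
#' @return Expected polymorphic fraction.
#' @export
footprint_kernel <- function(d, rate, scenario, depth = scenario$depth) {
  L <- scenario$L0 / pmax(rate, scenario$rho_min)
  scenario$pi0 * (1 - depth * exp(-d / L))
}

#' Simulate substitution-centred footprint windows
#'
#' Tiles 1,000 bp (by default) non-overlapping windows across `span` bp on
#' either side of each substitution, draws eligible-site counts per window,
#' and draws polymorphic-site counts binomially around the trough-kernel
#' expectation. Window covariates without a planted effect (GC, neutral
#' proxy, proportion coding, proportion nonsynonymous) are generated as
#' noise so the downstream model has its full design.
#'
#' @param scenario a [footprint_scenario()].
#' @return Data frame with one row per window: `sub_id`, `type`, `rate`,
#'   `distance` (bp, window midpoint to substitution), `eligible`,
#'   `polymorphic`, `gc`, `neutral`, `prop_coding`, `prop_nonsyn`;
#'   attribute `"truth"` holds the kernel parameters.
#' @export
simulate_footprint_region <- function(scenario) {
  stopifnot(inherits(scenario, "footprint_scenario"))
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  subs <- scenario$substitutions
  if (is.null(subs)) {
    n <- scenario$n_subs
    subs <- data.frame(pos = seq_len(n) * (2 * scenario$span + 1e5),
                       type = rep(c("nonsynonymous", "synonymous"),
                                  length.out = n),
                       rate = runif(n, 0.5, 5),
                       stringsAsFactors = FALSE)
  }
  k <- scenario$span %/% scenario$bin
  d_one_side <- scenario$bin * (seq_len(k) - 0.5)
  dist <- rep(d_one_side, 2L)                        # both sides pooled
  rows <- vector("list", nrow(subs))
  for (i in seq_len(nrow(subs))) {
    dep <- if (subs$type[i] == "nonsynonymous") scenario$depth else scenario$syn_depth
    nw <- length(dist)
    elig <- pmax(1L, rpois(nw, scenario$eligible_mean))
    pexp <- footprint_kernel(dist, subs$rate[i], scenario, depth = dep)
    rows[[i]] <- data.frame(sub_id = i, type = subs$type[i],
                            rate = subs$rate[i], distance = dist,
                            eligible = elig,
                            polymorphic = rbinom(nw, elig, pexp),
                            gc = runif(nw, 0.35, 0.55),
                            neutral = runif(nw, 0.02, 0.08),
                            prop_coding = runif(nw, 0, 0.8),
                            prop_nonsyn = rbinom(nw, 3, 0.2) / scenario$bin,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "truth") <- list(pi0 = scenario$pi0, depth = scenario$depth,
                             syn_depth = scenario$syn_depth, L0 = scenario$L0,
                             rho_min = scenario$rho_min)
  out
}
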