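#' Quasibinomial GLM with sequential deviance F-tests
#'
#' Fits the overdispersed logistic model for interval-level diversity (or
#' divergence): the response binds polymorphic to non-polymorphic eligible
#' sites, the dispersion is estimated as Pearson chi-square over residual
#' degrees of freedom, and each term is tested sequentially (type-I) with
#' an F statistic in a fixed term order — main effects gene density,
#' mutation proxy, recombination, GC, then the four two-way interactions.
#' Because sequential tests are order-dependent the order is part of the
#' model definition; the same machinery serves the diversity and the
#' divergence response, so the two streams share a formula.
#'
#' @param data interval table with columns for the response and covariates.
#' @param successes,failures column names (or a two-column matrix via
#'   `response`) for the bound count pair; default `polymorphic` and
#'   `eligible - polymorphic`.
#' @param terms character vector of model terms in testing order.
#' @return Object of class `"qb_fit"`: list with `fit` (the `glm`),
#'   `deviance_table` (term, df, deviance, residual df/deviance, F, p),
#'   `dispersion`, `coefficients`.
#' @export
fit_quasibinomial_glm <- function(data,
                                  successes = "polymorphic",
                                  failures = NULL,
                                  terms = c("gene_density", "mu", "rate", "gc",
                                            "gene_density:mu",
                                            "gene_density:rate",
                                            "mu:gc", "rate:gc")) {
  y1 <- data[[successes]]
  y0 <- if (is.null(failures)) data$eligible - y1 else data[[failures]]
  keep <- (y1 + y0) > 0
  if (!all(keep)) data <- data[keep, , drop = FALSE]
  y1 <- y1[keep]; y0 <- y0[keep]
  if (nrow(data) < 10L) warning("fewer than 10 intervals; F-tests will be weak")
  fml <- as.formula(paste("cbind(y1, y0) ~", paste(terms, collapse = " + ")))
  env <- list2env(as.list(data))
  env$y1 <- y1; env$y0 <- y0
  environment(fml) <- env
  fit <- glm(fml, family = quasibinomial(), data = env,
             control = list(epsilon = 1e-8, maxit = 50))
  if (!fit$converged) warning("quasibinomial IRLS did not converge")
  an <- anova(fit, test = "F")
  dt <- data.frame(term = rownames(an),
                   df = an$Df, deviance = an$Deviance,
                   resid_df = an$`Resid. Df`, resid_dev = an$`Resid. Dev`,
                   F = an$F, p = an$`Pr(>F)`, stringsAsFactors = FALSE)
  structure(list(fit = fit, deviance_table = dt,
                 dispersion = sum(residuals(fit, "pearson")^2) / fit$df.residual,
                 coefficients = coef(fit),
                 dropped = sum(!keep)),
            class = "qb_fit")
}

#' @export
print.qb_fit <- function(x, ...) {
  cat("Quasibinomial GLM (logit link), dispersion =",
      format(x$dispersion, digits = 4), "\n")
  dt <- x$deviance_table
  dt$deviance <- round(dt$deviance, 4); dt$resid_dev <- round(dt$resid_dev, 3)
  dt$F <- round(dt$F, 4); dt$p <- signif(dt$p, 4)
  print(dt, row.names = FALSE)
  invisible(x)
}

#' @export
coef.qb_fit <- function(object, ...) object$coefficients

mixed_fit_table <- function(fit) {
  sm <- summary(fit)$coefficients
  data.frame(term = rownames(sm), estimate = sm[, 1L], se = sm[, 2L],
             z = sm[, 3L], p = sm[, 4L], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Poisson mixed model for per-gene substitution counts
#'
#' Nonsynonymous substitution counts per gene are modelled with a Poisson
#' GLMM (log link): fixed effects for the gene's synonymous substitution
#' count (so genes with zero synonymous divergence stay in the model), GC
#' content, flanking gene density, the neutral-mutation proxy and the local
#' recombination rate; a random intercept per map interval absorbs the
#' pseudoreplication of multiple genes per interval. Fixed-effect p-values
#' use the normal reference for the Wald z.
#'
#' @param data gene table with columns `nonsyn`, `synonymous`, `gc`,
#'   `gene_density`, `mu`, `rate`, `interval`.
#' @return Object of class `"glmm_fit"`: list with `fit` (the `glmerMod`),
#'   `fixed` (term/estimate/se/z/p), `ranef_var`, `singular`.
#' @export
fit_poisson_glmm_genes <- function(data) {
  stopifnot(all(c("nonsyn", "synonymous", "gc", "gene_density", "mu", "rate",
                  "interval") %in% names(data)))
  if (length(unique(data$interval)) < 2L)
    stop("grouping factor needs at least 2 levels")
  fit <- lme4::glmer(nonsyn ~ synonymous + gc + gene_density + mu + rate +
                       (1 | interval),
                     data = data, family = stats::poisson())
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(fit = fit, fixed = mixed_fit_table(fit),
                 ranef_var = vc$vcov[1L],
                 grouping = "interval",
                 singular = lme4::isSingular(fit)),
            class = "glmm_fit")
}

#' Poisson mixed model for the sweep-footprint windows
#'
#' The trough model around substitutions: the number of polymorphic 4-fold
#' sites per 1,000 bp window, Poisson with log link, with standardized
#' fixed effects for eligible sites, GC, neutral proxy, proportion coding,
#' proportion nonsynonymous, absolute distance from the substitution,
#' local recombination rate, and the distance-by-recombination interaction
#' — whose sign and z-value are the headline outputs (a negative
#' interaction means diversity recovers at shorter distances where
#' recombination is high). Substitution identity is the random intercept.
#'
#' @param windows standardized window table (see
#'   [standardize_covariates()]) with columns `polymorphic`, `eligible`,
#'   `gc`, `neutral`, `prop_coding`, `prop_nonsyn`, `distance`, `rate`,
#'   `sub_id`.
#' @return Object of class `"glmm_fit"`; the interaction row is named
#'   `distance:rate`.
#' @export
fit_poisson_glmm_footprint <- function(windows) {
  stopifnot(all(c("polymorphic", "eligible", "gc", "neutral", "prop_coding",
                  "prop_nonsyn", "distance", "rate", "sub_id") %in%
                  names(windows)))
  if (length(unique(windows$sub_id)) < 2L)
    stop("need at least 2 substitutions")
  if (is.null(attr(windows, "standardization")))
    warning("covariates do not appear to be standardized; estimates will not be on the unit-sd scale")
  fit <- lme4::glmer(polymorphic ~ eligible + gc + neutral + prop_coding +
                       prop_nonsyn + distance + rate + distance:rate +
                       (1 | sub_id),
                     data = windows, family = stats::poisson())
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(fit = fit, fixed = mixed_fit_table(fit),
                 ranef_var = vc$vcov[1L],
                 grouping = "sub_id",
                 standardization = attr(windows, "standardization"),
                 singular = lme4::isSingular(fit)),
            class = "glmm_fit")
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat("Poisson GLMM (log link), random intercept by", x$grouping,
      sprintf("(var = %.4g%s)\n", x$ranef_var,
              if (isTRUE(x$singular)) ", singular fit" else ""))
  fx <- x$fixed
  fx$estimate <- round(fx$estimate, 6); fx$se <- round(fx$se, 6)
  fx$z <- round(fx$z, 2); fx$p <- signif(fx$p, 3)
  print(fx, row.names = FALSE)
  invisible(x)
}

#' @export
coef.glmm_fit <- function(object, ...) {
  setNames(object$fixed$estimate, object$fixed$term)
}
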