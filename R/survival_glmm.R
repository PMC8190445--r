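#' Survival model configuration
#'
#' The model of first-year survival is a binomial GLMM with logit link:
#' logit Pr(surv) = b0 + 100*f_long*b1 + 100*f_medium*b2 + 100*f_short*b3
#' + sex*b4 + twin*b5 + a_birthyear + a_motherid, with Normal random
#' intercepts for birth year and mother. The covariate scale factor of
#' 100 makes each coefficient the change in log-odds per 1% of genome in
#' the class. MCMC settings apply to the \code{"mcmc"} (JAGS) backend:
#' Normal(0, 5) priors on fixed effects and half-Student-t(3, 2.5) priors
#' on the group-level SDs, 4 chains of 10,000 iterations with 5,000
#' warmup by default, convergence flagged by Gelman-Rubin >= 1.1.
#'
#' @param scale covariate scale factor (100).
#' @param prior_sd fixed-effect prior SD.
#' @param st_df,st_scale half-Student-t hyperparameters for group SDs.
#' @param chains,iterations,warmup MCMC settings.
#' @return list of class \code{ModelConfig}.
#' @export
modelConfig <- function(scale = 100, prior_sd = 5, st_df = 3,
                        st_scale = 2.5, chains = 4, iterations = 10000,
                        warmup = 5000) {
  stopifnot(iterations > warmup, chains >= 2)
  structure(list(scale = scale, prior_sd = prior_sd, st_df = st_df,
                 st_scale = st_scale, chains = chains,
                 iterations = iterations, warmup = warmup),
            class = "ModelConfig")
}

.checkRecords <- function(records, terms) {
  need <- c("survived", "sex", "twin", "birth_year", "mother_id", terms)
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records missing column(s): ", paste(miss, collapse = ", "))
  drop <- is.na(records$mother_id)
  if (any(drop)) {
    message(sum(drop), " record(s) with missing mother dropped")
    records <- records[!drop, , drop = FALSE]
  }
  if (anyNA(records[need]))
    stop("missing values in model covariates")
  if (length(unique(records$birth_year)) < 2L ||
      length(unique(records$mother_id)) < 2L)
    stop("need at least 2 birth years and 2 mothers (single-level ",
         "grouping factor)")
  records
}

.fitGlmm <- function(records, covariates, config, backend, seed) {
  records <- .checkRecords(records, names(covariates))
  X <- cbind(`(Intercept)` = 1,
             as.matrix(records[names(covariates)]) %*%
               diag(covariates, length(covariates)))
  colnames(X) <- c("(Intercept)", names(covariates))
  # degenerate design: a constant non-intercept column cannot be estimated
  const <- apply(X[, -1, drop = FALSE], 2, function(v) sd(v) == 0)
  if (any(const))
    stop("constant covariate(s): ", paste(names(which(const)),
                                          collapse = ", "))
  X <- cbind(X, sex = records$sex, twin = records$twin)
  y <- records$survived
  yr <- factor(records$birth_year)
  mo <- factor(records$mother_id)

  if (backend == "glmer") {
    dat <- data.frame(y = y, X[, -1, drop = FALSE], yr = yr, mo = mo,
                      check.names = FALSE)
    f <- reformulate(c(sprintf("`%s`", colnames(X)[-1]), "(1|yr)", "(1|mo)"),
                     response = "y")
    fit <- lme4::glmer(f, data = dat, family = stats::binomial,
                       control = lme4::glmerControl(
                         optimizer = "bobyqa",
                         check.conv.grad = lme4::.makeCC("warning",
                                                         tol = 0.02)))
    beta <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    lower <- beta + qnorm(0.025) * se
    upper <- beta + qnorm(0.975) * se
    vc <- as.data.frame(lme4::VarCorr(fit))
    ranef_sd <- setNames(vc$sdcor[match(c("yr", "mo"), vc$grp)],
                         c("birth_year", "mother_id"))
    coefs <- data.frame(term = names(beta), estimate = unname(beta),
                        lower = unname(lower), upper = unname(upper),
                        rhat = NA_real_, stringsAsFactors = FALSE)
    coefs$term[coefs$term == "(Intercept)"] <- "(Intercept)"
    converged <- length(fit@optinfo$conv$lme4$messages) == 0L
  } else if (backend == "mcmc") {
    mstr <- "model {
      for (i in 1:n) {
        y[i] ~ dbern(p[i])
        logit(p[i]) <- inprod(X[i, ], beta) + ayr[yr[i]] + amo[mo[i]]
      }
      for (j in 1:J) { beta[j] ~ dnorm(0, prec_beta) }
      for (k in 1:K) { ayr[k] ~ dnorm(0, tau_yr) }
      for (l in 1:L) { amo[l] ~ dnorm(0, tau_mo) }
      sd_yr ~ dt(0, prec_t, df_t) T(0,)
      sd_mo ~ dt(0, prec_t, df_t) T(0,)
      tau_yr <- pow(sd_yr, -2)
      tau_mo <- pow(sd_mo, -2)
    }"
    dat <- list(y = y, X = X, n = length(y), J = ncol(X),
                yr = as.integer(yr), mo = as.integer(mo),
                K = nlevels(yr), L = nlevels(mo),
                prec_beta = 1 / config$prior_sd^2,
                prec_t = 1 / config$st_scale^2, df_t = config$st_df)
    inits <- lapply(seq_len(config$chains), function(ch) list(
      .RNG.name = "base::Mersenne-Twister",
      .RNG.seed = seed + ch))
    jm <- rjags::jags.model(textConnection(mstr), data = dat, inits = inits,
                            n.chains = config$chains, quiet = TRUE)
    update(jm, config$warmup, progress.bar = "none")
    samp <- rjags::coda.samples(jm, c("beta", "sd_yr", "sd_mo"),
                                n.iter = config$iterations - config$warmup,
                                progress.bar = "none")
    sm <- summary(samp)
    qs <- sm$quantiles
    means <- sm$statistics[, "Mean"]
    gd <- try(coda::gelman.diag(samp, autoburnin = FALSE,
                                multivariate = FALSE)$psrf[, 1], TRUE)
    if (inherits(gd, "try-error")) gd <- rep(NA_real_, length(means))
    bn <- paste0("beta[", seq_len(ncol(X)), "]")
    coefs <- data.frame(term = colnames(X), estimate = means[bn],
                        lower = qs[bn, "2.5%"], upper = qs[bn, "97.5%"],
                        rhat = gd[bn], stringsAsFactors = FALSE)
    ranef_sd <- c(birth_year = unname(means["sd_yr"]),
                  mother_id = unname(means["sd_mo"]))
    converged <- all(is.na(gd) | gd < 1.1)
    if (!converged)
      warning("Gelman-Rubin >= 1.1 for some parameter(s); ",
              "fit flagged as non-converged")
  } else stop("unknown backend: ", backend)

  coefs$or <- exp(coefs$estimate)
  coefs$or_lower <- exp(coefs$lower)
  coefs$or_upper <- exp(coefs$upper)
  rownames(coefs) <- NULL
  new("SurvivalFit", coefficients = coefs, ranef_sd = ranef_sd,
      backend = backend, converged = converged, n = nrow(records))
}

#' Fit the survival model on three length-class inbreeding coefficients
#'
#' Fits logit Pr(surv) = b0 + 100 f_long b1 + 100 f_medium b2 +
#' 100 f_short b3 + sex b4 + twin b5 + a_birthyear + a_motherid. The
#' \code{"mcmc"} backend (JAGS) samples the posterior under the priors in
#' [modelConfig()] and reports posterior means with 2.5/97.5 percentile
#' intervals and Gelman-Rubin diagnostics. The \code{"glmer"} backend
#' (lme4, Laplace maximum likelihood) is a fast alternative reporting
#' Wald 95\% intervals; with the weak default priors and cohort-scale n
#' the two agree closely.
#'
#' @param records data.frame with columns \code{survived}, \code{sex},
#'   \code{twin}, \code{birth_year}, \code{mother_id}, \code{f_long},
#'   \code{f_medium}, \code{f_short} (proportions in [0,1]).
#' @param config a [modelConfig()].
#' @param backend "mcmc" or "glmer".
#' @param seed seed for the MCMC chains.
#' @return A [SurvivalFit-class].
#' @export
fitSurvivalModel <- function(records, config = modelConfig(),
                             backend = c("mcmc", "glmer"), seed = 1) {
  backend <- match.arg(backend)
  covs <- setNames(rep(config$scale, 3), c("f_long", "f_medium", "f_short"))
  .fitGlmm(records, covs, config, backend, seed)
}

#' Fit the alternative model: overall F_ROH plus mean ROH length
#'
#' Replaces the three class coefficients with 100*f_total and the
#' individual's mean ROH length in cM (a per-cM effect).
#'
#' @inheritParams fitSurvivalModel
#' @export
fitAlternativeModel <- function(records, config = modelConfig(),
                                backend = c("mcmc", "glmer"), seed = 1) {
  backend <- match.arg(backend)
  covs <- setNames(c(config$scale, 1), c("f_total", "mean_roh_length_cm"))
  .fitGlmm(records, covs, config, backend, seed)
}

#' Odds-ratio report table
#'
#' One row per fixed effect: odds ratio (exp of the coefficient), its
#' 95\% interval, and the percent change in the odds of survival,
#' 100 * (1 - OR), reported for odds reductions (OR < 1).
#'
#' @param fit a [SurvivalFit-class].
#' @return data.frame: \code{term}, \code{or}, \code{or_lower},
#'   \code{or_upper}, \code{percent_reduction}.
#' @examples
#' ## an OR of 0.876 is a 12.4% reduction in the odds of survival
#' @export
oddsRatioTable <- function(fit) {
  co <- fit@coefficients
  data.frame(term = co$term, or = co$or, or_lower = co$or_lower,
             or_upper = co$or_upper,
             percent_reduction = ifelse(co$or < 1, 100 * (1 - co$or), 0),
             stringsAsFactors = FALSE)
}
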