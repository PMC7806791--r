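# Voxel-wise growth-trajectory inference on log-Jacobian maps.
#
# The working model at each voxel x is the linear mixed-effects model
#   J_i(x) = g0_i + g0_site + b0 + b1*age + b2*age^2 + b3*group
#            + b4*(group x age) + b5*sex + e
# with random intercepts for subject and acquisition site, fitted by
# maximum likelihood (ML, not REML) so that nested fixed-effect structures
# can be compared with log-likelihood ratio tests. Age enters centred (at
# 183 days by default, i.e. 6 months) and scaled to years for numerical
# conditioning; group uses dummy coding against a reference level, so the
# group x age coefficients are growth-rate differences per year.

FIXED_TERM_SET <- c("age", "age2", "age3", "group", "sex", "site",
                    "group:age", "sex:age")
RANDOM_TERM_SET <- c("subject_intercept", "subject_slope", "site_intercept")

#' Specify a voxel-wise growth model
#'
#' @param fixed character vector of fixed-effect terms, drawn from
#'   `"age"`, `"age2"`, `"age3"`, `"group"`, `"sex"`, `"site"`,
#'   `"group:age"`, `"sex:age"`. The intercept is always present.
#'   Interaction terms require their main effects.
#' @param random random-effect terms, drawn from `"subject_intercept"`,
#'   `"subject_slope"`, `"site_intercept"`. `"site"` as a fixed effect and
#'   `"site_intercept"` are mutually exclusive.
#' @param age_center_days age (days) subtracted before modelling; the
#'   default 183 centres the model at 6 months, where group main effects
#'   are evaluated.
#' @param age_scale_days divisor applied after centring (365.25: age in
#'   years since the centre).
#' @param group_ref reference group for dummy coding.
#' @return An object of class `gm_model_spec`.
#' @export
model_spec <- function(fixed = c("age", "age2", "group", "group:age", "sex"),
                       random = c("subject_intercept", "site_intercept"),
                       age_center_days = 183,
                       age_scale_days = 365.25,
                       group_ref = "LR-") {
  bad <- setdiff(fixed, FIXED_TERM_SET)
  if (length(bad)) stop("unknown fixed term(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(random, RANDOM_TERM_SET)
  if (length(bad)) stop("unknown random term(s): ", paste(bad, collapse = ", "))
  if ("group:age" %in% fixed && !all(c("group", "age") %in% fixed))
    stop("group:age requires the group and age main effects")
  if ("sex:age" %in% fixed && !all(c("sex", "age") %in% fixed))
    stop("sex:age requires the sex and age main effects")
  if ("age2" %in% fixed && !"age" %in% fixed)
    stop("age2 requires the age main effect")
  if ("age3" %in% fixed && !"age2" %in% fixed)
    stop("age3 requires the age2 term")
  if ("site" %in% fixed && "site_intercept" %in% random)
    stop("site cannot be both a fixed and a random effect")
  structure(list(fixed = fixed, random = random,
                 age_center_days = age_center_days,
                 age_scale_days = age_scale_days,
                 group_ref = group_ref),
            class = "gm_model_spec")
}

#' @export
print.gm_model_spec <- function(x, ...) {
  cat(sprintf("<gm_model_spec fixed: 1 + %s | random: %s>\n",
              paste(x$fixed, collapse = " + "),
              if (length(x$random)) paste(x$random, collapse = " + ")
              else "(none)"))
  invisible(x)
}

spec_nested_in <- function(a, b) {
  all(a$fixed %in% b$fixed) && setequal(a$random, b$random) &&
    a$age_center_days == b$age_center_days &&
    a$age_scale_days == b$age_scale_days
}

model_frame <- function(cohort, spec) {
  stopifnot(inherits(cohort, "gm_cohort"), inherits(spec, "gm_model_spec"))
  grp_levels <- c(spec$group_ref,
                  setdiff(intersect(GROUP_LEVELS, unique(cohort$group)),
                          spec$group_ref))
  data.frame(
    subject_id = factor(cohort$subject_id),
    group = factor(cohort$group, levels = grp_levels),
    sex = factor(cohort$sex, levels = c("F", "M")),
    site = factor(cohort$site),
    age_c = (cohort$age_days - spec$age_center_days) / spec$age_scale_days)
}

spec_formula <- function(spec) {
  term_map <- c(age = "age_c", age2 = "I(age_c^2)", age3 = "I(age_c^3)",
                group = "group", sex = "sex", site = "site",
                `group:age` = "group:age_c", `sex:age` = "sex:age_c")
  rhs <- c("1", unname(term_map[spec$fixed]))
  ran <- character(0)
  subj <- intersect(spec$random, c("subject_intercept", "subject_slope"))
  if (length(subj)) {
    inner <- if (setequal(subj, "subject_intercept")) "1"
    else if (setequal(subj, "subject_slope")) "0 + age_c"
    else "1 + age_c"
    ran <- c(ran, sprintf("(%s | subject_id)", inner))
  }
  if ("site_intercept" %in% spec$random) ran <- c(ran, "(1 | site)")
  as.formula(paste("y ~", paste(c(rhs, ran), collapse = " + ")))
}

check_design_rank <- function(X) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  invisible(TRUE)
}

extract_fit <- function(fit, spec, n) {
  if (inherits(fit, "merMod")) {
    beta <- lme4::fixef(fit)
    V <- as.matrix(vcov(fit))
    vc <- lme4::VarCorr(fit)
    s2_subj <- if ("subject_id" %in% names(vc))
      as.numeric(vc$subject_id)[1] else 0
    s2_site <- if ("site" %in% names(vc)) as.numeric(vc$site)[1] else 0
    s2_res <- stats::sigma(fit)^2
    ll <- as.numeric(stats::logLik(fit))
    conv <- length(fit@optinfo$conv$lme4$messages) == 0L
  } else {
    beta <- coef(fit)
    # ML (not unbiased) scaling; vcov warns on zero-residual perfect fits
    V <- suppressWarnings(stats::vcov(fit)) * (fit$df.residual / n)
    s2_subj <- 0; s2_site <- 0
    s2_res <- sum(stats::residuals(fit)^2) / n
    ll <- as.numeric(stats::logLik(fit))
    conv <- TRUE
  }
  se <- sqrt(diag(V))
  df <- n - length(beta)
  t <- beta / se
  structure(list(beta = beta, se = se, t = t,
                 p = 2 * pt(abs(t), df, lower.tail = FALSE),
                 df_coef = setNames(rep(df, length(beta)), names(beta)),
                 vcov_beta = V,
                 sigma2_subject = s2_subj, sigma2_site = s2_site,
                 sigma2_resid = s2_res,
                 loglik = ll, df = df, n = n, n_fixed = length(beta),
                 spec = spec, converged = conv),
            class = "gm_voxel_fit")
}

#' @export
print.gm_voxel_fit <- function(x, ...) {
  cat(sprintf("<gm_voxel_fit n = %d, logLik = %.3f, df = %d>\n",
              x$n, x$loglik, x$df))
  tab <- cbind(beta = x$beta, se = x$se, t = x$t, p = x$p)
  print(round(tab, 5))
  cat(sprintf("variance components: subject %.4g, site %.4g, residual %.4g\n",
              x$sigma2_subject, x$sigma2_site, x$sigma2_resid))
  invisible(x)
}

#' Fit the growth model at a single voxel
#'
#' Maximum-likelihood fit of the mixed model defined by `spec` to the
#' per-scan values `y` (one value per cohort row). With no random terms an
#' ordinary ML linear model is fitted instead.
#'
#' @param y numeric vector, `length(y) == nrow(cohort)`.
#' @param cohort a `gm_cohort`.
#' @param spec a [model_spec()].
#' @param REML fit by REML instead of ML. The default is ML because
#'   fixed-effect likelihood-ratio tests require it; REML is the usual
#'   choice when the goal is interval estimation.
#' @param ddf degrees-of-freedom method for t-statistics and p-values:
#'   `"residual"` (`n - n_fixed`) or `"satterthwaite"` (per-coefficient,
#'   via lmerTest; recommended with few sites, where between-cluster
#'   contrasts have far fewer effective df).
#' @return A `gm_voxel_fit`: fixed-effect estimates `beta`, standard errors
#'   `se`, `t`, two-sided `p`, per-coefficient df vector `df_coef`,
#'   variance components, `loglik` (of the chosen criterion), `df`, and
#'   `converged`.
#' @export
fit_lmm <- function(y, cohort, spec = model_spec(), REML = FALSE,
                    ddf = c("residual", "satterthwaite")) {
  ddf <- match.arg(ddf)
  if (length(y) != nrow(cohort))
    stop("length(y) must equal nrow(cohort)")
  df <- model_frame(cohort, spec)
  df$y <- y
  if (any(c("subject_intercept", "subject_slope") %in% spec$random)) {
    nobs <- table(df$subject_id)
    if (sum(nobs >= 2L) < 2L)
      stop("subject random effects need at least 2 subjects with 2+ observations")
  }
  form <- spec_formula(spec)
  fixed_form <- lme4::nobars(form)
  X <- stats::model.matrix(fixed_form[-2], df)
  check_design_rank(X)
  if (length(spec$random) == 0L) {
    fit <- lm(fixed_form, data = df)
    out <- extract_fit(fit, spec, nrow(df))
    return(out)
  }
  fit <- suppressMessages(lme4::lmer(
    form, data = df, REML = REML,
    control = lme4::lmerControl(calc.derivs = FALSE,
                                check.conv.singular = "ignore")))
  out <- extract_fit(fit, spec, nrow(df))
  if (ddf == "satterthwaite") {
    if (!requireNamespace("lmerTest", quietly = TRUE))
      stop("ddf = 'satterthwaite' requires the lmerTest package")
    mt <- lmerTest::as_lmerModLmerTest(fit)
    ct <- stats::coef(summary(mt, ddf = "Satterthwaite"))
    df_coef <- setNames(ct[, "df"], rownames(ct))[names(out$beta)]
    out$df_coef <- df_coef
    out$p <- 2 * pt(abs(out$t), df_coef, lower.tail = FALSE)
  } else {
    out$df_coef <- setNames(rep(out$df, length(out$beta)), names(out$beta))
  }
  out
}

#' Log-likelihood ratio test of nested voxel fits
#'
#' @param null_fit,full_fit `gm_voxel_fit`s of nested model specifications
#'   (same observations, same random structure, null fixed terms a subset
#'   of the full ones), both fitted by ML.
#' @return List with `stat` (`2 * (llf - ll0)`, clamped at 0), `df_diff`
#'   (difference in fixed-effect count) and chi-squared `p`.
#' @export
lrt <- function(null_fit, full_fit) {
  stopifnot(inherits(null_fit, "gm_voxel_fit"),
            inherits(full_fit, "gm_voxel_fit"))
  if (null_fit$n != full_fit$n)
    stop("fits use different numbers of observations")
  if (!spec_nested_in(null_fit$spec, full_fit$spec))
    stop("null model is not nested in the full model")
  df_diff <- full_fit$n_fixed - null_fit$n_fixed
  stat <- max(0, 2 * (full_fit$loglik - null_fit$loglik))
  p <- if (df_diff == 0L) as.numeric(stat <= 0) else
    pchisq(stat, df_diff, lower.tail = FALSE)
  list(stat = stat, df_diff = df_diff, p = p)
}

stack_matrix <- function(stack) {
  if (is.list(stack) && !is.null(stack$data)) stack <- stack$data
  stopifnot(is.array(stack), length(dim(stack)) == 4L)
  d <- dim(stack)
  list(Y = matrix(stack, nrow = prod(d[1:3])), dim3 = d[1:3],
       n_scans = d[4])
}

#' Fit the growth model at every voxel of a log-Jacobian stack
#'
#' One mixed-model fit per in-mask voxel (a prototype lme4 fit is reused
#' via `refit` for speed). Produces a t-map per fixed-effect coefficient
#' and, when `group:age` is in the model, the pairwise growth-rate
#' contrast between the two non-reference groups.
#'
#' @param stack 4-D array `(nx, ny, nz, n_scans)` (or the list returned by
#'   [read_stack()]); the 4th dimension must follow cohort row order.
#' @param cohort a `gm_cohort` with one row per stack volume.
#' @param spec a [model_spec()].
#' @param mask logical 3-D array (or `gm_volume`); default all voxels.
#' @param grid optional `gm_grid` for the output maps.
#' @param verbose print progress.
#' @return An object of class `gm_voxel_stats`: named lists `tmaps` and
#'   `pmaps` of `gm_volume`s (one per non-intercept coefficient plus
#'   derived pairwise contrasts), coefficient arrays `beta`, `se`,
#'   variance-component arrays, `loglik` vector, scalar `df`, the `mask`,
#'   and bookkeeping fields.
#' @export
fit_voxelwise <- function(stack, cohort, spec = model_spec(), mask = NULL,
                          grid = NULL, verbose = FALSE) {
  sm <- stack_matrix(stack)
  if (is.list(stack) && !is.null(stack$grid) && is.null(grid))
    grid <- stack$grid
  if (is.null(grid)) grid <- gm_grid(sm$dim3)
  if (sm$n_scans != nrow(cohort))
    stop("stack has ", sm$n_scans, " volumes but cohort has ",
         nrow(cohort), " rows")
  if (is.null(mask)) {
    mask <- array(TRUE, sm$dim3)
  } else {
    if (inherits(mask, "gm_volume")) mask <- mask$data != 0
    mask <- array(as.logical(mask), sm$dim3)
  }
  vox <- which(mask)
  if (!length(vox)) stop("mask is empty")
  frame <- model_frame(cohort, spec)
  frame$y <- sm$Y[vox[1], ]
  form <- spec_formula(spec)
  fixed_form <- lme4::nobars(form)
  X <- stats::model.matrix(fixed_form[-2], frame)
  check_design_rank(X)
  n <- nrow(frame)
  use_lmm <- length(spec$random) > 0L
  if (use_lmm) {
    proto <- suppressMessages(lme4::lmer(
      form, data = frame, REML = FALSE,
      control = lme4::lmerControl(calc.derivs = FALSE,
                                  check.conv.singular = "ignore")))
    cn <- names(lme4::fixef(proto))
  } else {
    cn <- colnames(X)
  }
  p <- length(cn)
  df <- n - p
  nv <- length(vox)
  beta <- matrix(NA_real_, nv, p, dimnames = list(NULL, cn))
  se <- matrix(NA_real_, nv, p, dimnames = list(NULL, cn))
  s2 <- matrix(NA_real_, nv, 3,
               dimnames = list(NULL, c("subject", "site", "resid")))
  ll <- numeric(nv)
  has_ia <- "group:age" %in% spec$fixed
  grp_alt <- levels(frame$group)[-1]
  ia_col_of <- function(g) {
    cand <- c(paste0("group", g, ":age_c"), paste0("age_c:group", g))
    cand[cand %in% cn][1]
  }
  ia_cols <- if (has_ia && length(grp_alt) == 2L)
    vapply(grp_alt, ia_col_of, character(1)) else NULL
  cdiff <- numeric(p)
  if (!is.null(ia_cols) && !anyNA(ia_cols)) {
    cdiff[match(ia_cols[2], cn)] <- 1
    cdiff[match(ia_cols[1], cn)] <- -1
  } else ia_cols <- NULL
  ct_est <- ct_se <- rep(NA_real_, nv)
  n_nonconv <- 0L
  if (use_lmm) {
    # slot-level extraction: vcov()/VarCorr()/logLik() S4 dispatch is the
    # bottleneck at thousands of refits
    th_names <- names(lme4::getME(proto, "theta"))
    i_subj <- match("subject_id.(Intercept)", th_names)
    i_site <- match("site.(Intercept)", th_names)
    for (i in seq_len(nv)) {
      m <- suppressWarnings(suppressMessages(
        lme4::refit(proto, sm$Y[vox[i], ])))
      if (length(m@optinfo$conv$lme4$messages))
        n_nonconv <- n_nonconv + 1L
      dc <- m@devcomp$cmp
      sig2 <- dc[["pwrss"]] / n
      unsc <- m@pp$unsc()
      beta[i, ] <- m@beta
      se[i, ] <- sqrt(sig2 * diag(unsc))
      s2[i, ] <- c(if (is.na(i_subj)) 0 else sig2 * m@theta[i_subj]^2,
                   if (is.na(i_site)) 0 else sig2 * m@theta[i_site]^2,
                   sig2)
      ll[i] <- -dc[["dev"]] / 2
      if (!is.null(ia_cols)) {
        ct_est[i] <- sum(cdiff * m@beta)
        ct_se[i] <- sqrt(sig2 * drop(t(cdiff) %*% unsc %*% cdiff))
      }
      if (verbose && i %% 500L == 0L)
        message(sprintf("  voxel %d / %d", i, nv))
    }
  } else {
    # no random terms: one vectorised least-squares solve for all voxels
    Yt <- t(sm$Y[vox, , drop = FALSE])
    qr_x <- qr(X)
    B <- qr.coef(qr_x, Yt)
    res <- Yt - X %*% B
    rss <- colSums(res^2)
    s2v <- rss / n
    XtXinv <- chol2inv(qr.R(qr_x))
    beta[] <- t(B)
    se[] <- sqrt(outer(rss / n, diag(XtXinv)))
    s2[, "resid"] <- s2v
    s2[, c("subject", "site")] <- 0
    ll <- -n / 2 * (log(2 * pi) + log(s2v) + 1)
    if (!is.null(ia_cols)) {
      ct_est <- colSums(cdiff * B)
      ct_se <- sqrt(drop(t(cdiff) %*% XtXinv %*% cdiff) * s2v)
    }
  }
  tmat <- beta / se
  effect_names <- setdiff(cn, "(Intercept)")
  tmaps <- list(); pmaps <- list()
  for (nm in effect_names) {
    tv <- array(0, sm$dim3); tv[vox] <- tmat[, nm]
    pv <- array(1, sm$dim3)
    pv[vox] <- 2 * pt(abs(tmat[, nm]), df, lower.tail = FALSE)
    tm <- as_volume(tv, grid$spacing, grid$affine, modality = "stat")
    attr(tm, "df") <- df; attr(tm, "contrast") <- nm
    tmaps[[nm]] <- tm
    pmaps[[nm]] <- pv
  }
  if (!is.null(ia_cols)) {
    nm <- sprintf("group:age %s vs %s", grp_alt[2], grp_alt[1])
    tv <- array(0, sm$dim3); tv[vox] <- ct_est / ct_se
    pv <- array(1, sm$dim3)
    pv[vox] <- 2 * pt(abs(ct_est / ct_se), df, lower.tail = FALSE)
    tm <- as_volume(tv, grid$spacing, grid$affine, modality = "stat")
    attr(tm, "df") <- df; attr(tm, "contrast") <- nm
    tmaps[[nm]] <- tm
    pmaps[[nm]] <- pv
    attr(tmaps[[nm]], "derived") <- TRUE
  }
  structure(list(tmaps = tmaps, pmaps = pmaps, beta = beta, se = se,
                 sigma2 = s2, loglik = ll, df = df, mask = mask,
                 voxels = vox, grid = grid, spec = spec, n = n,
                 coef_names = cn, n_nonconverged = n_nonconv,
                 derived_maps = if (is.null(ia_cols)) character(0)
                 else sprintf("group:age %s vs %s", grp_alt[2], grp_alt[1])),
            class = "gm_voxel_stats")
}

#' @export
print.gm_voxel_stats <- function(x, ...) {
  cat(sprintf("<gm_voxel_stats %d voxels, %d scans, df = %d>\n  maps: %s\n",
              length(x$voxels), x$n, x$df,
              paste(names(x$tmaps), collapse = ", ")))
  invisible(x)
}

voxelwise_loglik <- function(stack, cohort, spec, mask = NULL) {
  fit_voxelwise(stack, cohort, spec, mask = mask)$loglik
}

#' Default forward-selection ladder
#'
#' The nested candidate sequence used for growth-model selection:
#' age; + age^2; + group; + group x age; + sex — each with random
#' intercepts for subject and site.
#'
#' @inheritParams model_spec
#' @return List of [model_spec()]s ordered simple to complex.
#' @export
default_candidate_specs <- function(random = c("subject_intercept",
                                               "site_intercept"),
                                    age_center_days = 183,
                                    age_scale_days = 365.25,
                                    group_ref = "LR-") {
  ladders <- list(
    c("age"),
    c("age", "age2"),
    c("age", "age2", "group"),
    c("age", "age2", "group", "group:age"),
    c("age", "age2", "group", "group:age", "sex"))
  lapply(ladders, function(fx)
    model_spec(fx, random = random, age_center_days = age_center_days,
               age_scale_days = age_scale_days, group_ref = group_ref))
}

#' Forward model selection across voxels
#'
#' Walks an ordered nested candidate list, starting from the simplest
#' model. A more complex candidate replaces the current model when (a) the
#' voxel-wise likelihood-ratio test is significant at `alpha` for a strict
#' majority of in-mask voxels, and (b) the mean LRT statistic across
#' voxels exceeds the chi-squared critical value at the
#' Bonferroni-corrected level `alpha / (number of candidate comparisons)`.
#' The accepted specification is intended to be applied to all voxels.
#'
#' @param candidates list of [model_spec()]s ordered simple to complex,
#'   each nested in the next (default [default_candidate_specs()]).
#' @param stack,cohort,mask as in [fit_voxelwise()].
#' @param alpha voxel-wise LRT significance level.
#' @param verbose print the decision at each step.
#' @return The selected `gm_model_spec`, with attribute `trace`, a
#'   data.frame of per-comparison statistics.
#' @export
forward_select <- function(stack, cohort,
                           candidates = default_candidate_specs(),
                           mask = NULL, alpha = 0.05, verbose = FALSE) {
  if (!length(candidates)) stop("empty candidate list")
  for (k in seq_along(candidates)[-1]) {
    if (!spec_nested_in(candidates[[k - 1]], candidates[[k]]))
      stop("candidate ", k - 1, " is not nested in candidate ", k)
  }
  n_cmp <- max(1L, length(candidates) - 1L)
  n_fixed_of <- function(spec) {
    fr <- model_frame(cohort, spec)
    fr$y <- 0
    ncol(stats::model.matrix(lme4::nobars(spec_formula(spec))[-2], fr))
  }
  current <- candidates[[1]]
  ll_cur <- voxelwise_loglik(stack, cohort, current, mask)
  p_cur <- n_fixed_of(current)
  trace <- data.frame()
  for (k in seq_along(candidates)[-1]) {
    cand <- candidates[[k]]
    ll_new <- voxelwise_loglik(stack, cohort, cand, mask)
    p_new <- n_fixed_of(cand)
    df_diff <- p_new - p_cur
    stat <- pmax(0, 2 * (ll_new - ll_cur))
    pvals <- pchisq(stat, df_diff, lower.tail = FALSE)
    prop_sig <- mean(pvals < alpha)
    crit <- qchisq(1 - alpha / n_cmp, df_diff)
    accept <- prop_sig > 0.5 && mean(stat) > crit
    trace <- rbind(trace, data.frame(
      candidate = k, df_diff = df_diff, prop_significant = prop_sig,
      mean_stat = mean(stat), critical = crit, accepted = accept))
    if (verbose)
      message(sprintf(
        "candidate %d: %.0f%% voxels significant, mean stat %.2f vs crit %.2f -> %s",
        k, 100 * prop_sig, mean(stat), crit,
        if (accept) "accept" else "reject"))
    if (accept) {
      current <- cand
      ll_cur <- ll_new
      p_cur <- p_new
    }
  }
  attr(current, "trace") <- trace
  current
}

#' Benjamini-Hochberg step-up on a pooled p-value list
#'
#' @param pvalues numeric vector of p-values in `[0, 1]` pooled across all
#'   effects and voxels.
#' @param q target false discovery rate.
#' @return List with `p_threshold` (largest p-value rejected; 0 when
#'   nothing is rejected), `n_rejected`, and `reject`, the logical vector
#'   aligned with `pvalues`.
#' @export
bh_threshold <- function(pvalues, q = 0.05) {
  if (!length(pvalues)) stop("empty p-value list")
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  m <- length(pvalues)
  o <- sort(pvalues)
  ok <- which(o <= q * seq_len(m) / m)
  if (!length(ok))
    return(list(p_threshold = 0, n_rejected = 0L,
                reject = rep(FALSE, m)))
  p_thr <- o[max(ok)]
  list(p_threshold = p_thr, n_rejected = sum(pvalues <= p_thr),
       reject = pvalues <= p_thr)
}

#' Pooled-FDR thresholding of a set of t-maps
#'
#' Pools the uncorrected p-values of all model-term t-maps (the derived
#' pairwise contrast is thresholded but not pooled) across all in-mask
#' voxels, applies Benjamini-Hochberg step-up at rate `q`, and converts the
#' resulting single p-value threshold into a two-sided t-value threshold
#' per map through the map's estimated degrees of freedom. Voxels with
#' `|t| >= threshold` are significant.
#'
#' @param vstats a `gm_voxel_stats` from [fit_voxelwise()].
#' @param q target false discovery rate (default 0.05).
#' @return List with `p_threshold`, `n_rejected`, `t_thresholds` (named;
#'   `Inf` when nothing survives), and `masks`, a named list of logical
#'   significance arrays.
#' @export
pooled_fdr_threshold <- function(vstats, q = 0.05) {
  stopifnot(inherits(vstats, "gm_voxel_stats"))
  pooled_names <- setdiff(names(vstats$tmaps), vstats$derived_maps)
  vox <- vstats$voxels
  pooled <- unlist(lapply(pooled_names, function(nm) vstats$pmaps[[nm]][vox]),
                   use.names = FALSE)
  bh <- bh_threshold(pooled, q)
  t_thr <- if (bh$n_rejected == 0L) Inf else
    qt(1 - bh$p_threshold / 2, vstats$df)
  thresholds <- setNames(rep(t_thr, length(vstats$tmaps)),
                         names(vstats$tmaps))
  masks <- lapply(names(vstats$tmaps), function(nm)
    abs(vstats$tmaps[[nm]]$data) >= thresholds[[nm]] & vstats$mask)
  names(masks) <- names(vstats$tmaps)
  list(p_threshold = bh$p_threshold, n_rejected = bh$n_rejected,
       t_thresholds = thresholds, masks = masks, q = q)
}
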