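#' Mixed linear model of adjusted on unadjusted signed deviations
#'
#' Quantifies automation bias: regresses the signed deviation from ground
#' truth after physician adjustment (`dmda_gt_adjusted`) on the deviation
#' before adjustment (`dmda_gt_unadjusted`), with no intercept, random
#' intercepts for segment and physician, and (by default) physician-specific
#' slope deviations around the global slope as fixed effects under
#' sum-to-zero contrasts. A slope of 1 means the algorithm's error is kept
#' in full (pure automation bias); 0 means perfect correction. Estimation is
#' maximum likelihood; slope heterogeneity across physicians is tested by a
#' likelihood-ratio test.
#'
#' @param records A tibble with columns `dmda_gt_adjusted`,
#'   `dmda_gt_unadjusted`, `physician_id`, `segment_id`, and optionally
#'   `algorithm`, `experience_group`, `preceding_algorithm`, `session`.
#' @param per_physician_slopes Estimate fixed slope deviations per physician
#'   (default TRUE).
#' @param random_slopes Model physician slopes as a random effect
#'   `(0 + x | physician)` instead of fixed deviations; the global-slope SE
#'   then includes the between-physician slope variance. Per-physician
#'   slopes are reported as conditional means (no SE).
#' @param experience_groups Add slope deltas for experience groups (needs an
#'   `experience_group` column; the least-experienced group is the
#'   reference).
#' @param algorithm_effect Add a fixed algorithm main effect.
#' @param carryover_term Add a preceding-algorithm main effect.
#' @param washout_term Add the session index as a regression term.
#' @param intercept Include a global intercept (default FALSE; it does not
#'   reach significance in this design).
#' @param method `"ml"` (maximum likelihood, default), `"reml"`, or `"ols"`
#'   (variance components fixed at zero; ordinary least squares).
#' @return An `adjustment_model_fit` with the global slope and its SE,
#'   per-physician slopes, experience-group deltas, variance components,
#'   residual SD, and the slope-heterogeneity test.
#' @export
fit_adjustment_model <- function(records,
                                 per_physician_slopes = TRUE,
                                 random_slopes = FALSE,
                                 experience_groups = FALSE,
                                 algorithm_effect = FALSE,
                                 carryover_term = FALSE,
                                 washout_term = FALSE,
                                 intercept = FALSE,
                                 method = c("ml", "reml", "ols")) {
  method <- match.arg(method)
  if (random_slopes) per_physician_slopes <- FALSE
  req <- c("dmda_gt_adjusted", "dmda_gt_unadjusted", "physician_id", "segment_id")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols) > 0L) {
    abort_domain(paste("records are missing columns:",
                       paste(missing_cols, collapse = ", ")))
  }
  df <- as.data.frame(records)
  if (dplyr::n_distinct(df$physician_id) < 2L ||
      dplyr::n_distinct(df$segment_id) < 2L) {
    abort_domain("need at least 2 physicians and 2 segments")
  }
  df$physician <- factor(df$physician_id)
  df$segment <- factor(df$segment_id)
  df$x <- df$dmda_gt_unadjusted
  df$y <- df$dmda_gt_adjusted

  fixed <- c(if (intercept) "1" else "0", "x")
  if (per_physician_slopes) {
    # explicit sum-to-zero slope-deviation columns, so the `x` coefficient
    # is the unweighted mean of the physician slopes
    k <- nlevels(df$physician)
    C <- stats::contr.sum(k)
    dev <- C[as.integer(df$physician), , drop = FALSE] * df$x
    colnames(dev) <- paste0("x_dev", seq_len(k - 1L))
    df <- cbind(df, dev)
    fixed <- c(fixed, colnames(dev))
  }
  if (experience_groups) {
    if (!"experience_group" %in% names(df)) {
      abort_domain("`experience_groups = TRUE` needs an experience_group column")
    }
    # least-experienced group (last label in A < B < C order) is the reference
    lev <- sort(unique(as.character(df$experience_group)))
    for (g in lev[-length(lev)]) {
      cn <- paste0("x_exp_", g)
      df[[cn]] <- df$x * (df$experience_group == g)
      fixed <- c(fixed, cn)
    }
  }
  if (algorithm_effect && "algorithm" %in% names(df)) fixed <- c(fixed, "algorithm")
  if (carryover_term && "preceding_algorithm" %in% names(df)) {
    df$preceding <- factor(ifelse(is.na(df$preceding_algorithm), "none",
                                  df$preceding_algorithm))
    fixed <- c(fixed, "preceding")
  }
  if (washout_term && "session" %in% names(df)) fixed <- c(fixed, "session")
  fixed_rhs <- paste(fixed, collapse = " + ")

  ols_fit <- stats::lm(stats::as.formula(paste("y ~", fixed_rhs)), data = df)
  # summary.lm warns on noiseless (exact) fits; the zero sigma is the point
  ols_sigma <- suppressWarnings(summary(ols_fit)$sigma)
  use_ols <- method == "ols" || !is.finite(ols_sigma) || ols_sigma < 1e-8

  if (use_ols) {
    fit <- ols_fit
    varcomp <- tibble::tibble(component = c("segment", "physician", "residual"),
                              sd = c(0, 0, max(ols_sigma, 0)))
    resid_sd <- max(ols_sigma, 0)
    het <- heterogeneity_test_lm(df, fixed, per_physician_slopes)
  } else {
    reml <- method == "reml"
    ranef_rhs <- if (random_slopes) {
      "+ (1 | segment) + (1 | physician) + (0 + x | physician)"
    } else "+ (1 | segment) + (1 | physician)"
    form <- stats::as.formula(paste("y ~", fixed_rhs, ranef_rhs))
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(form, data = df, REML = reml,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))))
    vc <- as.data.frame(lme4::VarCorr(fit))
    seg_sd <- vc$sdcor[vc$grp == "segment" & vc$var1 == "(Intercept)"][1]
    phys_sd <- vc$sdcor[vc$grp %in% c("physician", "physician.1") &
                          vc$var1 == "(Intercept)"][1]
    varcomp <- tibble::tibble(
      component = c("segment", "physician", "residual"),
      sd = c(seg_sd, phys_sd, stats::sigma(fit))
    )
    if (random_slopes) {
      slope_sd <- vc$sdcor[vc$grp %in% c("physician", "physician.1") &
                             vc$var1 == "x"][1]
      varcomp <- dplyr::bind_rows(
        varcomp, tibble::tibble(component = "physician_slope", sd = slope_sd))
    }
    resid_sd <- stats::sigma(fit)
    het <- if (per_physician_slopes) {
      form0 <- stats::as.formula(paste(
        "y ~", paste(setdiff(fixed, grep("^x_dev", fixed, value = TRUE)),
                     collapse = " + "),
        "+ (1 | segment) + (1 | physician)"))
      fit0 <- suppressMessages(suppressWarnings(
        lme4::lmer(form0, data = df, REML = FALSE,
                   control = lme4::lmerControl(check.conv.singular = "ignore"))))
      fit1 <- if (reml) {
        suppressMessages(suppressWarnings(
          lme4::lmer(form, data = df, REML = FALSE,
                     control = lme4::lmerControl(check.conv.singular = "ignore"))))
      } else fit
      a <- stats::anova(fit0, fit1)
      tibble::tibble(statistic = a$Chisq[2], df = a$Df[2],
                     p_value = a$`Pr(>Chisq)`[2], method = "likelihood ratio")
    } else NULL
  }

  est <- extract_slopes(fit, df, per_physician_slopes, experience_groups,
                        random_slopes)
  structure(
    c(est,
      list(varcomp = varcomp, residual_sd = resid_sd,
           heterogeneity = het, method = method,
           n_obs = nrow(df), n_physicians = nlevels(df$physician),
           n_segments = nlevels(df$segment), fit = fit, data = df)),
    class = "adjustment_model_fit"
  )
}

# LRT analogue for the OLS branch
heterogeneity_test_lm <- function(df, fixed, per_physician_slopes) {
  if (!per_physician_slopes) return(NULL)
  f1 <- stats::lm(stats::as.formula(paste("y ~", paste(fixed, collapse = " + "))),
                  data = df)
  f0 <- stats::lm(stats::as.formula(
    paste("y ~", paste(setdiff(fixed, grep("^x_dev", fixed, value = TRUE)),
                       collapse = " + "))), data = df)
  a <- stats::anova(f0, f1)
  tibble::tibble(statistic = a$F[2], df = a$Df[2], p_value = a$`Pr(>F)`[2],
                 method = "F test")
}

# global slope, per-physician slopes and experience deltas with SEs from the
# coefficient covariance (sum-to-zero physician deviation columns)
extract_slopes <- function(fit, df, per_physician_slopes, experience_groups,
                           random_slopes = FALSE) {
  b <- if (inherits(fit, "merMod")) lme4::fixef(fit) else stats::coef(fit)
  V <- suppressWarnings(as.matrix(stats::vcov(fit)))
  nm <- names(b)
  gi <- which(nm == "x")
  global_slope <- unname(b[gi])
  global_slope_se <- sqrt(V[gi, gi])
  phys <- NULL
  if (per_physician_slopes) {
    lev <- levels(df$physician)
    k <- length(lev)
    C <- stats::contr.sum(k) # k x (k-1)
    di <- match(paste0("x_dev", seq_len(k - 1L)), nm)
    phys <- purrr::map_dfr(seq_len(k), function(i) {
      # slope_i = global + sum_j C[i, j] * dev_j
      lvec <- numeric(length(b))
      lvec[gi] <- 1
      lvec[di] <- C[i, ]
      tibble::tibble(
        physician_id = lev[i],
        slope = sum(lvec * b),
        se = sqrt(drop(t(lvec) %*% V %*% lvec))
      )
    })
  } else if (random_slopes && inherits(fit, "merMod")) {
    re <- lme4::ranef(fit)$physician
    if (!is.null(re) && "x" %in% colnames(re)) {
      phys <- tibble::tibble(
        physician_id = rownames(re),
        slope = global_slope + re[["x"]],
        se = NA_real_
      )
    }
  }
  expd <- NULL
  if (experience_groups) {
    ei <- grep("^x_exp_", nm)
    expd <- tibble::tibble(
      term = sub("^x_exp_", "", nm[ei]),
      delta = unname(b[ei]),
      se = sqrt(diag(V)[ei])
    )
  }
  list(global_slope = global_slope, global_slope_se = global_slope_se,
       physician_slopes = phys, experience_deltas = expd)
}

#' @exportS3Method base::print
print.adjustment_model_fit <- function(x, ...) {
  cat(sprintf(
    "<adjustment_model_fit> %s fit, %d obs (%d physicians x %d segments)\n",
    toupper(x$method), x$n_obs, x$n_physicians, x$n_segments))
  cat(sprintf("  global slope %.4f +/- %.4f; residual SD %.2f mm\n",
              x$global_slope, x$global_slope_se, x$residual_sd))
  if (!is.null(x$physician_slopes)) {
    rng <- range(x$physician_slopes$slope)
    cat(sprintf("  physician slopes %.4f .. %.4f", rng[1], rng[2]))
    if (!is.null(x$heterogeneity)) {
      cat(sprintf(" (heterogeneity p = %.4g)", x$heterogeneity$p_value))
    }
    cat("\n")
  }
  invisible(x)
}

#' @describeIn fit_adjustment_model Coefficient-level summary: the global
#'   slope, per-physician slopes and experience deltas as one tibble.
#' @param x,object An `adjustment_model_fit`.
#' @param ... Unused.
#' @export
tidy.adjustment_model_fit <- function(x, ...) {
  out <- tibble::tibble(term = "global_slope", estimate = x$global_slope,
                        std_error = x$global_slope_se)
  if (!is.null(x$physician_slopes)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      term = paste0("slope[", x$physician_slopes$physician_id, "]"),
      estimate = x$physician_slopes$slope,
      std_error = x$physician_slopes$se))
  }
  if (!is.null(x$experience_deltas)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      term = paste0("slope_delta[", x$experience_deltas$term, "]"),
      estimate = x$experience_deltas$delta,
      std_error = x$experience_deltas$se))
  }
  out
}

#' @describeIn fit_adjustment_model One-row model summary.
#' @export
glance.adjustment_model_fit <- function(x, ...) {
  tibble::tibble(
    global_slope = x$global_slope, global_slope_se = x$global_slope_se,
    residual_sd = x$residual_sd,
    segment_sd = x$varcomp$sd[x$varcomp$component == "segment"],
    physician_sd = x$varcomp$sd[x$varcomp$component == "physician"],
    heterogeneity_p = if (is.null(x$heterogeneity)) NA_real_ else x$heterogeneity$p_value,
    n_obs = x$n_obs, method = x$method
  )
}

#' @describeIn fit_adjustment_model Observed values and fitted per-physician
#'   regression lines against the unadjusted deviation, with the 1:1
#'   automation-bias reference line.
#' @export
autoplot.adjustment_model_fit <- function(object, ...) {
  df <- object$data
  sl <- object$physician_slopes
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        colour = .data$physician)) +
    ggplot2::geom_point(shape = 1, alpha = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "solid",
                         colour = "grey30")
  if (!is.null(sl)) {
    p <- p + ggplot2::geom_abline(
      data = sl,
      mapping = ggplot2::aes(slope = .data$slope, intercept = 0,
                             colour = .data$physician_id),
      linetype = "dashed")
  }
  p + ggplot2::labs(
    x = "unadjusted dMDA to ground truth (mm)",
    y = "adjusted dMDA to ground truth (mm)",
    colour = "physician") +
    ggplot2::theme_minimal()
}
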