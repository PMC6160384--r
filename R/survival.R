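#' Univariate Cox proportional-hazards fit
#'
#' Maximizes the Cox partial likelihood (Breslow ties) for a single
#' expression covariate via [survival::coxph()] with tight convergence
#' settings. Features with fewer than 2 events, a constant covariate, or a
#' monotone (non-convergent) likelihood are rejected with an error so a
#' screening caller can skip them.
#'
#' @param time follow-up times (> 0).
#' @param event event indicators (1 = death observed, 0 = censored).
#' @param expression covariate values.
#' @return list with `beta`, `se`, `p`.
#' @export
cox_fit_univariate <- function(time, event, expression) {
  if (sum(event) < 2) stopf("need >= 2 events")
  if (stats::sd(expression) == 0) stopf("constant covariate")
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ expression,
                    ties = "breslow",
                    control = survival::coxph.control(eps = 1e-9, iter.max = 50)),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be", conditionMessage(w))) {
        stopf("monotone likelihood / non-convergence")
      }
      invokeRestart("muffleWarning")
    })
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(diag(fit$var)))[1]
  if (!is.finite(beta) || abs(beta) > 20) stopf("monotone likelihood / non-convergence")
  list(beta = beta, se = se,
       p = 2 * stats::pnorm(abs(beta / se), lower.tail = FALSE))
}

#' Risk-score dichotomization
#'
#' The per-sample risk score is the Cox coefficient times the expression
#' level. Samples with a score strictly above the median score form the
#' HIGH risk group; scores at or below the median (including exact-median
#' ties) are LOW. The quantile is configurable.
#'
#' @param beta Cox coefficient.
#' @param expression per-sample expression values.
#' @param quantile split point of the score distribution (default median).
#' @return list with `score` (numeric) and `group` (factor LOW/HIGH).
#' @export
risk_groups <- function(beta, expression, quantile = 0.5) {
  if (!is.finite(beta)) stopf("beta must be finite")
  score <- beta * expression
  cut <- stats::quantile(score, quantile, names = FALSE)
  group <- factor(ifelse(score > cut, "HIGH", "LOW"), levels = c("LOW", "HIGH"))
  list(score = score, group = group)
}

#' Two-group log-rank test
#'
#' Standard Mantel-Haenszel log-rank comparison of two survival curves via
#' [survival::survdiff()]: the chi-square statistic (1 df) sums
#' (observed - expected)^2 / variance over distinct event times.
#'
#' @param group factor with levels LOW/HIGH (or any two levels).
#' @param time follow-up times.
#' @param event event indicators.
#' @return list `chi2, p_value, n_high, n_low, events_high, events_low`.
#' @export
logrank_test <- function(group, time, event) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2L) stopf("one group is empty")
  if (sum(event) < 1) stopf("no events")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  chi2 <- unname(sd$chisq)
  lv <- levels(group)
  n <- as.vector(sd$n); names(n) <- lv
  obs <- sd$obs; names(obs) <- lv
  hi <- if ("HIGH" %in% lv) "HIGH" else lv[2]
  lo <- setdiff(lv, hi)[1]
  list(chi2 = chi2,
       p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       n_high = unname(n[hi]), n_low = unname(n[lo]),
       events_high = unname(obs[hi]), events_low = unname(obs[lo]))
}

#' Per-feature risk-score survival screen
#'
#' For every feature: univariate Cox coefficient, risk-score median split,
#' log-rank test between the risk groups, and BH adjustment across
#' features. Features that cannot be fit (no events, constant expression,
#' monotone likelihood) are reported with `NA` statistics and skipped in
#' the adjustment. Kaplan-Meier step coordinates per risk group are
#' returned for plotting.
#'
#' @param expr feature x sample expression matrix.
#' @param clinical data.frame `sample_id, time, event`; samples are matched
#'   to the matrix columns by id and unmatched samples dropped.
#' @param quantile risk-score split quantile.
#' @return list with `table` (per feature: `feature_id, beta, se, chi2, p,
#'   adj_p, direction, n_high, n_low`) and `km` (named list of per-feature
#'   Kaplan-Meier coordinate data.frames: `group, time, surv`).
#' @export
survival_screen <- function(expr, clinical, quantile = 0.5) {
  common <- intersect(colnames(expr), clinical$sample_id)
  if (length(common) < length(clinical$sample_id) ||
      length(common) < ncol(expr)) {
    message(sprintf("survival_screen: %d unmatched sample(s) dropped",
                    length(union(colnames(expr), clinical$sample_id)) - length(common)))
  }
  if (length(common) == 0L) stopf("no samples in common")
  expr <- expr[, common, drop = FALSE]
  cl <- clinical[match(common, clinical$sample_id), ]
  rows <- vector("list", nrow(expr))
  km <- list()
  for (i in seq_len(nrow(expr))) {
    fid <- rownames(expr)[i]
    res <- tryCatch({
      fit <- cox_fit_univariate(cl$time, cl$event, expr[i, ])
      rg <- risk_groups(fit$beta, expr[i, ], quantile = quantile)
      if (nlevels(droplevels(rg$group)) < 2L) stopf("degenerate risk split")
      lr <- logrank_test(rg$group, cl$time, cl$event)
      sf <- survival::survfit(survival::Surv(cl$time, cl$event) ~ rg$group)
      grp <- rep(sub("^rg\\$group=", "", names(sf$strata)), sf$strata)
      km[[fid]] <- data.frame(group = grp, time = sf$time, surv = sf$surv,
                              stringsAsFactors = FALSE)
      data.frame(feature_id = fid, beta = fit$beta, se = fit$se,
                 chi2 = lr$chi2, p = lr$p_value,
                 direction = if (fit$beta > 0) "HIGH_EXPR_RISK" else "LOW_EXPR_RISK",
                 n_high = lr$n_high, n_low = lr$n_low,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(feature_id = fid, beta = NA_real_, se = NA_real_,
                 chi2 = NA_real_, p = NA_real_, direction = NA_character_,
                 n_high = NA_integer_, n_low = NA_integer_,
                 stringsAsFactors = FALSE)
    })
    rows[[i]] <- res
  }
  tab <- do.call(rbind, rows)
  tab$adj_p <- NA_real_
  ok <- !is.na(tab$p)
  tab$adj_p[ok] <- bh_adjust(tab$p[ok])
  list(table = tab, km = km)
}
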