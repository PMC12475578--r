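#' Survival stratification by panel methylation
#'
#' Samples are split into low/high groups by mean panel methylation
#' (median split by default) and compared with the log-rank test;
#' Kaplan-Meier step curves are emitted per group.
#'
#' @name survstrat
NULL

#' Median-split log-rank survival stratification
#'
#' @param panel_meth named numeric vector: mean panel methylation per
#'   sample.
#' @param sheet sample sheet with sample_id, survival_time, event.
#' @param quantile split quantile (default 0.5 = median split); samples at
#'   or below the quantile form the "low" group.
#' @return list of class `survival_stratification`: `groups` (named
#'   low/high factor), `n_events` per group, `worse_group` (the group with
#'   more events than expected), `chisq` (log-rank, 1 df), `p_value`,
#'   `km` (data.frame group, time, surv: Kaplan-Meier curves). With no
#'   events anywhere the statistic is NA and `undefined` is TRUE.
#' @export
km_split_logrank <- function(panel_meth, sheet, quantile = 0.5) {
  ok <- sheet$sample_id %in% names(panel_meth) &
    is.finite(sheet$survival_time) & !is.na(sheet$event)
  sheet <- sheet[ok, , drop = FALSE]
  x <- panel_meth[sheet$sample_id]
  cut <- stats::quantile(x, quantile)
  grp <- factor(ifelse(x <= cut, "low", "high"), levels = c("low", "high"))
  if (any(table(grp) < 2)) stop("need >= 2 samples per group")
  n_events <- tapply(sheet$event, grp, sum)
  if (sum(sheet$event) == 0) {
    warning("no events; log-rank statistic undefined")
    return(structure(list(groups = stats::setNames(grp, sheet$sample_id),
                          n_events = n_events, chisq = NA_real_,
                          p_value = NA_real_, km = NULL, undefined = TRUE),
                     class = "survival_stratification"))
  }
  s <- survival::Surv(sheet$survival_time, sheet$event)
  sd <- survival::survdiff(s ~ grp)
  fit <- survival::survfit(s ~ grp)
  km <- data.frame(
    group = rep(sub("^grp=", "", names(fit$strata)), fit$strata),
    time = fit$time, surv = fit$surv)
  grp_names <- sub("^grp=", "", rownames(as.matrix(sd$n)))
  worse <- grp_names[which.max(sd$obs - sd$exp)]  # more events than expected
  structure(list(groups = stats::setNames(grp, sheet$sample_id),
                 n_events = n_events, worse_group = worse,
                 chisq = unname(sd$chisq),
                 p_value = stats::pchisq(sd$chisq, df = 1,
                                         lower.tail = FALSE),
                 km = km, undefined = FALSE),
            class = "survival_stratification")
}

#' @export
print.survival_stratification <- function(x, ...) {
  cat(sprintf("log-rank chisq = %.3f (1 df), p = %.4g; events low/high = %d/%d\n",
              x$chisq, x$p_value, x$n_events["low"], x$n_events["high"]))
  invisible(x)
}
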