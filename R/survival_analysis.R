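# Survival screens: median-expression split, Kaplan-Meier estimate, log-rank
# test, and the expression-age trend contrast between cases and controls.

#' Split samples at the median expression
#'
#' Samples at or above the median are labelled `"high"`, below `"low"`. The
#' median is computed over all samples (midpoint of the middle two for even
#' n). When all values are identical every sample is `"high"` and a warning
#' is emitted.
#'
#' @param x Numeric expression vector (>= 2 samples).
#' @return Character vector of `"high"`/`"low"`, same length/names as `x`.
#' @export
median_split <- function(x) {
  if (length(x) < 2) stop_invalid("need at least 2 samples")
  med <- stats::median(x)
  if (all(x == x[1])) warning("constant expression: all samples labelled high")
  out <- ifelse(x >= med, "high", "low")
  names(out) <- names(x)
  out
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate `S(t) = prod over event times t_i <= t of
#' (1 - d_i / n_i)`; censored records reduce the risk set only.
#'
#' @param time Non-negative follow-up times.
#' @param event Event indicator (1 = event, 0 = censored).
#' @return Data frame of class `km_curve`: `time` (distinct event times,
#'   ascending), `n_risk`, `n_event`, `surv` (non-increasing, starts below
#'   S(0) = 1).
#' @export
km_estimate <- function(time, event) {
  if (length(time) < 1) stop_invalid("need at least one record")
  if (any(time < 0)) stop_invalid("negative survival times")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  keep <- fit$n.event > 0
  out <- data.frame(time = fit$time[keep], n_risk = fit$n.risk[keep],
                    n_event = fit$n.event[keep], surv = fit$surv[keep])
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Survival probability of a KM curve at given times
#' @param curve A [km_estimate()] result.
#' @param t Times at which to evaluate S(t).
#' @export
km_survival_at <- function(curve, t) {
  vapply(t, function(ti) {
    past <- curve$time <= ti
    if (!any(past)) 1 else curve$surv[max(which(past))]
  }, numeric(1))
}

#' Log-rank test for equality of two survival curves
#'
#' @param time,event As in [km_estimate()].
#' @param group Two-level group labels.
#' @return List with `chisq` (1 df statistic), `p` (two-sided), and the
#'   observed/expected event counts per group.
#' @export
logrank_test <- function(time, event, group) {
  g <- factor(group)
  if (nlevels(g) != 2) stop_invalid("log-rank test needs exactly two groups")
  if (any(table(g) == 0)) stop_invalid("both groups must be non-empty")
  sd <- survival::survdiff(survival::Surv(time, event) ~ g)
  list(chisq = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       observed = unname(sd$obs), expected = unname(sd$exp))
}

#' Expression-age trend contrast between groups
#'
#' Ordinary least squares of expression on age, group and their interaction;
#' the reported p-value is the two-sided test of the age-by-group interaction
#' coefficient, i.e. whether expression trends differently with age in the
#' two groups. Per-group slopes are also returned.
#'
#' @param expression Numeric vector.
#' @param age Numeric ages (years).
#' @param group Two-level labels (e.g. case/control).
#' @return List with `slope` (named per group), `interaction_p`.
#' @export
age_trend_test <- function(expression, age, group) {
  g <- factor(group)
  if (nlevels(g) != 2) stop_invalid("need exactly two groups")
  if (any(tapply(age, g, function(a) length(unique(a))) < 2)) {
    stop_invalid("age is constant within a group; trend not identifiable")
  }
  if (any(table(g) < 3)) stop_invalid("need at least 3 samples per group")
  fit <- stats::lm(expression ~ age * g)
  co <- summary(fit)$coefficients
  slope1 <- co["age", "Estimate"]
  int_row <- grep("^age:", rownames(co))
  slope2 <- slope1 + co[int_row, "Estimate"]
  list(slope = setNames(c(slope1, slope2), levels(g)),
       interaction_p = co[int_row, "Pr(>|t|)"])
}

#' Screen risk genes for prognostic value
#'
#' For each risk gene and brain region: split the cases at the median
#' expression, log-rank test on survival between the high and low groups, and
#' the case/control age-trend contrast. A gene is flagged prognostic when its
#' log-rank p and its age-trend interaction p are both below `alpha` in at
#' least one region (raw p-values, no multiplicity correction by default).
#'
#' @param cohort An expression cohort: list with `matrix` (genes x samples)
#'   and `meta` (data frame with `group` ("case"/"control"), `region`, `age`,
#'   `time`, `event` per sample).
#' @param risk_genes Genes to screen (intersected with the matrix rows).
#' @param alpha Significance level for both criteria (default 0.05).
#' @param adjust Apply Benjamini-Hochberg within each criterion first.
#' @return Data frame, one row per (gene, region): `gene_id`, `region`,
#'   `logrank_p`, `trend_p`, `flagged` (gene-level flag repeated per row).
#' @export
screen_prognostic_genes <- function(cohort, risk_genes, alpha = 0.05,
                                    adjust = FALSE) {
  genes <- intersect(risk_genes, rownames(cohort$matrix))
  meta <- cohort$meta
  regions <- unique(meta$region)
  if (length(genes) == 0) {
    return(data.frame(gene_id = character(), region = character(),
                      logrank_p = numeric(), trend_p = numeric(),
                      flagged = logical()))
  }
  rows <- list()
  for (g in genes) {
    for (rg in regions) {
      in_region <- meta$region == rg
      cases <- in_region & meta$group == "case"
      expr_cases <- cohort$matrix[g, cases]
      lr_p <- NA_real_
      if (sum(cases) >= 4 && !all(expr_cases == expr_cases[1])) {
        grp <- median_split(expr_cases)
        if (length(unique(grp)) == 2) {
          lr_p <- logrank_test(meta$time[cases], meta$event[cases], grp)$p
        }
      }
      tr_p <- tryCatch(
        age_trend_test(cohort$matrix[g, in_region], meta$age[in_region],
                       meta$group[in_region])$interaction_p,
        error = function(e) NA_real_
      )
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, region = rg, logrank_p = lr_p, trend_p = tr_p,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  if (adjust) {
    out$logrank_p <- stats::p.adjust(out$logrank_p, method = "BH")
    out$trend_p <- stats::p.adjust(out$trend_p, method = "BH")
  }
  hit <- !is.na(out$logrank_p) & out$logrank_p < alpha &
    !is.na(out$trend_p) & out$trend_p < alpha
  flagged_genes <- unique(out$gene_id[hit])
  out$flagged <- out$gene_id %in% flagged_genes
  rownames(out) <- NULL
  out
}
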