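#' Recode a clinical table to a survival endpoint
#'
#' Overall survival counts death from any cause as an event. Disease-specific
#' survival counts only deaths caused by the disease; patients who died from
#' other causes are considered alive at their death time and censored there
#' (requires a `cause` column with values `"disease"` / `"other"` for
#' events).
#'
#' @param clinical Tibble with `sample_id`, `time`, `event`, and `cause`
#'   (required for the disease-specific endpoint).
#' @param endpoint `"overall"` or `"disease_specific"`.
#' @return The tibble with `event` recoded and an `endpoint` column.
#' @export
make_endpoint <- function(clinical, endpoint = c("overall",
                                                 "disease_specific")) {
  endpoint <- match.arg(endpoint)
  out <- clinical
  if (endpoint == "disease_specific") {
    if (!"cause" %in% names(clinical)) {
      abort("make_endpoint: disease-specific endpoint needs a `cause` column",
            class = "stromasig_input_error")
    }
    out$event <- as.integer(out$event == 1 &
                              !is.na(out$cause) & out$cause == "disease")
  } else {
    out$event <- as.integer(out$event == 1)
  }
  out$endpoint <- endpoint
  out
}

#' Kaplan-Meier product-limit estimate
#'
#' Standard product-limit estimator: at each distinct event time `t_i` with
#' `d_i` events among `n_i` at risk, survival multiplies by
#' `1 - d_i / n_i`. Patients censored at an event time are counted as at
#' risk at that time; the curve is right-continuous.
#'
#' @param clinical Tibble with `time` and `event`; an optional `group`
#'   column produces one curve per group.
#' @return A `km_fit`: tibble with `group`, `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival` (rows at distinct event or censoring times).
#' @export
kaplan_meier <- function(clinical) {
  if (nrow(clinical) < 1) abort("kaplan_meier: empty table",
                                class = "stromasig_input_error")
  if (any(clinical$time < 0)) {
    abort("kaplan_meier: negative survival time",
          class = "stromasig_input_error")
  }
  groups <- if ("group" %in% names(clinical)) clinical$group else
    rep("all", nrow(clinical))
  out <- purrr::map_dfr(unique(groups[!is.na(groups)]), function(gr) {
    t <- clinical$time[groups == gr & !is.na(groups)]
    e <- clinical$event[groups == gr & !is.na(groups)]
    times <- sort(unique(t))
    n_risk <- vapply(times, function(tt) sum(t >= tt), numeric(1))
    n_event <- vapply(times, function(tt) sum(t == tt & e == 1), numeric(1))
    n_cens <- vapply(times, function(tt) sum(t == tt & e == 0), numeric(1))
    surv <- cumprod(1 - n_event / n_risk)
    tibble(group = gr, time = times, n_risk = n_risk, n_event = n_event,
           n_censor = n_cens, survival = surv)
  })
  class(out) <- c("km_fit", class(out))
  out
}

#' Read a survival probability off a product-limit curve
#'
#' Returns the step-function value at the given horizon: the survival at
#' the largest observed time not exceeding the horizon (1 before the first
#' step).
#'
#' @param km A [kaplan_meier()] tibble.
#' @param horizons Numeric vector of times (months).
#' @return Tibble (`group`, `horizon`, `survival`).
#' @export
km_at <- function(km, horizons) {
  purrr::map_dfr(unique(km$group), function(gr) {
    k <- km[km$group == gr, ]
    s <- vapply(horizons, function(h) {
      idx <- which(k$time <= h)
      if (length(idx) == 0) 1 else k$survival[max(idx)]
    }, numeric(1))
    tibble(group = gr, horizon = horizons, survival = s)
  })
}

# Efron-ties partial log-likelihood, gradient, information for one covariate
cox_loglik <- function(beta, time, event, x) {
  eta <- beta * x
  w <- exp(eta)
  ll <- 0
  grad <- 0
  info <- 0
  for (t in unique(time[event == 1])) {
    risk <- time >= t
    died <- time == t & event == 1
    d <- sum(died)
    sw_r <- sum(w[risk])
    swx_r <- sum((w * x)[risk])
    swxx_r <- sum((w * x^2)[risk])
    sw_d <- sum(w[died])
    swx_d <- sum((w * x)[died])
    swxx_d <- sum((w * x^2)[died])
    ll <- ll + sum(eta[died])
    for (l in seq_len(d) - 1) {
      f <- l / d
      s0 <- sw_r - f * sw_d
      s1 <- swx_r - f * swx_d
      s2 <- swxx_r - f * swxx_d
      ll <- ll - log(s0)
      grad <- grad - s1 / s0
      info <- info + s2 / s0 - (s1 / s0)^2
    }
    grad <- grad + sum(x[died])
  }
  list(ll = ll, grad = grad, info = info)
}

#' Univariate Cox proportional-hazards fit
#'
#' Partial-likelihood Newton-Raphson with Efron handling of tied event
#' times (Breslow switchable). Convergence is declared when the relative
#' change of the log partial likelihood falls below `1e-9` (at most 50
#' iterations). A monotone likelihood (complete separation) triggers a
#' warning and a capped, flagged estimate. For a factor covariate the
#' reference level is the first sorted level (the low group when labels are
#' `"low"`/`"high"` and `reference = "low"`, the default).
#'
#' @param clinical Tibble with `time`, `event`, and the covariate column.
#' @param covariate Name of the covariate column; a two-level
#'   factor/character is coded 0/1, a numeric column is used as is.
#' @param reference Reference level for a two-level covariate.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return A `cox_fit` with `log_hr`, `hr`, `se`, `p_wald`, `p_score`,
#'   `p_lrt`, `n`, `n_event`, plus the swapped-reference coding.
#' @export
cox_univariate <- function(clinical, covariate = "group",
                           reference = NULL, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  keep <- !is.na(clinical[[covariate]]) & !is.na(clinical$time)
  cl <- clinical[keep, , drop = FALSE]
  xraw <- cl[[covariate]]
  if (is.numeric(xraw)) {
    x <- xraw
    levels_used <- NULL
  } else {
    lev <- sort(unique(as.character(xraw)))
    if (length(lev) != 2) {
      abort("cox_univariate: a non-numeric covariate must have 2 levels",
            class = "stromasig_input_error")
    }
    if (is.null(reference)) {
      reference <- if ("low" %in% lev) "low" else lev[1]
    }
    x <- as.numeric(as.character(xraw) != reference)
    levels_used <- c(reference = reference,
                     effect = setdiff(lev, reference))
  }
  if (sum(cl$event) < 2) {
    abort("cox_univariate: need >= 2 events",
          class = "stromasig_input_error")
  }
  if (length(unique(x)) < 2) {
    abort("cox_univariate: covariate is constant",
          class = "stromasig_input_error")
  }
  time <- cl$time
  event <- cl$event
  loglik <- if (ties == "efron") cox_loglik else function(beta, time,
                                                          event, x) {
    # Breslow: no within-tie downweighting
    eta <- beta * x
    w <- exp(eta)
    ll <- 0; grad <- 0; info <- 0
    for (t in unique(time[event == 1])) {
      risk <- time >= t
      died <- time == t & event == 1
      d <- sum(died)
      s0 <- sum(w[risk]); s1 <- sum((w * x)[risk])
      s2 <- sum((w * x^2)[risk])
      ll <- ll + sum(eta[died]) - d * log(s0)
      grad <- grad + sum(x[died]) - d * s1 / s0
      info <- info + d * (s2 / s0 - (s1 / s0)^2)
    }
    list(ll = ll, grad = grad, info = info)
  }

  beta <- 0
  fit0 <- loglik(0, time, event, x)
  ll_old <- fit0$ll
  flagged <- FALSE
  for (it in seq_len(50)) {
    fit <- loglik(beta, time, event, x)
    if (fit$info <= 0) break
    step <- fit$grad / fit$info
    # step halving to keep the likelihood increasing
    for (h in 1:20) {
      cand <- beta + step
      llc <- loglik(cand, time, event, x)$ll
      if (is.finite(llc) && llc >= fit$ll - 1e-12) break
      step <- step / 2
    }
    beta <- beta + step
    llnew <- loglik(beta, time, event, x)$ll
    if (abs(llnew - fit$ll) < 1e-9 * (abs(fit$ll) + 1e-9)) {
      ll_old <- llnew
      break
    }
    ll_old <- llnew
    if (abs(beta) > 15) {
      flagged <- TRUE
      warn("cox_univariate: monotone likelihood (complete separation); estimate capped")
      beta <- sign(beta) * 15
      break
    }
  }
  final <- loglik(beta, time, event, x)
  se <- 1 / sqrt(final$info)
  z <- beta / se
  p_wald <- 2 * pnorm(-abs(z))
  score_z <- fit0$grad / sqrt(fit0$info)
  p_score <- 2 * pnorm(-abs(score_z))
  p_lrt <- pchisq(2 * (final$ll - fit0$ll), df = 1, lower.tail = FALSE)
  structure(list(
    log_hr = beta, hr = exp(beta), se = se, p_wald = p_wald,
    p_score = p_score, p_lrt = p_lrt, n = nrow(cl),
    n_event = sum(event), ties = ties, covariate = covariate,
    levels = levels_used, flagged = flagged,
    log_hr_swapped = -beta, hr_swapped = exp(-beta),
    loglik = c(null = fit0$ll, fitted = final$ll)
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Univariate Cox fit (", x$ties, " ties)\n", sep = "")
  if (!is.null(x$levels)) {
    cat("  ", x$covariate, ": ", x$levels[["effect"]], " vs ",
        x$levels[["reference"]], " (reference)\n", sep = "")
  }
  cat(sprintf("  HR %.3f (log HR %.3f, SE %.3f), Wald p = %.4g, n = %d, events = %d\n",
              x$hr, x$log_hr, x$se, x$p_wald, x$n, x$n_event))
  cat(sprintf("  swapped reference: HR %.3f\n", x$hr_swapped))
  invisible(x)
}

#' Tidy a Cox fit
#'
#' @param x A `cox_fit`.
#' @param ... Unused.
#' @return One row per coding (native and swapped reference).
#' @method tidy cox_fit
#' @export
tidy.cox_fit <- function(x, ...) {
  tibble(term = c(x$covariate, paste0(x$covariate, "_swapped_ref")),
         estimate = c(x$log_hr, x$log_hr_swapped),
         hr = c(x$hr, x$hr_swapped),
         std.error = x$se, statistic = c(x$log_hr, -x$log_hr) / x$se,
         p.value = x$p_wald)
}

#' @rdname tidy.cox_fit
#' @method glance cox_fit
#' @export
glance.cox_fit <- function(x, ...) {
  tibble(n = x$n, n_event = x$n_event, log_hr = x$log_hr, hr = x$hr,
         se = x$se, p_wald = x$p_wald, p_score = x$p_score,
         p_lrt = x$p_lrt, ties = x$ties, flagged = x$flagged)
}

#' Signature-based survival stratification
#'
#' Stratifies a cohort either by cutting the root of an uncentered-Pearson
#' average-linkage dendrogram over samples (`cluster_split`) or by the
#' centroid-score median split (`median_score`); labels the group with the
#' larger mean centroid score `"high"`; and reports per-group
#' Kaplan-Meier curves, survival at the requested horizons, and the
#' univariate Cox comparison under both reference codings.
#'
#' @param mapped Wide expression tibble of mapped signature genes (samples
#'   aligned with `clinical$sample_id`).
#' @param clinical Clinical tibble (`sample_id`, `time`, `event`, ...).
#' @param method `"median_score"` or `"cluster_split"`.
#' @param horizons Months at which to report group survival.
#' @return A `strat_report` list: `groups`, `km`, `survival_at`, `cox`,
#'   `method`.
#' @export
stratified_analysis <- function(mapped, clinical,
                                method = c("median_score", "cluster_split"),
                                horizons = c(12, 24, 60)) {
  method <- match.arg(method)
  ids <- sample_ids(mapped)
  missing_ids <- setdiff(clinical$sample_id, ids)
  if (length(missing_ids) > 0) {
    abort(paste0("stratified_analysis: clinical sample(s) absent from expression: ",
                 paste(head(missing_ids, 5), collapse = ", ")),
          class = "stromasig_input_error")
  }
  scores <- centroid_score(mapped)
  if (method == "median_score") {
    grouped <- median_split(scores)
  } else {
    d <- uncentered_pearson_distance(mapped, axis = "samples")
    dend <- average_linkage(d)
    cut <- cut_two_groups(dend)
    grouped <- scores %>%
      mutate(cluster = cut[.data$sample_id])
    mean_by <- tapply(grouped$score, grouped$cluster, mean, na.rm = TRUE)
    high_cluster <- as.integer(names(which.max(mean_by)))
    grouped <- grouped %>%
      mutate(group = ifelse(.data$cluster == high_cluster, "high", "low"))
  }
  n_per <- table(grouped$group)
  if (length(n_per) < 2 || any(n_per < 2)) {
    abort("stratified_analysis: fewer than 2 samples in a group",
          class = "stromasig_analysis_error")
  }
  cl <- clinical %>%
    left_join(grouped %>% select("sample_id", "score", "group"),
              by = "sample_id")
  km <- kaplan_meier(cl)
  structure(list(
    method = method, groups = grouped,
    km = km, survival_at = km_at(km, horizons),
    cox = cox_univariate(cl, covariate = "group", reference = "low"),
    horizons = horizons
  ), class = "strat_report")
}

#' @export
print.strat_report <- function(x, ...) {
  cat("Stratified survival analysis (", x$method, ")\n", sep = "")
  print(x$survival_at)
  print(x$cox)
  invisible(x)
}
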