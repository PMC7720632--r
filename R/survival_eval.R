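#' Construct a validated survival data frame
#'
#' @param time non-negative follow-up times (months).
#' @param event 0/1 event indicators (1 = event observed).
#' @param patient_id optional identifiers.
#' @return data.frame of class `surv_data` with columns `time`, `event`
#'   (and `patient_id` if given).
#' @export
surv_data <- function(time, event, patient_id = NULL) {
  stopifnot(length(time) == length(event))
  if (any(!is.finite(time)) || any(time < 0)) stop("times must be finite and >= 0")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  out <- data.frame(time = as.numeric(time), event = as.integer(event))
  if (!is.null(patient_id)) out$patient_id <- patient_id
  class(out) <- c("surv_data", "data.frame")
  out
}

#' Kaplan-Meier product-limit estimate
#'
#' Thin, typed wrapper around the standard product-limit estimator with
#' right censoring; ties are handled by simultaneous risk-set reduction.
#'
#' @param surv a [surv_data()] (or data.frame with `time`, `event`).
#' @return data.frame of class `km_curve`: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`.
#' @export
km_estimate <- function(surv) {
  stopifnot(nrow(surv) > 0)
  fit <- survival::survfit(survival::Surv(surv$time, surv$event) ~ 1,
                           conf.type = "none")
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' k-sample log-rank test
#'
#' Observed-minus-expected event counts with the hypergeometric variance,
#' chi-squared with `k - 1` degrees of freedom.
#'
#' @param groups group labels, one per patient (>= 2 non-empty groups).
#' @param surv a [surv_data()].
#' @return List of class `logrank_result`: `chi2`, `df`, `p`, `observed`,
#'   `expected`.
#' @export
logrank_test <- function(groups, surv) {
  g <- droplevels(as.factor(groups))
  if (length(g) != nrow(surv)) stop("groups and surv differ in length")
  if (nlevels(g) < 2L) stop("need >= 2 non-empty groups")
  if (any(table(g) == 0L)) stop("empty group")
  res <- logrank_chi2_cpp(as.numeric(surv$time), as.integer(surv$event),
                          as.integer(g), nlevels(g))
  df <- nlevels(g) - 1L
  out <- list(chi2 = res$chi2, df = df,
              p = pchisq(res$chi2, df, lower.tail = FALSE),
              observed = setNames(res$observed, levels(g)),
              expected = setNames(res$expected, levels(g)))
  class(out) <- "logrank_result"
  out
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("log-rank: chi2 = %.4g on %d df, p = %.4g\n", x$chi2, x$df, x$p))
  invisible(x)
}

#' Harrell's concordance index
#'
#' Convention: a higher score means higher risk, i.e. concordance means the
#' higher-scored member of a pair has the shorter survival. A pair is
#' usable only when the ordering of the event times is determinable under
#' censoring (the earlier time is an observed event and the times differ);
#' score ties count one half.
#'
#' @param score finite numeric risk scores.
#' @param surv a [surv_data()].
#' @return List of class `concordance_result`: `c`, `n_concordant`,
#'   `n_discordant`, `n_tied`, `n_usable`.
#' @export
harrell_c <- function(score, surv) {
  stopifnot(length(score) == nrow(surv), all(is.finite(score)))
  t <- surv$time; e <- surv$event
  # ordered pairs (i, j) where i's time is strictly shorter and i had the
  # event; each usable unordered pair appears exactly once
  short <- outer(t, t, "<") & (e == 1L)
  sgt <- outer(score, score, ">")
  seq_ <- outer(score, score, "==")
  n_con <- sum(short & sgt)
  n_tie <- sum(short & seq_)
  n_use <- sum(short)
  n_dis <- n_use - n_con - n_tie
  if (n_use == 0L) stop("no usable pairs (all times tied or censored)")
  out <- list(c = (n_con + 0.5 * n_tie) / n_use,
              n_concordant = n_con, n_discordant = n_dis,
              n_tied = n_tie, n_usable = n_use)
  class(out) <- "concordance_result"
  out
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("Harrell's C = %.4f (%d usable pairs)\n", x$c, x$n_usable))
  invisible(x)
}

#' Log-rank-maximizing cutpoints for score trichotomization
#'
#' Exhaustive search over ordered pairs of candidate cutpoints (midpoints
#' between consecutive sorted unique scores) that satisfy a minimum
#' per-group size, returning the pair maximizing the log-rank chi-squared
#' (equivalently minimizing its p-value at fixed df). Ties resolve
#' deterministically to the smaller first cutpoint, then the smaller
#' second. Two-group search is supported with a single cutpoint.
#'
#' Note the selected p-value is an optimized minimum and is anti-
#' conservative; it is reported as-is (the customary usage) without
#' correction.
#'
#' @param score numeric score per patient.
#' @param surv a [surv_data()].
#' @param n_groups 3 (default) or 2.
#' @param min_frac minimum group size as a fraction of n (default 0.10).
#' @return List of class `cutpoint_result`: `cutpoints`, `chi2`, `p`,
#'   `group_sizes`, `groups` (integer codes 0..n_groups-1, ascending risk
#'   in score order).
#' @export
optimal_cutpoints <- function(score, surv, n_groups = 3L, min_frac = 0.10) {
  stopifnot(length(score) == nrow(surv), all(is.finite(score)),
            n_groups %in% c(2L, 3L), min_frac > 0, min_frac < 0.5)
  n <- length(score)
  min_n <- max(1L, ceiling(min_frac * n))
  u <- sort(unique(score))
  if (length(u) < n_groups)
    stop("score has fewer distinct values than groups requested")
  cuts <- (u[-1L] + u[-length(u)]) / 2
  if (n_groups == 3L) {
    res <- cutpoint_grid_search(as.numeric(surv$time),
                                as.integer(surv$event),
                                as.numeric(score), cuts, min_n)
    if (res$n_evaluated == 0 || res$chi2 < 0)
      stop("min-group-size constraint infeasible for 3 groups; ",
           "largest feasible n_groups is ",
           if (sum(score <= cuts[1]) >= min_n) 2 else 1)
    cp <- c(res$c1, res$c2)
    sizes <- c(res$n1, res$n2, res$n3)
    chi2 <- res$chi2
  } else {
    best <- NULL
    for (cc in cuts) {
      lo <- score <= cc
      if (sum(lo) < min_n || sum(!lo) < min_n) next
      lt <- logrank_test(ifelse(lo, 0L, 1L), surv)
      if (is.null(best) || lt$chi2 > best$chi2)
        best <- list(chi2 = lt$chi2, cut = cc,
                     sizes = c(sum(lo), sum(!lo)))
    }
    if (is.null(best)) stop("min-group-size constraint infeasible for 2 groups")
    cp <- best$cut
    sizes <- best$sizes
    chi2 <- best$chi2
  }
  groups <- as.integer(cut(score, c(-Inf, cp, Inf), labels = FALSE)) - 1L
  # internal consistency: the objective equals the log-rank statistic at
  # the returned stratification
  check <- logrank_test(groups, surv)
  if (abs(check$chi2 - chi2) > 1e-8 * max(1, abs(chi2)))
    stop("internal error: cutpoint objective does not match log-rank test")
  df <- n_groups - 1L
  out <- list(cutpoints = cp, chi2 = chi2,
              p = pchisq(chi2, df, lower.tail = FALSE),
              group_sizes = sizes, groups = groups)
  class(out) <- "cutpoint_result"
  out
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf("optimal cutpoints: %s | chi2 = %.4g, p = %.4g | groups: %s\n",
              paste(signif(x$cutpoints, 4), collapse = ", "),
              x$chi2, x$p, paste(x$group_sizes, collapse = "/")))
  invisible(x)
}

#' Side-by-side comparison of prognostic indices
#'
#' For each index: stratify into risk groups (fixed cutpoints if supplied,
#' otherwise log-rank-optimized), then report the log-rank chi-squared and
#' p for OS (and PFS if given) together with Harrell's C of the continuous
#' score.
#'
#' @param indices named list of per-patient numeric scores.
#' @param surv OS [surv_data()].
#' @param pfs optional PFS [surv_data()].
#' @param cutpoints optional named list; entries give fixed cutpoints for
#'   that index (others are optimized).
#' @param n_groups,min_frac passed to [optimal_cutpoints()].
#' @return data.frame, one row per index, plus a `stratification` attribute
#'   (list of group codes per index).
#' @export
compare_indices <- function(indices, surv, pfs = NULL, cutpoints = list(),
                            n_groups = 3L, min_frac = 0.10) {
  stopifnot(is.list(indices), length(indices) >= 1L,
            !is.null(names(indices)))
  rows <- list()
  strat <- list()
  for (nm in names(indices)) {
    sc <- indices[[nm]]
    keep <- is.finite(sc)
    s_os <- surv[keep, , drop = FALSE]
    if (!is.null(cutpoints[[nm]])) {
      cp <- cutpoints[[nm]]
      grp <- as.integer(cut(sc[keep], c(-Inf, cp, Inf), labels = FALSE)) - 1L
    } else {
      opt <- optimal_cutpoints(sc[keep], s_os, n_groups, min_frac)
      cp <- opt$cutpoints
      grp <- opt$groups
    }
    strat[[nm]] <- grp
    n_distinct <- length(unique(grp))
    if (n_distinct < 2L) {
      lr <- list(chi2 = NA_real_, df = NA_integer_, p = NA_real_)
      note <- "single stratum; log-rank skipped"
    } else {
      lr <- logrank_test(grp, s_os)
      note <- ""
    }
    hc <- harrell_c(sc[keep], s_os)
    row <- data.frame(index = nm, n = sum(keep),
                      cut1 = cp[1],
                      cut2 = if (length(cp) > 1) cp[2] else NA_real_,
                      chi2_os = lr$chi2, df = lr$df, p_os = lr$p,
                      harrell_c = hc$c, note = note,
                      stringsAsFactors = FALSE)
    if (!is.null(pfs)) {
      p_pfs <- pfs[keep, , drop = FALSE]
      lr_p <- if (n_distinct < 2L) list(chi2 = NA_real_, p = NA_real_)
              else logrank_test(grp, p_pfs)
      row$chi2_pfs <- lr_p$chi2
      row$p_pfs <- lr_p$p
    }
    rows[[nm]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "stratification") <- strat
  out
}

#' Kaplan-Meier plot by risk group
#'
#' @param surv a [surv_data()].
#' @param groups group labels.
#' @param title plot title.
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_km <- function(surv, groups, title = "Kaplan-Meier by risk group") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_km requires ggplot2")
  g <- as.factor(groups)
  dfs <- lapply(levels(g), function(l) {
    km <- km_estimate(surv[g == l, , drop = FALSE])
    data.frame(time = c(0, km$time), surv = c(1, km$surv), group = l)
  })
  dd <- do.call(rbind, dfs)
  ggplot2::ggplot(dd, ggplot2::aes(x = time, y = surv, colour = group)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "months", y = "survival probability", title = title) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
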