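#' Univariate Cox screen over all analytes
#'
#' Each analyte is standardized (zero mean, unit SD on the log2 scale,
#' missing values mean-imputed first) and fit in a univariate Cox
#' proportional-hazards model (partial likelihood, Efron tie handling).
#' Analytes with Wald p below `alpha` form the passing set; each passing
#' analyte is annotated with a scaled-Schoenfeld-residual PH test p-value
#' (violations are flagged, not excluded). Benjamini-Hochberg q-values are
#' reported for transparency but not used for filtering.
#'
#' @param x samples x analytes matrix (log2).
#' @param surv a [surv_data()] aligned with `x` rows.
#' @param alpha Wald p-value threshold for the passing set (default 0.05).
#' @return data.frame of class `cox_screen`: `analyte_id`, `beta` (per SD),
#'   `se`, `hr`, `ci_low`, `ci_high`, `p`, `q`, `pass`, `ph_p`,
#'   `ph_flag`. Constant or non-convergent analytes are skipped with a
#'   warning.
#' @export
cox_screen <- function(x, surv, alpha = 0.05) {
  stopifnot(is.matrix(x), nrow(x) == nrow(surv))
  if (sum(surv$event) < 2L) stop("need >= 2 events for Cox screening")
  x <- impute_missing(x)
  ss <- survival::Surv(surv$time, surv$event)
  ids <- colnames(x)
  if (is.null(ids)) ids <- sprintf("V%d", seq_len(ncol(x)))
  res <- vector("list", ncol(x))
  skipped <- character()
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    if (sd(v) == 0) {
      skipped <- c(skipped, ids[j])
      next
    }
    z <- (v - mean(v)) / sd(v)
    fit <- tryCatch(
      survival::coxph(ss ~ z, ties = "efron"),
      error = function(e) NULL, warning = function(w) {
        f <- suppressWarnings(survival::coxph(ss ~ z, ties = "efron"))
        if (!is.finite(f$coefficients) || abs(f$coefficients) > 20) NULL else f
      })
    if (is.null(fit) || !is.finite(fit$coefficients)) {
      skipped <- c(skipped, ids[j])
      next
    }
    b <- unname(fit$coefficients)
    se <- sqrt(unname(fit$var[1, 1]))
    res[[j]] <- data.frame(
      analyte_id = ids[j], beta = b, se = se, hr = exp(b),
      ci_low = exp(b - 1.96 * se), ci_high = exp(b + 1.96 * se),
      p = 2 * stats::pnorm(-abs(b / se)), stringsAsFactors = FALSE)
  }
  if (length(skipped))
    warning(sprintf("%d analyte(s) skipped (constant or non-convergent)",
                    length(skipped)))
  out <- do.call(rbind, res)
  if (is.null(out)) stop("no analyte could be fit")
  out$q <- p.adjust(out$p, "BH")
  out$pass <- out$p < alpha
  out$ph_p <- NA_real_
  # Schoenfeld PH check on the passing set only
  for (i in which(out$pass)) {
    v <- x[, out$analyte_id[i]]
    z <- (v - mean(v)) / sd(v)
    zp <- tryCatch(
      survival::cox.zph(survival::coxph(ss ~ z, ties = "efron")),
      error = function(e) NULL)
    if (!is.null(zp)) out$ph_p[i] <- zp$table["z", "p"]
  }
  out$ph_flag <- !is.na(out$ph_p) & out$ph_p < 0.05
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "skipped") <- skipped
  class(out) <- c("cox_screen", "data.frame")
  out
}

#' Dichotomize a survival outcome into classifier labels
#'
#' The SVM/ROC step of the backward-elimination arm needs a binary label:
#' by default the event indicator (died during follow-up vs. not);
#' alternatively an above/below-median split of observed time.
#'
#' @param surv a [surv_data()].
#' @param method `"event"` (default) or `"median"`.
#' @return Integer labels in {0, 1}; errors if only one class results.
#' @export
dichotomize_outcome <- function(surv, method = c("event", "median")) {
  method <- match.arg(method)
  lab <- if (method == "event") as.integer(surv$event)
         else as.integer(surv$time > median(surv$time))
  if (length(unique(lab)) < 2L)
    stop("outcome dichotomization produced a single class")
  lab
}

#' ROC AUC with mid-rank tie handling
#'
#' @param scores numeric decision values.
#' @param labels 0/1 class labels (1 = positive).
#' @return AUC in `[0, 1]`.
#' @export
auc_midrank <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) stop("AUC needs both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Leave-one-out cross-validated SVM AUC
#'
#' For every sample, a linear-kernel SVM (fixed regularization C = 1, no
#' internal tuning) is trained on the remaining samples -- features
#' standardized within each training fold -- and the held-out sample is
#' scored by its decision value; the AUC over all held-out scores is
#' returned. Fully deterministic.
#'
#' @param x samples x features matrix.
#' @param labels 0/1 labels.
#' @param cost SVM regularization constant (default 1).
#' @return AUC in `[0, 1]`; constant features yield uninformative scores
#'   and an AUC of 0.5.
#' @export
loocv_auc <- function(x, labels, cost = 1) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(labels), all(labels %in% c(0, 1)))
  if (length(unique(labels)) < 2L) stop("need both classes")
  y <- ifelse(labels == 1, 1L, -1L)
  dec <- svm_loocv_decision(x, as.integer(y), C = cost)
  auc_midrank(dec, labels)
}

#' Backward-elimination configuration
#'
#' @param n_runs number of seeded BE runs whose intersection forms the
#'   consensus (default 12).
#' @param subsample_fraction patient fraction drawn (stratified by class)
#'   per run (default 0.9) -- the source of run-to-run variability.
#' @param wilcoxon_alpha rank-sum p threshold for the per-run candidate
#'   filter (default 0.05).
#' @param auc_tolerance margin of the removal rule (default 0.01).
#' @param removal_rule `"improve"` (default): a feature is removed only
#'   while the best resulting AUC exceeds the current AUC by more than the
#'   tolerance, so elimination stops once no removal clearly helps and the
#'   per-run selection is dominated by the rank-sum filter (matching the
#'   reported per-run panel sizes); `"no_drop"`: removed while the best
#'   resulting AUC is at least the current AUC minus the tolerance
#'   (plateau removals allowed -- this churns interchangeable clones at
#'   saturated AUC; see the methods vignette).
#' @param min_panel stop eliminating when this many features remain.
#' @param cost SVM regularization constant.
#' @param label_method passed to [dichotomize_outcome()].
#' @param rng_seed seed from which the per-run seeds are derived.
#' @return List of class `be_config`.
#' @export
be_config <- function(n_runs = 12L, subsample_fraction = 0.9,
                      wilcoxon_alpha = 0.05, auc_tolerance = 0.01,
                      removal_rule = c("improve", "no_drop"),
                      min_panel = 2L, cost = 1, label_method = "event",
                      rng_seed = 1L) {
  stopifnot(n_runs >= 1L, subsample_fraction > 0, subsample_fraction <= 1,
            wilcoxon_alpha > 0, wilcoxon_alpha <= 1, min_panel >= 1L)
  structure(list(n_runs = as.integer(n_runs),
                 subsample_fraction = subsample_fraction,
                 wilcoxon_alpha = wilcoxon_alpha,
                 auc_tolerance = auc_tolerance,
                 removal_rule = match.arg(removal_rule),
                 min_panel = as.integer(min_panel), cost = cost,
                 label_method = label_method,
                 rng_seed = as.integer(rng_seed)),
            class = "be_config")
}

#' Repeated backward elimination with SVM/LOOCV consensus
#'
#' Per run: a stratified patient subsample is drawn; candidates are
#' filtered by Wilcoxon rank-sum p < `wilcoxon_alpha` between outcome
#' classes on the subsample; then features are removed one at a time --
#' always the removal yielding the highest LOOCV AUC, accepted while that
#' AUC is no worse than the current AUC minus the tolerance (ties broken
#' by larger Wilcoxon p, then analyte id). The consensus is the
#' intersection of all runs' selections.
#'
#' @param x samples x analytes matrix (typically the screen's passing set).
#' @param surv a [surv_data()].
#' @param candidates analyte ids to start from.
#' @param cfg a [be_config()].
#' @param annotation optional analyte annotation; when given, a consensus
#'   at the target-protein level is also reported (a protein is in the
#'   consensus when every run retains at least one of its clones --
#'   interchangeable clones of one target otherwise alternate across runs
#'   and would rarely all survive a clone-level intersection).
#' @return List of class `be_result`: `runs` (data.frame: run, n_subsample,
#'   n_after_filter, n_selected, loocv_auc), `selected` (list of per-run
#'   selections), `consensus` (analyte-level character vector),
#'   `consensus_proteins` (protein ids, NULL without annotation).
#' @export
backward_eliminate <- function(x, surv, candidates, cfg = be_config(),
                               annotation = NULL) {
  stopifnot(inherits(cfg, "be_config"))
  if (length(candidates) == 0L) {
    warning("empty candidate set; empty consensus")
    return(structure(list(runs = NULL, selected = list(),
                          consensus = character()), class = "be_result"))
  }
  x <- impute_missing(as.matrix(x))
  miss <- setdiff(candidates, colnames(x))
  if (length(miss)) stop("candidates not in matrix: ", paste(miss, collapse = ", "))
  labels <- dichotomize_outcome(surv, cfg$label_method)
  n <- nrow(x)
  runs <- vector("list", cfg$n_runs)
  selected <- vector("list", cfg$n_runs)
  for (r in seq_len(cfg$n_runs)) {
    idx <- withr::with_seed(
      derive_seed(cfg$rng_seed, paste0("be_run_", r)), {
        keep <- unlist(lapply(split(seq_len(n), labels), function(ii) {
          k <- max(1L, round(cfg$subsample_fraction * length(ii)))
          sort(sample(ii, k))
        }), use.names = FALSE)
        sort(keep)
      })
    xs <- x[idx, , drop = FALSE]
    ls <- labels[idx]
    wilcox_p <- vapply(candidates, function(a) {
      suppressWarnings(
        wilcox.test(xs[ls == 1, a], xs[ls == 0, a], exact = FALSE)$p.value)
    }, numeric(1))
    feats <- candidates[!is.na(wilcox_p) & wilcox_p < cfg$wilcoxon_alpha]
    n_filtered <- length(feats)
    if (length(feats) == 0L) {
      runs[[r]] <- data.frame(run = r, n_subsample = length(idx),
                              n_after_filter = 0L, n_selected = 0L,
                              loocv_auc = NA_real_)
      selected[[r]] <- character()
      next
    }
    cur_auc <- loocv_auc(xs[, feats, drop = FALSE], ls, cfg$cost)
    repeat {
      if (length(feats) <= cfg$min_panel) break
      aucs <- vapply(seq_along(feats), function(k) {
        loocv_auc(xs[, feats[-k], drop = FALSE], ls, cfg$cost)
      }, numeric(1))
      best <- max(aucs)
      qualifies <- if (cfg$removal_rule == "improve")
        best > cur_auc + cfg$auc_tolerance
      else best >= cur_auc - cfg$auc_tolerance
      if (!qualifies) break
      tie <- which(aucs >= best - 1e-12)
      if (length(tie) > 1L) {
        # least marginally informative first: larger Wilcoxon p, then id
        wp <- wilcox_p[feats[tie]]
        tie <- tie[order(-wp, feats[tie])]
      }
      drop_k <- tie[1L]
      cur_auc <- aucs[drop_k]
      feats <- feats[-drop_k]
    }
    runs[[r]] <- data.frame(run = r, n_subsample = length(idx),
                            n_after_filter = n_filtered,
                            n_selected = length(feats), loocv_auc = cur_auc)
    selected[[r]] <- feats
  }
  consensus <- Reduce(intersect, selected)
  consensus_proteins <- NULL
  if (!is.null(annotation)) {
    prot_sets <- lapply(selected, function(a)
      unique(annotation$protein_id[match(a, annotation$analyte_id)]))
    consensus_proteins <- sort(Reduce(intersect, prot_sets))
  }
  structure(list(runs = do.call(rbind, runs), selected = selected,
                 consensus = consensus,
                 consensus_proteins = consensus_proteins),
            class = "be_result")
}

#' @export
print.be_result <- function(x, ...) {
  if (is.null(x$runs)) {
    cat("backward elimination: empty candidate set\n")
    return(invisible(x))
  }
  cat(sprintf("backward elimination: %d runs, mean AUC %.3f, consensus %d analytes\n",
              nrow(x$runs), mean(x$runs$loocv_auc, na.rm = TRUE),
              length(x$consensus)))
  invisible(x)
}

#' Collapse a clone-level selection to proteins
#'
#' Proteins hit by multiple selected clones keep the clone with the
#' smallest univariate Cox p-value (deterministic tie-break by analyte
#' id).
#'
#' @param analytes selected analyte ids.
#' @param screen a [cox_screen()] result covering these analytes.
#' @param annotation data.frame with `analyte_id`, `protein_id`.
#' @return data.frame: `protein_id`, `analyte_id` (representative clone),
#'   `beta`, `p`.
#' @export
dedupe_clones <- function(analytes, screen, annotation) {
  if (length(analytes) == 0L)
    return(data.frame(protein_id = character(), analyte_id = character(),
                      beta = numeric(), p = numeric()))
  un <- setdiff(analytes, annotation$analyte_id)
  if (length(un)) stop("unannotated analyte(s): ", paste(un, collapse = ", "))
  sc <- screen[match(analytes, screen$analyte_id), c("analyte_id", "beta", "p")]
  if (any(is.na(sc$analyte_id)))
    stop("analyte(s) missing from the Cox screen table")
  sc$protein_id <- annotation$protein_id[match(analytes, annotation$analyte_id)]
  sc <- sc[order(sc$p, sc$analyte_id), ]
  out <- sc[!duplicated(sc$protein_id),
            c("protein_id", "analyte_id", "beta", "p")]
  out <- out[order(out$protein_id), ]
  rownames(out) <- NULL
  out
}

#' Elastic-net configuration
#'
#' @param alpha_grid mixing parameters to scan (default 0, 0.1, ..., 1).
#' @param train_fraction training split fraction (default 0.8).
#' @param nfolds internal CV folds for the penalty strength.
#' @param response `"os_months"` (observed time, censoring ignored --
#'   mirroring RMSE-in-months model selection; a documented limitation) or
#'   `"events_only"` (fit on patients with observed events).
#' @param rng_seed seed for the split and fold assignment.
#' @return List of class `enr_config`.
#' @export
enr_config <- function(alpha_grid = seq(0, 1, by = 0.1),
                       train_fraction = 0.8, nfolds = 10L,
                       response = c("os_months", "events_only"),
                       rng_seed = 1L) {
  stopifnot(all(alpha_grid >= 0 & alpha_grid <= 1),
            train_fraction > 0, train_fraction < 1, nfolds >= 3L)
  structure(list(alpha_grid = alpha_grid, train_fraction = train_fraction,
                 nfolds = as.integer(nfolds),
                 response = match.arg(response),
                 rng_seed = as.integer(rng_seed)),
            class = "enr_config")
}

#' Elastic-net regression arm of the consensus selection
#'
#' The full analyte panel is regressed on observed survival months with an
#' 80/20 train/test split: for each mixing parameter alpha in the grid an
#' elastic net is fit with internally cross-validated penalty strength on
#' the training split and evaluated by RMSE and R-squared on the test
#' split; the minimum-RMSE model wins (ties to the larger R-squared). The
#' nonzero-coefficient analytes form the selection; when `screen` and
#' `annotation` are given, proteins hit by multiple clones (or clones with
#' contradictory signs) are resolved by deferring to the univariate Cox
#' results.
#'
#' @param x samples x analytes matrix.
#' @param surv a [surv_data()].
#' @param cfg an [enr_config()].
#' @param screen optional [cox_screen()] result for the dedupe rule.
#' @param annotation optional analyte annotation for protein collapsing.
#' @return List of class `enr_result`: `chosen_alpha`, `rmse`, `r2`,
#'   `path` (per-alpha table), `coefficients` (named, nonzero),
#'   `selected_analytes`, `selected_proteins` (if resolvable),
#'   `ridge_full_panel` flag.
#' @export
enr_select <- function(x, surv, cfg = enr_config(), screen = NULL,
                       annotation = NULL) {
  stopifnot(inherits(cfg, "enr_config"))
  x <- impute_missing(as.matrix(x))
  keep <- rep(TRUE, nrow(x))
  if (cfg$response == "events_only") keep <- surv$event == 1
  xx <- x[keep, , drop = FALSE]
  y <- surv$time[keep]
  n <- nrow(xx)
  n_test <- n - floor(cfg$train_fraction * n)
  if (n_test < 5L)
    stop("test split has < 5 samples; enlarge the cohort or lower train_fraction")
  sp <- withr::with_seed(derive_seed(cfg$rng_seed, "enr_split"), {
    tr <- sort(sample.int(n, floor(cfg$train_fraction * n)))
    fid <- sample(rep(seq_len(cfg$nfolds), length.out = length(tr)))
    list(tr = tr, fid = fid)
  })
  tr <- sp$tr
  xtr <- xx[tr, , drop = FALSE]
  ytr <- y[tr]
  xte <- xx[-tr, , drop = FALSE]
  yte <- y[-tr]
  path <- data.frame(alpha = cfg$alpha_grid, lambda = NA_real_,
                     rmse = NA_real_, r2 = NA_real_, n_nonzero = NA_integer_)
  fits <- vector("list", length(cfg$alpha_grid))
  for (i in seq_along(cfg$alpha_grid)) {
    cvfit <- glmnet::cv.glmnet(xtr, ytr, alpha = cfg$alpha_grid[i],
                               foldid = sp$fid, standardize = TRUE)
    pred <- as.vector(predict(cvfit, newx = xte, s = "lambda.min"))
    path$lambda[i] <- cvfit$lambda.min
    path$rmse[i] <- sqrt(mean((yte - pred)^2))
    path$r2[i] <- 1 - sum((yte - pred)^2) / sum((yte - mean(yte))^2)
    cf <- coef(cvfit, s = "lambda.min")
    path$n_nonzero[i] <- sum(cf[-1] != 0)
    fits[[i]] <- cvfit
  }
  ord <- order(path$rmse, -path$r2)
  best <- ord[1L]
  cf <- coef(fits[[best]], s = "lambda.min")
  co <- setNames(as.vector(cf)[-1], rownames(cf)[-1])
  nz <- co[co != 0]
  ridge_full <- cfg$alpha_grid[best] == 0 && length(nz) == ncol(xx)
  if (ridge_full)
    warning("chosen alpha = 0 (ridge): no sparsity; selection is the full panel")
  out <- list(chosen_alpha = cfg$alpha_grid[best],
              rmse = path$rmse[best], r2 = path$r2[best], path = path,
              coefficients = nz, selected_analytes = names(nz),
              selected_proteins = NULL, ridge_full_panel = ridge_full)
  if (!is.null(screen) && !is.null(annotation) && length(nz)) {
    out$selected_proteins <- dedupe_clones(names(nz), screen, annotation)
  }
  class(out) <- "enr_result"
  out
}

#' @export
print.enr_result <- function(x, ...) {
  cat(sprintf(
    "elastic net: alpha = %.1f, test RMSE = %.2f months, R2 = %.3f, %d nonzero\n",
    x$chosen_alpha, x$rmse, x$r2, length(x$coefficients)))
  invisible(x)
}

#' Intersect the two selection arms into the signature panel
#'
#' The final signature is the protein-level intersection of the Cox-BE and
#' ENR panels; each protein carries its representative clone's univariate
#' Cox coefficient as its score weight.
#'
#' @param coxbe_proteins protein-level data.frame from the Cox-BE arm
#'   (as returned by [dedupe_clones()]), or a character vector of protein
#'   ids.
#' @param enr_proteins same for the ENR arm.
#' @param screen a [cox_screen()] result.
#' @param annotation analyte annotation.
#' @return data.frame of class `signature_panel`: `protein_id`,
#'   `analyte_id`, `beta`, `p` -- empty (with a warning) if the arms do not
#'   overlap.
#' @export
intersect_panels <- function(coxbe_proteins, enr_proteins, screen, annotation) {
  pid <- function(z) if (is.data.frame(z)) z$protein_id else as.character(z)
  common <- intersect(pid(coxbe_proteins), pid(enr_proteins))
  if (length(common) == 0L) {
    warning("selection arms do not overlap; empty signature panel")
    out <- data.frame(protein_id = character(), analyte_id = character(),
                      beta = numeric(), p = numeric())
    class(out) <- c("signature_panel", "data.frame")
    return(out)
  }
  cand <- annotation$analyte_id[annotation$protein_id %in% common]
  cand <- intersect(cand, screen$analyte_id)
  out <- dedupe_clones(cand, screen, annotation)
  class(out) <- c("signature_panel", "data.frame")
  out
}

#' Rank candidate signature lengths
#'
#' For each candidate panel, the coefficient-weighted score is computed and
#' evaluated by the univariate Cox p-value of the score and Harrell's C;
#' panels are ranked by C (descending), then p (ascending).
#'
#' @param panels named list of `signature_panel` data.frames.
#' @param x samples x analytes matrix.
#' @param surv a [surv_data()].
#' @return data.frame: panel, n_proteins, harrell_c, cox_p, rank.
#' @export
compare_signature_lengths <- function(panels, x, surv) {
  stopifnot(is.list(panels), length(panels) >= 1L, !is.null(names(panels)))
  rows <- lapply(names(panels), function(nm) {
    pan <- panels[[nm]]
    s <- compute_ris(x, pan)$s_continuous
    fit <- survival::coxph(survival::Surv(surv$time, surv$event) ~ s)
    pv <- summary(fit)$coefficients[1, "Pr(>|z|)"]
    data.frame(panel = nm, n_proteins = nrow(pan),
               harrell_c = harrell_c(s, surv)$c, cox_p = pv,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$harrell_c, out$cox_p), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
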