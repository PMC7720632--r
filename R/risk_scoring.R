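#' Compute the MCL International Prognostic Index (MIPI)
#'
#' The standard prognostic score for mantle cell lymphoma, built from age,
#' ECOG performance status, the LDH ratio (LDH over its upper limit of
#' normal) and white blood cell count:
#' `0.03535*age + 0.6978*[ECOG > 1] + 1.367*log10(ldh_ratio) +
#' 0.9393*log10(wbc in 10^6/L)`. The WBC term of the published index uses
#' counts per 10^6/L (cells per microlitre); clinical tables usually
#' record 10^9/L, so the input is multiplied by 1000 internally -- this is
#' what places typical scores around the published 5.7/6.2 category
#' boundaries. Categories: low risk at 5.7 or below, high risk at 6.2 or
#' above, intermediate strictly between.
#'
#' @param age years.
#' @param ecog ECOG performance status 0--4.
#' @param ldh_ratio LDH / upper limit of normal (> 0).
#' @param wbc white blood cell count, 10^9/L (> 0).
#' @param score optional precomputed MIPI score (skips the formula).
#' @return List: `score` (numeric, NA where components are missing) and
#'   `category` (factor LR/IR/HR).
#' @examples
#' # age 60, ECOG 0, normal LDH, WBC 10e9/L:
#' # 2.121 + 0 + 0 + 0.9393*log10(10000) = 5.878 -> IR
#' compute_mipi(age = 60, ecog = 0, ldh_ratio = 1, wbc = 10)
#' @export
compute_mipi <- function(age = NULL, ecog = NULL, ldh_ratio = NULL,
                         wbc = NULL, score = NULL) {
  if (is.null(score)) {
    if (is.null(age) || is.null(ecog) || is.null(ldh_ratio) || is.null(wbc))
      stop("supply either all MIPI components or a precomputed score")
    bad <- !is.na(ldh_ratio) & ldh_ratio <= 0 | !is.na(wbc) & wbc <= 0
    if (any(bad, na.rm = TRUE)) stop("ldh_ratio and wbc must be positive")
    if (any(!is.na(ecog) & (ecog < 0 | ecog > 4))) stop("ecog must be 0..4")
    score <- 0.03535 * age + 0.6978 * as.numeric(ecog > 1) +
      1.367 * log10(ldh_ratio) + 0.9393 * log10(wbc * 1000)
  }
  list(score = score, category = mipi_category(score))
}

#' MIPI risk category from a score
#'
#' Boundaries: LR at or below 5.7, HR at or above 6.2, IR strictly
#' between.
#'
#' @param score numeric MIPI score(s).
#' @return Factor with levels LR, IR, HR (NA preserved).
#' @export
mipi_category <- function(score) {
  cat <- ifelse(is.na(score), NA_character_,
                ifelse(score <= 5.7, "LR",
                       ifelse(score >= 6.2, "HR", "IR")))
  factor(cat, levels = c("LR", "IR", "HR"))
}

#' Compute the relapsed immune signature (RIS) score
#'
#' The panel's analytes are standardized within the cohort (zero mean,
#' unit SD of their log2 signal) and combined linearly with the panel's
#' univariate Cox coefficients: `s = sum_i beta_i * z_i`. Because the
#' signature proteins are protective (negative beta), low expression gives
#' a high score, i.e. higher `s` means higher risk. The ternary coding
#' (0/1/2, ascending risk) splits `s` at two cutpoints chosen by log-rank
#' maximization unless fixed cutpoints are supplied.
#'
#' Patients missing some panel proteins are imputed with the mean of their
#' available panel z-scores (flagged in the `n_imputed` attribute).
#'
#' @param x samples x analytes matrix (log2).
#' @param panel a `signature_panel` (protein_id, analyte_id, beta).
#' @param surv a [surv_data()]; required unless `cutpoints` is given or
#'   `ternary = FALSE`.
#' @param cutpoints optional fixed cutpoints `c(c1, c2)`.
#' @param ternary compute the ternary code (default TRUE).
#' @param min_frac minimum group fraction for the cutpoint search.
#' @return data.frame: `s_continuous` and (if requested) `s_ternary`;
#'   attributes `cutpoints` and `n_imputed`.
#' @export
compute_ris <- function(x, panel, surv = NULL, cutpoints = NULL,
                        ternary = !is.null(surv) || !is.null(cutpoints),
                        min_frac = 0.10) {
  stopifnot(is.data.frame(panel), nrow(panel) >= 1L,
            all(c("analyte_id", "beta") %in% names(panel)))
  miss <- setdiff(panel$analyte_id, colnames(x))
  if (length(miss)) stop("panel analytes absent from matrix: ",
                         paste(miss, collapse = ", "))
  xp <- x[, panel$analyte_id, drop = FALSE]
  z <- scale(xp)
  n_imp <- 0L
  if (anyNA(z)) {
    rm_ <- rowMeans(z, na.rm = TRUE)
    rm_[!is.finite(rm_)] <- 0
    idx <- which(is.na(z), arr.ind = TRUE)
    z[idx] <- rm_[idx[, 1L]]
    n_imp <- nrow(idx)
  }
  s <- as.vector(z %*% panel$beta)
  out <- data.frame(s_continuous = s)
  if (!is.null(rownames(x))) out$patient_id <- rownames(x)
  if (ternary) {
    if (is.null(cutpoints)) {
      if (is.null(surv)) stop("ternary coding needs surv or fixed cutpoints")
      opt <- optimal_cutpoints(s, surv, n_groups = 3L, min_frac = min_frac)
      cutpoints <- opt$cutpoints
    }
    out$s_ternary <- as.integer(cut(s, c(-Inf, cutpoints, Inf),
                                    labels = FALSE)) - 1L
  }
  attr(out, "cutpoints") <- cutpoints
  attr(out, "n_imputed") <- n_imp
  out
}

#' Weights of the combined prognostic index
#'
#' @param w_mipi,w_ris numeric weights; the published defaults are 0.708
#'   and 1.327 (multivariate Cox coefficients of MIPI and the ternary
#'   signature score).
#' @param source `"published"` or `"refit"`.
#' @return List of class `index_weights`.
#' @export
index_weights <- function(w_mipi = 0.708, w_ris = 1.327,
                          source = c("published", "refit")) {
  stopifnot(is.finite(w_mipi), is.finite(w_ris))
  structure(list(w_mipi = w_mipi, w_ris = w_ris,
                 source = match.arg(source)),
            class = "index_weights")
}

#' Multivariate Cox model of MIPI and the signature score
#'
#' Complete-case Cox regression of survival on the MIPI score and the
#' ternary signature score (optionally plus Ki-67 as a percentage), with
#' Benjamini-Hochberg q-values over the model's covariates. The fitted
#' coefficients provide refit weights for the combined index.
#'
#' @param mipi_score numeric per patient (NA allowed, dropped).
#' @param s_ternary ternary signature codes 0/1/2.
#' @param surv a [surv_data()].
#' @param ki67 optional percentage per patient.
#' @return List of class `multivariate_fit`: `weights`
#'   ([index_weights()] with source `"refit"`), `table` (beta, HR, CI, p,
#'   q per covariate), `n_complete`.
#' @export
fit_multivariate <- function(mipi_score, s_ternary, surv, ki67 = NULL) {
  stopifnot(length(mipi_score) == nrow(surv),
            length(s_ternary) == nrow(surv))
  df <- data.frame(time = surv$time, event = surv$event,
                   mipi = mipi_score, ris = s_ternary)
  if (!is.null(ki67)) df$ki67 <- ki67
  cc <- stats::complete.cases(df)
  df <- df[cc, ]
  if (sum(df$event) < 2L) stop("need >= 2 events among complete cases")
  form <- if (is.null(ki67)) survival::Surv(time, event) ~ mipi + ris
          else survival::Surv(time, event) ~ mipi + ris + ki67
  fit <- tryCatch(survival::coxph(form, data = df),
                  warning = function(w)
                    stop("multivariate Cox did not converge cleanly: ",
                         conditionMessage(w)))
  sm <- summary(fit)$coefficients
  tab <- data.frame(covariate = rownames(sm), beta = sm[, "coef"],
                    hr = sm[, "exp(coef)"], se = sm[, "se(coef)"],
                    p = sm[, "Pr(>|z|)"], stringsAsFactors = FALSE)
  tab$ci_low <- exp(tab$beta - 1.96 * tab$se)
  tab$ci_high <- exp(tab$beta + 1.96 * tab$se)
  tab$q <- p.adjust(tab$p, "BH")
  rownames(tab) <- NULL
  w <- index_weights(w_mipi = tab$beta[tab$covariate == "mipi"],
                     w_ris = tab$beta[tab$covariate == "ris"],
                     source = "refit")
  structure(list(weights = w, table = tab, n_complete = nrow(df)),
            class = "multivariate_fit")
}

#' @export
print.multivariate_fit <- function(x, ...) {
  cat(sprintf("multivariate Cox (n = %d complete cases):\n", x$n_complete))
  print(x$table[, c("covariate", "beta", "hr", "p", "q")], digits = 3)
  invisible(x)
}

#' Combined MIPI + signature index
#'
#' `w_mipi * mipi_score + w_ris * s_ternary`; strictly increasing in each
#' argument when both weights are positive. Patients missing either input
#' get NA (and are excluded from downstream stratification).
#'
#' @param mipi_score numeric MIPI scores.
#' @param s_ternary ternary signature codes 0/1/2.
#' @param weights an [index_weights()]; defaults to the published
#'   (0.708, 1.327).
#' @return Numeric vector of index values.
#' @examples
#' compute_mipi_ris(5, 1) # 0.708*5 + 1.327*1 = 4.867
#' @export
compute_mipi_ris <- function(mipi_score, s_ternary,
                             weights = index_weights()) {
  stopifnot(inherits(weights, "index_weights"))
  n <- max(length(mipi_score), length(s_ternary))
  if (length(mipi_score) == 1L) mipi_score <- rep_len(mipi_score, n)
  if (length(s_ternary) == 1L) s_ternary <- rep_len(s_ternary, n)
  stopifnot(length(mipi_score) == length(s_ternary))
  weights$w_mipi * mipi_score + weights$w_ris * s_ternary
}
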