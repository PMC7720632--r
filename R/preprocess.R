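#' Aggregate replicate spots with the 15% CV rule
#'
#' Local background is removed (`fg - bg`), flagged or non-positive spots
#' are set invalid, and each (sample, analyte) triplet is collapsed to one
#' signal: if the coefficient of variation (SD/mean) of three valid
#' replicates is at most `cv_threshold` the mean of the three is used;
#' otherwise the outlier replicate -- the one farthest from the triplet
#' median (ties resolved to the higher replicate index) -- is eliminated
#' and the remaining two are averaged. Two valid replicates are averaged
#' directly; fewer than two yield a missing value.
#'
#' @param spots a raw spot table (see [read_spot_table()] for the dialect).
#' @param cv_threshold CV above which the outlier replicate is dropped
#'   (default 0.15; a CV of exactly 0.15 keeps all three replicates).
#' @return A data.table with one row per (sample_id, analyte_id):
#'   `mean_signal`, `cv` (of the replicates used), `n_used` (0, 2 or 3) and
#'   `eliminated_replicate` (NA unless the CV rule fired).
#' @examples
#' spots <- data.table::data.table(
#'   sample_id = "S1", analyte_id = "A1", replicate = 1:3,
#'   fg = c(200, 200, 300), bg = 100, flag = "ok")
#' aggregate_replicates(spots) # CV 0.43 > 0.15: drops 200, mean 100
#' @export
aggregate_replicates <- function(spots, cv_threshold = 0.15) {
  stopifnot(cv_threshold > 0, cv_threshold < 1)
  dt <- data.table::as.data.table(spots)
  need <- c("sample_id", "analyte_id", "replicate", "fg", "bg", "flag")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("spot table is missing column(s): ", paste(miss, collapse = ", "))
  if (any(dt$replicate < 1L | dt$replicate > 3L))
    stop("replicate index outside 1..3")
  dt <- dt[, .(sample_id, analyte_id, replicate,
               net = fg - bg, valid = flag == "ok" & (fg - bg) > 0)]
  if (anyDuplicated(dt[, .(sample_id, analyte_id, replicate)]))
    stop("duplicate (sample_id, analyte_id, replicate) rows")

  wide <- data.table::dcast(dt, sample_id + analyte_id ~ replicate,
                            value.var = c("net", "valid"), fill = NA)
  for (nm in c("net_1", "net_2", "net_3", "valid_1", "valid_2", "valid_3"))
    if (!nm %in% names(wide)) wide[[nm]] <- if (grepl("net", nm)) NA_real_ else NA
  v <- as.matrix(wide[, .(valid_1, valid_2, valid_3)])
  v[is.na(v)] <- FALSE
  x <- as.matrix(wide[, .(net_1, net_2, net_3)])
  x[!v] <- NA_real_

  nv <- rowSums(v)
  m3 <- rowMeans(x, na.rm = TRUE)
  sd3 <- apply(x, 1L, sd, na.rm = TRUE)
  cv_all <- ifelse(nv >= 2 & m3 > 0, sd3 / m3, NA_real_)

  mean_signal <- rep(NA_real_, nrow(x))
  cv_used <- rep(NA_real_, nrow(x))
  n_used <- integer(nrow(x))
  eliminated <- rep(NA_integer_, nrow(x))

  two <- which(nv == 2)
  if (length(two)) {
    mean_signal[two] <- m3[two]
    cv_used[two] <- cv_all[two]
    n_used[two] <- 2L
  }
  three <- which(nv == 3)
  if (length(three)) {
    keep3 <- three[cv_all[three] <= cv_threshold]
    mean_signal[keep3] <- m3[keep3]
    cv_used[keep3] <- cv_all[keep3]
    n_used[keep3] <- 3L
    drop1 <- setdiff(three, keep3)
    if (length(drop1)) {
      xo <- x[drop1, , drop = FALSE]
      med <- apply(xo, 1L, median)
      dev <- abs(xo - med)
      # farthest from the median; ties resolve to the higher replicate index
      out_idx <- max.col(dev, ties.method = "last")
      xo[cbind(seq_along(drop1), out_idx)] <- NA_real_
      m2 <- rowMeans(xo, na.rm = TRUE)
      s2 <- apply(xo, 1L, sd, na.rm = TRUE)
      mean_signal[drop1] <- m2
      cv_used[drop1] <- ifelse(m2 > 0, s2 / m2, NA_real_)
      n_used[drop1] <- 2L
      eliminated[drop1] <- out_idx
    }
  }
  out <- wide[, .(sample_id, analyte_id)]
  out[, `:=`(mean_signal = mean_signal, cv = cv_used, n_used = n_used,
             eliminated_replicate = eliminated)]
  out[]
}

#' Per-sample subarray quality report
#'
#' A spot counts as discarded if it is quality-flagged or its
#' background-subtracted signal is non-positive. A sample whose discarded
#' fraction exceeds 30\% (strictly) is flagged for assay repetition and is
#' excluded from the expression matrix by [preprocess_cohort()].
#'
#' @param spots raw spot table.
#' @param repeat_threshold discard fraction above which the assay is
#'   flagged (default 0.30, strict inequality).
#' @return data.frame: `sample_id`, `fraction_discarded`, `repeat_flag`.
#' @export
subarray_qc <- function(spots, repeat_threshold = 0.30) {
  dt <- data.table::as.data.table(spots)
  qc <- dt[, .(fraction_discarded = mean(!(flag == "ok" & (fg - bg) > 0))),
           by = sample_id]
  qc[, repeat_flag := fraction_discarded > repeat_threshold]
  as.data.frame(qc)
}

#' Trim extreme signals per analyte
#'
#' For each analyte (column) across samples, values beyond the 5th/95th
#' percentiles (linear-interpolation quantile definition, R type 7) are
#' either winsorized to those percentiles (default) or discarded (set
#' missing), mirroring the two readings of "5% of the lower and upper
#' extreme values were discarded". Columns with fewer than `min_n`
#' non-missing values are passed through with a warning.
#'
#' @param x numeric matrix, samples x analytes, pre-log signals.
#' @param lower,upper percentile bounds (defaults 0.05 and 0.95).
#' @param mode `"winsorize"` (clamp, default) or `"discard"` (set NA).
#' @param min_n minimum non-missing values required to trim a column.
#' @return Matrix of the same shape.
#' @export
trim_extremes <- function(x, lower = 0.05, upper = 0.95,
                          mode = c("winsorize", "discard"), min_n = 10L) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(x), lower >= 0, upper <= 1, lower < upper)
  skipped <- 0L
  for (j in seq_len(ncol(x))) {
    ok <- !is.na(x[, j])
    if (sum(ok) < min_n) {
      skipped <- skipped + 1L
      next
    }
    q <- quantile(x[ok, j], c(lower, upper), type = 7, names = FALSE)
    if (mode == "winsorize") {
      x[, j] <- pmin(pmax(x[, j], q[1]), q[2])
    } else {
      x[ok, j][x[ok, j] < q[1] | x[ok, j] > q[2]] <- NA_real_
    }
  }
  if (skipped > 0L)
    warning(sprintf("trimming skipped for %d analyte(s) with < %d values",
                    skipped, min_n))
  x
}

#' Log2-transform a signal matrix
#'
#' Non-positive or missing signals become missing values; everything else
#' is `log2()`.
#'
#' @param x numeric matrix of linear-scale signals.
#' @return Matrix of log2 signals with missingness propagated.
#' @export
log2_transform <- function(x) {
  x[!is.na(x) & x <= 0] <- NA_real_
  log2(x)
}

#' Parametric empirical-Bayes batch correction (ComBat)
#'
#' Location/scale batch adjustment following the parametric empirical-Bayes
#' scheme: each analyte is standardized against its pooled (batch-mean
#' adjusted) variance, per-batch location and scale are estimated, shrunk
#' toward their across-analyte priors (normal prior on location,
#' inverse-gamma on scale, hyperparameters by moment matching, joint
#' estimates by fixed-point iteration), and the data are adjusted and
#' back-transformed. A final per-analyte recentring step restores each
#' analyte's grand mean exactly. Only the batch factor enters the model
#' (no biological covariates).
#'
#' @param x numeric matrix, samples x analytes (log2 scale).
#' @param batch factor-like vector of batch labels, one per sample.
#' @param conv convergence tolerance of the EB fixed-point iteration.
#' @return Corrected matrix, same shape and dimnames; with a single batch
#'   the input is returned unchanged (there is no batch contrast to
#'   estimate). All-missing or zero-variance analytes pass through.
#' @export
combat_correct <- function(x, batch, conv = 1e-4) {
  stopifnot(is.matrix(x), length(batch) == nrow(x))
  batch <- droplevels(as.factor(batch))
  nb <- nlevels(batch)
  if (nb == 1L) return(x)
  tab <- table(batch)
  if (any(tab < 2L))
    stop("each batch needs >= 2 samples (merge or drop batch(es): ",
         paste(names(tab)[tab < 2], collapse = ", "), ")")
  dat <- t(x) # genes x samples
  G <- nrow(dat); n <- ncol(dat)
  b_idx <- lapply(levels(batch), function(l) which(batch == l))

  # per-gene per-batch means and counts (NA-aware)
  bmean <- sapply(b_idx, function(ii) rowMeans(dat[, ii, drop = FALSE],
                                               na.rm = TRUE))
  bn <- sapply(b_idx, function(ii) rowSums(!is.na(dat[, ii, drop = FALSE])))
  ntot <- rowSums(bn)
  usable <- ntot >= 2 & apply(bn, 1L, function(z) all(z >= 1))

  fitted <- matrix(NA_real_, G, n)
  for (b in seq_len(nb)) fitted[, b_idx[[b]]] <- bmean[, b]
  resid <- dat - fitted
  var_pooled <- rowSums(resid^2, na.rm = TRUE) / ntot
  usable <- usable & var_pooled > 0
  if (!any(usable)) return(x)

  grand <- rowSums(bmean * bn, na.rm = TRUE) / ntot
  sdat <- (dat - grand) / sqrt(var_pooled)

  gamma_hat <- sapply(b_idx, function(ii) rowMeans(sdat[, ii, drop = FALSE],
                                                   na.rm = TRUE))
  delta_hat <- sapply(b_idx, function(ii)
    apply(sdat[, ii, drop = FALSE], 1L, var, na.rm = TRUE))

  adj <- sdat
  for (b in seq_len(nb)) {
    g <- gamma_hat[usable, b]
    d <- delta_hat[usable, b]
    d[!is.finite(d) | d <= 0] <- 1
    gbar <- mean(g); t2 <- var(g)
    m <- mean(d); s2 <- var(d)
    a_prior <- (2 * s2 + m^2) / s2
    b_prior <- (m * s2 + m^3) / s2
    ii <- b_idx[[b]]
    sub <- sdat[usable, ii, drop = FALSE]
    nobs <- rowSums(!is.na(sub))
    g_new <- g; d_new <- d
    repeat {
      g_old <- g_new; d_old <- d_new
      g_new <- (t2 * nobs * g + d_old * gbar) / (t2 * nobs + d_old)
      sum2 <- rowSums((sub - g_new)^2, na.rm = TRUE)
      d_new <- (0.5 * sum2 + b_prior) / (nobs / 2 + a_prior - 1)
      change <- max(abs(g_new - g_old) / pmax(abs(g_old), 1e-12),
                    abs(d_new - d_old) / pmax(abs(d_old), 1e-12))
      if (is.na(change) || change < conv) break
    }
    adj[usable, ii] <- (sub - g_new) / sqrt(d_new)
  }
  corrected <- adj * sqrt(var_pooled) + grand
  corrected[!usable, ] <- dat[!usable, ]
  # restore each analyte's grand mean exactly
  shift_back <- rowMeans(dat, na.rm = TRUE) - rowMeans(corrected, na.rm = TRUE)
  shift_back[!is.finite(shift_back)] <- 0
  corrected <- corrected + shift_back
  out <- t(corrected)
  dimnames(out) <- dimnames(x)
  out
}

#' Run the full pre-processing chain on a cohort
#'
#' Fixed order, matching the platform's processing narrative: background
#' subtraction, replicate aggregation (CV rule), subarray QC exclusion,
#' extreme-value trimming, log2 transformation, empirical-Bayes batch
#' correction on the scan-date factor.
#'
#' @param spots raw spot table (long format).
#' @param cv_threshold replicate CV threshold (default 0.15).
#' @param trim lower trim fraction (default 0.05; upper is `1 - trim`).
#' @param trim_mode `"winsorize"` or `"discard"`.
#' @param batch_column `"scan_batch"` (default) or `"slide_batch"`.
#' @param combat apply batch correction (default TRUE).
#' @return List: `x` (samples x analytes log2 matrix), `qc` (subarray QC
#'   report), `batch` (named batch factor used), `log` (character vector of
#'   processing messages).
#' @export
preprocess_cohort <- function(spots, cv_threshold = 0.15, trim = 0.05,
                              trim_mode = "winsorize",
                              batch_column = "scan_batch", combat = TRUE) {
  dt <- data.table::as.data.table(spots)
  if (!batch_column %in% names(dt))
    stop("batch column '", batch_column, "' not found in spot table")
  log <- character()
  agg <- aggregate_replicates(dt, cv_threshold = cv_threshold)
  qc <- subarray_qc(dt)
  bad <- qc$sample_id[qc$repeat_flag]
  if (length(bad)) {
    log <- c(log, paste("excluded (repeat_flag):", paste(bad, collapse = ", ")))
    agg <- agg[!sample_id %in% bad]
  }
  wide <- data.table::dcast(agg, sample_id ~ analyte_id,
                            value.var = "mean_signal")
  m <- as.matrix(wide[, -1L])
  rownames(m) <- wide$sample_id
  log <- c(log, sprintf("aggregated %d samples x %d analytes; %.2f%% missing",
                        nrow(m), ncol(m), 100 * mean(is.na(m))))
  m <- suppressWarnings(trim_extremes(m, trim, 1 - trim, mode = trim_mode))
  m <- log2_transform(m)
  batch_map <- unique(dt[, c("sample_id", batch_column), with = FALSE])
  batch <- setNames(as.character(batch_map[[batch_column]]),
                    batch_map$sample_id)[rownames(m)]
  if (combat) {
    m <- combat_correct(m, batch)
    log <- c(log, sprintf("ComBat on %s (%d batches)", batch_column,
                          length(unique(batch))))
  }
  log <- c(log, paste("order: bg-subtract > aggregate > QC > trim >",
                      "log2 > batch-correct"))
  list(x = m, qc = qc, batch = batch, log = log)
}

#' Impute missing expression values by per-analyte means
#'
#' @param x samples x analytes matrix.
#' @return Same matrix with NAs replaced by column means (columns that are
#'   entirely missing are filled with the grand mean); the number of
#'   imputed cells is recorded in the `"n_imputed"` attribute.
#' @export
impute_missing <- function(x) {
  n_imp <- sum(is.na(x))
  if (n_imp > 0) {
    cm <- colMeans(x, na.rm = TRUE)
    cm[!is.finite(cm)] <- mean(x, na.rm = TRUE)
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- cm[idx[, 2L]]
  }
  attr(x, "n_imputed") <- n_imp
  x
}
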