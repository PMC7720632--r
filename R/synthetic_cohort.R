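#' Configuration for the synthetic relapsed-MCL cohort generator
#'
#' Defaults emulate the shape of a serum antibody-microarray study in
#' relapsed/refractory mantle cell lymphoma: 371 scFv analytes targeting
#' 158 proteins with one to nine clones per target, three replicate spots
#' per analyte, three scan-date batches and two slide batches, exponential
#' proportional-hazards survival with a protective planted signature
#' (hazard ratio below 1 per SD of the latent protein level), and MIPI
#' covariates entering the hazard.
#'
#' @param n_patients cohort size (default 44, a typical relapsed trial arm).
#' @param n_proteins number of target proteins (default 158).
#' @param n_clones total number of scFv analytes (default 371); allocated
#'   one to nine clones per protein.
#' @param n_signature_proteins number of proteins with a planted survival
#'   effect (default 11).
#' @param signature_log_hr_per_sd log hazard ratio per SD of the latent
#'   protein level for each signature protein; must be `<= 0` (protective),
#'   recycled to `n_signature_proteins`.
#' @param n_scan_batches,n_slide_batches batch structure (defaults 3 and 2).
#' @param batch_shift additive log2 offset per scan batch (recycled).
#' @param batch_scale multiplicative dispersion factor per scan batch.
#' @param replicate_cv target mean coefficient of variation of a replicate
#'   triplet (sample CV; the generator corrects for the small-sample bias
#'   of the SD so the *observed* triplet CV averages this value).
#' @param outlier_spot_rate probability that one replicate of a triplet is
#'   corrupted (multiplied by a factor far above the noise scale), which
#'   exercises the CV > 15\% elimination rule downstream.
#' @param flagged_spot_rate probability a spot carries a quality flag.
#' @param censoring_rate target fraction of censored observations.
#' @param baseline_hazard events per month for a patient at the covariate
#'   mean (default `log(2)/15`: median OS 15 months).
#' @param follow_up_months administrative censoring horizon.
#' @param mipi_effect log hazard ratio per MIPI unit (centred).
#' @param ki67_effect log hazard ratio per Ki-67 percentage point (centred).
#' @param progression_hazard events per month for the progression process
#'   (PFS = min(OS, progression), sharing the patient's linear predictor).
#' @param signature_correlation equicorrelation among the signature
#'   proteins through a shared latent factor (default 0.5). The signature
#'   emulates a functionally coherent immune program, and this value
#'   reproduces the reported range of univariate per-SD hazard ratios for
#'   signature analytes (about 0.25--0.4); with independent signature
#'   proteins the marginal effects attenuate to roughly a third of the
#'   conditional ones.
#' @param block_correlation optional equicorrelation within consecutive
#'   blocks of 10 proteins (default 0, independence across the background
#'   proteome).
#' @param ki67_missing_rate,mipi_missing_rate fraction of patients with
#'   missing Ki-67 / missing MIPI components.
#' @param rng_seed integer seed; the whole cohort is a deterministic
#'   function of the configuration.
#' @return A list of class `sim_config`.
#' @seealso [generate_cohort()]
#' @export
simulation_config <- function(n_patients = 44,
                              n_proteins = 158,
                              n_clones = 371,
                              n_signature_proteins = 11,
                              signature_log_hr_per_sd = -1,
                              n_scan_batches = 3,
                              n_slide_batches = 2,
                              batch_shift = c(0, 0.6, -0.4),
                              batch_scale = c(1, 1.15, 0.9),
                              replicate_cv = 0.08,
                              outlier_spot_rate = 0.02,
                              flagged_spot_rate = 0.01,
                              censoring_rate = 0.4,
                              baseline_hazard = log(2) / 15,
                              follow_up_months = 36,
                              mipi_effect = 0.68,
                              ki67_effect = 0.02,
                              progression_hazard = log(2) / 13,
                              signature_correlation = 0.5,
                              block_correlation = 0,
                              ki67_missing_rate = 0.27,
                              mipi_missing_rate = 0.07,
                              rng_seed = 1L) {
  stopifnot(n_patients >= 2, n_proteins >= 1,
            n_signature_proteins >= 0, n_signature_proteins <= n_proteins,
            censoring_rate >= 0, censoring_rate < 1,
            replicate_cv >= 0, outlier_spot_rate >= 0, outlier_spot_rate <= 1,
            flagged_spot_rate >= 0, flagged_spot_rate <= 1,
            follow_up_months >= 0, progression_hazard > 0,
            signature_correlation >= 0, signature_correlation < 1,
            block_correlation >= 0, block_correlation < 1)
  if (baseline_hazard <= 0) stop("baseline_hazard must be positive")
  if (n_clones < n_proteins || n_clones > 9 * n_proteins)
    stop("infeasible clone allocation: need n_proteins <= n_clones <= 9 * n_proteins")
  beta <- rep_len(signature_log_hr_per_sd, n_signature_proteins)
  if (any(!is.finite(beta)) || any(beta > 0))
    stop("signature_log_hr_per_sd must be finite and <= 0 (protective effects)")
  cfg <- list(
    n_patients = as.integer(n_patients), n_proteins = as.integer(n_proteins),
    n_clones = as.integer(n_clones),
    n_signature_proteins = as.integer(n_signature_proteins),
    signature_log_hr_per_sd = beta,
    n_scan_batches = as.integer(n_scan_batches),
    n_slide_batches = as.integer(n_slide_batches),
    batch_shift = rep_len(batch_shift, n_scan_batches),
    batch_scale = rep_len(batch_scale, n_scan_batches),
    replicate_cv = replicate_cv, outlier_spot_rate = outlier_spot_rate,
    flagged_spot_rate = flagged_spot_rate,
    censoring_rate = censoring_rate, baseline_hazard = baseline_hazard,
    follow_up_months = follow_up_months, mipi_effect = mipi_effect,
    ki67_effect = ki67_effect, progression_hazard = progression_hazard,
    signature_correlation = signature_correlation,
    block_correlation = block_correlation,
    ki67_missing_rate = ki67_missing_rate,
    mipi_missing_rate = mipi_missing_rate,
    rng_seed = as.integer(rng_seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Allocate clone counts (1--9) to proteins
#'
#' Deterministic round-robin: every protein starts with one clone and the
#' remainder is dealt out cyclically (capped at nine per protein) until the
#' requested analyte total is reached; a seeded shuffle then assigns the
#' counts to proteins.
#'
#' @param n_proteins,n_clones totals to reconcile.
#' @param rng_seed seed for the shuffle.
#' @return Integer vector of length `n_proteins` summing to `n_clones`.
#' @export
allocate_clones <- function(n_proteins, n_clones, rng_seed = 1L) {
  if (n_clones < n_proteins || n_clones > 9 * n_proteins)
    stop("infeasible clone allocation")
  counts <- rep(1L, n_proteins)
  i <- 1L
  while (sum(counts) < n_clones) {
    if (counts[i] < 9L) counts[i] <- counts[i] + 1L
    i <- if (i == n_proteins) 1L else i + 1L
  }
  withr::with_seed(rng_seed, sample(counts))
}

# bias of the sample SD at n = 3 (normal c4 constant, sqrt(2/(n-1)) *
# gamma(n/2)/gamma((n-1)/2)); the generator inflates the population CV by
# 1/c4 so observed triplet sample CVs average the requested replicate_cv
.c4_3 <- sqrt(2 / 2) * gamma(3 / 2) / gamma(1)

#' Emit replicate spot triplets around latent clone intensities
#'
#' Three replicates per latent value with multiplicative log-normal noise
#' calibrated so the expected triplet sample CV equals `replicate_cv`.
#' With probability `outlier_spot_rate` one replicate (chosen at random) is
#' corrupted by a multiplicative shift of at least five times the noise
#' scale, guaranteeing the downstream CV > 15\% elimination path fires.
#'
#' @param latent positive vector of latent clone intensities (linear scale).
#' @param cfg a [simulation_config()].
#' @return Numeric matrix `length(latent)` x 3 of replicate intensities.
#' @export
emit_spot_replicates <- function(latent, cfg) {
  stopifnot(all(latent > 0))
  n <- length(latent)
  cv <- cfg$replicate_cv
  reps <- matrix(rep(latent, 3L), nrow = n, ncol = 3L)
  if (cv > 0) {
    sigma <- sqrt(log1p((cv / .c4_3)^2))
    noise <- matrix(exp(rnorm(3L * n, -sigma^2 / 2, sigma)), nrow = n)
    reps <- reps * noise
  }
  if (cfg$outlier_spot_rate > 0) {
    hit <- runif(n) < cfg$outlier_spot_rate
    if (any(hit)) {
      which_rep <- sample.int(3L, sum(hit), replace = TRUE)
      factor_out <- pmax(2.5, 1 + 10 * cv)
      reps[cbind(which(hit), which_rep)] <-
        reps[cbind(which(hit), which_rep)] * factor_out
    }
  }
  reps
}

#' Simulate right-censored survival times under an exponential PH model
#'
#' Event times follow `h(t) = baseline_hazard * exp(lp)`. Censoring is an
#' independent exponential whose rate is tuned (numerically, given the
#' realised linear predictors) so the expected censored fraction --
#' including administrative censoring at `follow_up_months` -- matches
#' `censoring_rate`.
#'
#' @param lp finite numeric vector of linear predictors.
#' @param cfg a [simulation_config()].
#' @return A list with `time` (months) and `event` (1 = death observed).
#' @export
simulate_survival <- function(lp, cfg) {
  stopifnot(all(is.finite(lp)))
  if (cfg$baseline_hazard <= 0) stop("baseline_hazard must be positive")
  n <- length(lp)
  rates <- cfg$baseline_hazard * exp(lp)
  t_event <- rexp(n, rates)
  tau <- cfg$follow_up_months
  if (tau == 0) return(list(time = rep(0, n), event = rep(0L, n)))
  lc <- .censoring_rate_solve(rates, cfg$censoring_rate, tau)
  t_cens <- if (lc > 0) pmin(rexp(n, lc), tau) else rep(tau, n)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  list(time = time, event = event)
}

# expected censored fraction with event rates `rates`, censoring rate lc and
# administrative horizon tau: 1 - mean( r/(r+lc) * (1 - exp(-(r+lc) tau)) )
.censoring_expected <- function(lc, rates, tau) {
  tot <- rates + lc
  1 - mean(rates / tot * (1 - exp(-tot * tau)))
}

.censoring_rate_solve <- function(rates, target, tau) {
  if (target <= 0) return(0)
  base <- .censoring_expected(0, rates, tau)
  if (base >= target) return(0) # administrative censoring alone suffices
  f <- function(lc) .censoring_expected(lc, rates, tau) - target
  upper <- mean(rates)
  while (f(upper) < 0) upper <- upper * 2
  stats::uniroot(f, c(0, upper), tol = 1e-8)$root
}

#' Generate a full synthetic cohort: spot table, clinical table, truth
#'
#' Produces (i) a replicate-level spot intensity table with scan-date and
#' slide batch structure, (ii) a clinical table with OS/PFS, MIPI
#' components, Ki-67 and TP53 status, and (iii) the ground truth (planted
#' signature proteins, their log hazard ratios, batch parameters and the
#' per-patient linear predictor) that downstream recovery tests check
#' against. Deterministic given `cfg$rng_seed`.
#'
#' @param cfg a [simulation_config()].
#' @return A list of class `mcl_cohort` with elements `spots`
#'   (data.table), `clinical` (data.frame), `annotation` (data.frame:
#'   analyte_id, protein_id, protein_name, uniprot_id, clone_number) and
#'   `truth` (list).
#' @examples
#' coh <- generate_cohort(simulation_config(n_patients = 8, n_proteins = 20,
#'                                          n_clones = 40, rng_seed = 7))
#' nrow(coh$clinical)
#' length(unique(coh$spots$analyte_id))
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$rng_seed, .generate_cohort_impl(cfg))
}

.generate_cohort_impl <- function(cfg) {
  np <- cfg$n_patients
  npr <- cfg$n_proteins

  ## --- annotation -------------------------------------------------------
  clone_counts <- allocate_clones(npr, cfg$n_clones, cfg$rng_seed)
  protein_id <- sprintf("P%03d", seq_len(npr))
  annotation <- data.frame(
    analyte_id = sprintf("scFv%03d", seq_len(cfg$n_clones)),
    protein_id = rep(protein_id, clone_counts),
    protein_name = rep(sprintf("protein_%03d", seq_len(npr)), clone_counts),
    uniprot_id = rep(sprintf("SYNP%05d", seq_len(npr)), clone_counts),
    clone_number = unlist(lapply(clone_counts, seq_len)),
    stringsAsFactors = FALSE)

  ## --- latent protein levels -------------------------------------------
  Z <- matrix(rnorm(np * npr), np, npr, dimnames = list(NULL, protein_id))
  if (cfg$block_correlation > 0) {
    rho <- cfg$block_correlation
    blocks <- split(seq_len(npr), ceiling(seq_len(npr) / 10))
    for (b in blocks) {
      f <- rnorm(np)
      Z[, b] <- sqrt(rho) * f + sqrt(1 - rho) * Z[, b]
    }
  }
  sig_idx <- sort(sample.int(npr, cfg$n_signature_proteins))
  sig_ids <- protein_id[sig_idx]
  beta <- setNames(cfg$signature_log_hr_per_sd, sig_ids)
  if (cfg$signature_correlation > 0 && length(sig_idx) > 1L) {
    # shared immune-program factor: marginally standard normal per protein
    rho <- cfg$signature_correlation
    f <- rnorm(np)
    Z[, sig_idx] <- sqrt(rho) * f + sqrt(1 - rho) * Z[, sig_idx]
  }

  ## --- clinical covariates ---------------------------------------------
  age <- round(runif(np, 45, 85))
  ecog <- sample(0:3, np, replace = TRUE, prob = c(0.35, 0.35, 0.2, 0.1))
  ldh_ratio <- exp(runif(np, log(0.5), log(4)))
  wbc <- exp(runif(np, log(2), log(40)))
  mipi <- compute_mipi(age = age, ecog = ecog, ldh_ratio = ldh_ratio,
                       wbc = wbc)$score
  ki67 <- round(runif(np, 5, 95), 1)
  tp53 <- sample(c("wild-type", "deleted", "mutated", "missing"), np,
                 replace = TRUE, prob = c(0.45, 0.29, 0.24, 0.02))

  ## --- survival ---------------------------------------------------------
  lp <- as.vector(Z[, sig_idx, drop = FALSE] %*% beta) +
    cfg$mipi_effect * (mipi - mean(mipi)) +
    cfg$ki67_effect * (ki67 - mean(ki67))
  os_rates <- cfg$baseline_hazard * exp(lp)
  t_os <- rexp(np, os_rates)
  t_prog <- rexp(np, cfg$progression_hazard * exp(lp))
  t_pfs <- pmin(t_os, t_prog)
  tau <- cfg$follow_up_months
  lc <- .censoring_rate_solve(os_rates, cfg$censoring_rate, tau)
  t_cens <- if (lc > 0) pmin(rexp(np, lc), tau) else rep(tau, np)
  os_months <- pmin(t_os, t_cens)
  os_event <- as.integer(t_os <= t_cens)
  pfs_months <- pmin(t_pfs, t_cens)
  pfs_event <- as.integer(t_pfs <= t_cens)

  patient_id <- sprintf("PT%03d", seq_len(np))
  clinical <- data.frame(
    patient_id = patient_id,
    os_months = round(os_months, 3), os_event = os_event,
    pfs_months = round(pfs_months, 3), pfs_event = pfs_event,
    age = age, ecog = ecog, ldh_ratio = round(ldh_ratio, 3),
    wbc = round(wbc, 2),
    mipi_score = round(mipi, 4),
    ki67_pct = ki67, tp53_status = tp53, stringsAsFactors = FALSE)
  # published-cohort-style missingness: a few patients lack MIPI components / Ki-67
  miss_mipi <- runif(np) < cfg$mipi_missing_rate
  clinical$mipi_score[miss_mipi] <- NA_real_
  clinical$ki67_pct[runif(np) < cfg$ki67_missing_rate] <- NA_real_

  ## --- slide / batch layout (7 patients per slide) ----------------------
  slide_of <- ceiling(seq_len(np) / 7L)
  n_slides <- max(slide_of)
  scan_batch_of_slide <- as.integer(cut(seq_len(n_slides),
                                        breaks = cfg$n_scan_batches,
                                        labels = FALSE))
  slide_batch_of_slide <- as.integer(cut(seq_len(n_slides),
                                         breaks = cfg$n_slide_batches,
                                         labels = FALSE))
  scan_b <- scan_batch_of_slide[slide_of]
  slide_b <- slide_batch_of_slide[slide_of]
  subarray <- ((seq_len(np) - 1L) %% 7L) + 1L

  ## --- spot intensities -------------------------------------------------
  prot_mean <- runif(npr, 9, 13)   # baseline log2 abundance per protein
  prot_sd <- runif(npr, 0.4, 0.8)  # biological spread (log2)
  prot_of_clone <- match(annotation$protein_id, protein_id)
  clone_offset <- runif(cfg$n_clones, -0.5, 0.5) # clone affinity offset
  clone_noise_sd <- 0.15                          # clone-level measurement noise

  # latent log2 level per (patient, clone), with scan-batch shift/scale
  bio <- Z[, prot_of_clone, drop = FALSE] * rep(prot_sd[prot_of_clone],
                                                each = np)
  bio <- bio + matrix(rnorm(np * cfg$n_clones, 0, clone_noise_sd),
                      np, cfg$n_clones)
  shift <- cfg$batch_shift[scan_b]
  scale_f <- cfg$batch_scale[scan_b]
  log2lvl <- sweep(bio * scale_f,
                   2L, prot_mean[prot_of_clone] + clone_offset, "+") + shift

  latent <- as.vector(2^log2lvl) # column-major: patients fastest
  reps <- emit_spot_replicates(latent, cfg)
  n_spot <- length(latent)
  bg <- matrix(pmax(rnorm(3L * n_spot, 300, 30), 0), n_spot, 3L)
  flags <- matrix(ifelse(runif(3L * n_spot) < cfg$flagged_spot_rate,
                         "bad", "ok"), n_spot, 3L)

  spots <- data.table::data.table(
    sample_id = rep(patient_id, times = cfg$n_clones * 3L),
    slide_id = rep(sprintf("SL%02d", slide_of), times = cfg$n_clones * 3L),
    scan_batch = rep(sprintf("day%d", scan_b), times = cfg$n_clones * 3L),
    slide_batch = rep(sprintf("batch%d", slide_b), times = cfg$n_clones * 3L),
    subarray = rep(subarray, times = cfg$n_clones * 3L),
    analyte_id = rep(rep(annotation$analyte_id, each = np), times = 3L),
    clone_id = rep(rep(annotation$analyte_id, each = np), times = 3L),
    replicate = rep(1:3, each = n_spot),
    fg = round(as.vector(reps) + as.vector(bg), 2),
    bg = round(as.vector(bg), 2),
    flag = as.vector(flags))
  data.table::setorder(spots, sample_id, analyte_id, replicate)

  truth <- list(
    signature_protein_ids = sig_ids,
    true_log_hr = beta,
    true_batch_params = list(shift = cfg$batch_shift,
                             scale = cfg$batch_scale),
    per_patient_linear_predictor = lp,
    latent_z = Z,
    clone_counts = clone_counts,
    censoring_rate_realized = 1 - mean(os_event))

  out <- list(spots = spots, clinical = clinical, annotation = annotation,
              truth = truth, config = cfg)
  class(out) <- "mcl_cohort"
  out
}

#' @export
print.mcl_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic MCL cohort: %d patients, %d analytes / %d proteins, %d planted\n",
    nrow(x$clinical), x$config$n_clones, x$config$n_proteins,
    x$config$n_signature_proteins))
  cat(sprintf("  events: %d/%d  (censoring %.0f%%)\n",
              sum(x$clinical$os_event), nrow(x$clinical),
              100 * (1 - mean(x$clinical$os_event))))
  invisible(x)
}
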