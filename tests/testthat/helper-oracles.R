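# Independent oracles, deliberately naive: brute-force enumerations and a
# from-scratch Newton partial-likelihood fit. They share no code with the
# implementation paths they check.

# product-limit estimator by explicit risk-set recomputation
km_oracle <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = numeric(), surv = numeric())
  for (t in ut) {
    n_at_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_at_risk)
    out <- rbind(out, data.frame(time = t, surv = s))
  }
  out
}

# Harrell's C by explicit double loop
harrell_oracle <- function(score, time, event) {
  n <- length(score)
  conc <- disc <- tied <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (time[i] == time[j]) next
      a <- if (time[i] < time[j]) i else j # shorter time
      b <- if (time[i] < time[j]) j else i
      if (event[a] != 1) next               # ordering not determinable
      if (score[a] > score[b]) conc <- conc + 1L
      else if (score[a] < score[b]) disc <- disc + 1L
      else tied <- tied + 1L
    }
  }
  list(c = (conc + 0.5 * tied) / (conc + disc + tied),
       n_concordant = conc, n_discordant = disc, n_tied = tied,
       n_usable = conc + disc + tied)
}

# single-covariate Cox partial likelihood (Breslow ties) by Newton iteration
cox_newton_oracle <- function(x, time, event, tol = 1e-10, max_iter = 50) {
  beta <- 0
  for (it in seq_len(max_iter)) {
    eta <- exp(beta * x)
    U <- 0; I <- 0
    for (t in sort(unique(time[event == 1]))) {
      risk <- time >= t
      d <- which(time == t & event == 1)
      s0 <- sum(eta[risk])
      s1 <- sum(x[risk] * eta[risk])
      s2 <- sum(x[risk]^2 * eta[risk])
      U <- U + sum(x[d]) - length(d) * s1 / s0
      I <- I + length(d) * (s2 / s0 - (s1 / s0)^2)
    }
    step <- U / I
    beta <- beta + step
    if (abs(step) < tol) break
  }
  beta
}

# exhaustive two-cutpoint search via survdiff over the full candidate grid
cutpoint_oracle <- function(score, time, event, min_frac = 0.10) {
  n <- length(score)
  min_n <- max(1L, ceiling(min_frac * n))
  u <- sort(unique(score))
  cuts <- (u[-1] + u[-length(u)]) / 2
  best <- NULL
  for (a in seq_along(cuts)) {
    for (b in seq_along(cuts)) {
      if (b <= a) next
      g <- cut(score, c(-Inf, cuts[a], cuts[b], Inf), labels = FALSE)
      if (min(table(factor(g, levels = 1:3))) < min_n) next
      chi <- survival::survdiff(survival::Surv(time, event) ~ g)$chisq
      if (is.null(best) || chi > best$chi2 + 1e-9)
        best <- list(chi2 = chi, c1 = cuts[a], c2 = cuts[b])
    }
  }
  best
}

# mid-rank AUC by explicit pair counting
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
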