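# Independent brute-force oracles used to cross-check the package's
# ANOVA / Tukey implementations, written directly from the defining
# sums-of-squares formulas (no shared code with the implementation).

oracle_oneway <- function(groups) {
  y <- unlist(groups)
  k <- length(groups)
  n <- lengths(groups)
  grand <- mean(y)
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  dfb <- k - 1
  dfw <- length(y) - k
  F <- (ssb / dfb) / (ssw / dfw)
  list(ssb = ssb, ssw = ssw, sst = sum((y - grand)^2),
       dfb = dfb, dfw = dfw, F = F,
       p = stats::pf(F, dfb, dfw, lower.tail = FALSE))
}

# studentized-range (Tukey-Kramer) pairwise comparison from first principles
oracle_tukey <- function(groups, alpha = 0.05) {
  k <- length(groups)
  n <- lengths(groups)
  means <- vapply(groups, mean, numeric(1))
  dfw <- sum(n) - k
  msw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1))) / dfw
  out <- list()
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    se <- sqrt(msw / 2 * (1 / n[i] + 1 / n[j]))
    q <- abs(means[i] - means[j]) / se
    p <- stats::ptukey(q, k, dfw, lower.tail = FALSE)
    out[[length(out) + 1]] <- data.frame(
      i = i, j = j, diff = means[j] - means[i], adj_p = p,
      significant = p < alpha)
  }
  do.call(rbind, out)
}

# brute-force mixed-design SS decomposition: between-subjects factor
# `treatment`, within-subjects factor `time`, subject nested in treatment;
# requires a balanced grid (same number of subjects per treatment here)
oracle_rm_ss <- function(df) {
  a_lev <- unique(df$treatment); t_lev <- unique(df$time)
  n <- length(unique(df$subject[df$treatment == a_lev[1]]))
  a <- length(a_lev); tt <- length(t_lev)
  m <- mean(df$y)
  m_i <- tapply(df$y, df$treatment, mean)
  m_k <- tapply(df$y, df$time, mean)
  m_ij <- tapply(df$y, df$subject, mean)
  subj_trt <- tapply(df$treatment, df$subject, function(x) x[1])
  m_ik <- tapply(df$y, list(df$treatment, df$time), mean)
  ss_treat <- n * tt * sum((m_i - m)^2)
  ss_subj_within <- tt * sum((m_ij - m_i[subj_trt])^2)
  ss_time <- a * n * sum((m_k - m)^2)
  ss_inter <- n * sum((m_ik - outer(m_i, m_k, "+") + m)^2)
  cell <- m_ik[cbind(as.character(df$treatment), as.character(df$time))]
  ss_err <- sum((df$y - cell - m_ij[df$subject] + m_i[as.character(df$treatment)])^2)
  list(ss_treat = ss_treat, ss_subj_within = ss_subj_within,
       ss_time = ss_time, ss_inter = ss_inter, ss_err = ss_err)
}

# build a single-date trial dataset from a list of per-treatment height
# vectors (replicates)
make_onedate_trial <- function(groups, month = 18, accession = "acc") {
  rows <- do.call(rbind, lapply(seq_along(groups), function(i) {
    data.frame(species = "synthetic", accession = accession,
               treatment = sprintf("trt%d", i),
               replicate = seq_along(groups[[i]]),
               months_after_planting = month, height_cm = groups[[i]],
               stringsAsFactors = FALSE)
  }))
  trial_dataset(rows)
}

# reference feasibility vector reproducing the highest-scoring species
rosa_scores <- c(
  existing_cultivations = 6, threat_category = 1, protection_status = 0,
  ex_situ_conservation = 6, distribution = 0, commercial_products = 6,
  known_propagation = 6, vegetative_propagation_success = 6,
  seed_germination_success = 6, cultivation_needs = 6,
  existing_cultivation_protocols = 6, water_demand = 3)
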