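#' Synthetic-cohort configuration
#'
#' Parameters of the seeded generator that emulates the statistical
#' structure of a spinal-decompression MMG cohort: 42 patients with 1--6
#' decompressed nerves each (mean about 2.7), integer stimulation
#' thresholds from a 1 mA-increment protocol with a right-skewed elevated
#' baseline distribution (nerve-level mean about 7.4 mA, SD about 4.9,
#' roughly 90% above the 2.0 mA reference), no threshold worsening, and a
#' recovery process mixing complete normalization with partial
#' Beta-distributed elevation reduction. Pain improvement is linearly
#' coupled to the patient's residual Threshold Excess:
#' `improvement_frac = clip(alpha + beta_te * TE + eps, 0, 1)` with
#' `eps ~ Normal(0, sigma)`.
#'
#' @param n_patients cohort size, default 42.
#' @param nerves_probs probabilities of 1--6 nerves per patient; the default
#'   has mean 2.73.
#' @param region_lumbar probability a patient is lumbar (vs cervical),
#'   default 0.76.
#' @param pre_shape,pre_scale,pre_max pre-decompression thresholds are
#'   `1 + round(Gamma(shape, scale))` truncated to `[1, pre_max]`; defaults
#'   give mean about 7.4 mA, SD about 4.7, with about 90% above 2 mA.
#' @param nerve_rho exchangeable within-patient correlation of the latent
#'   Gaussian driving nerve baselines, default 0.3 (not anchored to reported
#'   data; the within-patient threshold correlation is unreported).
#' @param p_improve probability an elevated nerve improves by at least 1 mA,
#'   default 0.891.
#' @param p_normalize probability an improving nerve normalizes to at or
#'   below the reference, default 0.522.
#' @param partial_shape1,partial_shape2 Beta parameters of the fraction of
#'   elevation removed in partial (non-normalizing) recovery, default
#'   Beta(2, 2).
#' @param nps_zero_prob probability of a zero pain baseline (surgery for
#'   functional impairment), default 0.05.
#' @param nps_mean,nps_sd nonzero baselines are `round(Normal(mean, sd))`
#'   clamped to 1--10; defaults give overall NPS mean about 6.8, SD 2.4.
#' @param alpha,beta_te,sigma outcome-model intercept, TE slope (per mA) and
#'   noise SD on the improvement-fraction scale; defaults 0.92, -0.063,
#'   0.22.
#' @param reference_mA physiologic reference threshold, default 2.0 mA.
#' @param seed default RNG seed carried by the config.
#' @return list of class `mmg_syn_config`.
#' @export
synthetic_config <- function(n_patients = 42,
                             nerves_probs = c(0.20, 0.30, 0.25, 0.12, 0.08, 0.05),
                             region_lumbar = 0.76,
                             pre_shape = 1.757, pre_scale = 3.659,
                             pre_max = 25,
                             nerve_rho = 0.3,
                             p_improve = 0.891,
                             p_normalize = 0.522,
                             partial_shape1 = 2, partial_shape2 = 2,
                             nps_zero_prob = 0.05,
                             nps_mean = 7.16, nps_sd = 1.9,
                             alpha = 0.92, beta_te = -0.063, sigma = 0.22,
                             reference_mA = 2.0,
                             seed = 1L) {
  stopifnot(n_patients >= 1,
            length(nerves_probs) == 6, all(nerves_probs >= 0),
            abs(sum(nerves_probs) - 1) < 1e-8,
            region_lumbar >= 0, region_lumbar <= 1,
            pre_shape > 0, pre_scale > 0, pre_max > reference_mA,
            nerve_rho >= 0, nerve_rho < 1,
            p_improve >= 0, p_improve <= 1,
            p_normalize >= 0, p_normalize <= 1,
            nps_zero_prob >= 0, nps_zero_prob <= 1,
            sigma >= 0, reference_mA > 0)
  if (p_normalize > 0 && floor(reference_mA) < 1) {
    stop("infeasible config: normalization requires an integer threshold ",
         "at or below the reference", call. = FALSE)
  }
  structure(as.list(environment()), class = "mmg_syn_config")
}

#' Generate a synthetic cohort
#'
#' Deterministic given the seed. Thresholds are integers, no nerve worsens
#' (`post <= pre` always), and the six-week NPS is
#' `round(nps_pre * (1 - improvement_frac))` clipped to 0--10, so
#' improvement fractions take the rational values an integer pain
#' instrument produces.
#'
#' @param config a [synthetic_config()].
#' @param seed RNG seed; defaults to the seed carried in the config.
#' @return an `mmg_cohort` (see [as_cohort()]); the config and seed are
#'   recorded in its provenance.
#' @export
generate_cohort <- function(config = synthetic_config(), seed = config$seed) {
  stopifnot(inherits(config, "mmg_syn_config"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  R <- config$reference_mA
  floorR <- floor(R)

  pat_rows <- vector("list", config$n_patients)
  nerve_rows <- vector("list", config$n_patients)
  for (i in seq_len(config$n_patients)) {
    id <- sprintf("S%03d", i)
    k <- sample.int(6, 1, prob = config$nerves_probs)

    # correlated latent Gaussian -> gamma quantile -> integer baseline
    z_pat <- stats::rnorm(1)
    z <- sqrt(config$nerve_rho) * z_pat +
      sqrt(1 - config$nerve_rho) * stats::rnorm(k)
    pre <- 1 + round(stats::qgamma(stats::pnorm(z),
                                   shape = config$pre_shape,
                                   scale = config$pre_scale))
    pre <- pmin(pmax(pre, 1), config$pre_max)

    post <- pre
    for (j in seq_len(k)) {
      if (pre[j] > R && stats::runif(1) < config$p_improve) {
        # improvement >= 1 mA from pre <= R + 1 forces normalization
        must_normalize <- pre[j] - 1 <= R
        if (must_normalize || stats::runif(1) < config$p_normalize) {
          post[j] <- sample.int(floorR, 1)
        } else {
          frac_removed <- stats::rbeta(1, config$partial_shape1,
                                       config$partial_shape2)
          resid <- round(R + (pre[j] - R) * (1 - frac_removed))
          post[j] <- min(max(resid, floorR + 1), pre[j] - 1)
        }
      }
    }

    nps_pre <- if (stats::runif(1) < config$nps_zero_prob) {
      0L
    } else {
      as.integer(pmin(pmax(round(stats::rnorm(1, config$nps_mean,
                                              config$nps_sd)), 1), 10))
    }
    te <- max(mean(post) - R, 0)
    frac <- config$alpha + config$beta_te * te +
      stats::rnorm(1, 0, config$sigma)
    frac <- min(max(frac, 0), 1)
    nps_6wk <- as.integer(pmin(pmax(round(nps_pre * (1 - frac)), 0), 10))

    pat_rows[[i]] <- data.frame(
      patient_id = id,
      region = if (stats::runif(1) < config$region_lumbar) "lumbar" else "cervical",
      nps_pre = nps_pre, nps_6wk = nps_6wk,
      stringsAsFactors = FALSE)
    nerve_rows[[i]] <- data.frame(
      patient_id = id,
      nerve_label = sprintf("N%d", seq_len(k)),
      pre_mA = as.numeric(pre), post_mA = as.numeric(post),
      stringsAsFactors = FALSE)
  }

  as_cohort(do.call(rbind, pat_rows), do.call(rbind, nerve_rows),
            provenance = list(generator = "synthetic", seed = seed,
                              config = unclass(config)))
}

#' Inject validator-visible anomalies into a cohort
#'
#' Returns a perturbed copy with the requested numbers of anomalies, for
#' exercising [validate_cohort()]: `worsening` raises a nerve's post
#' threshold above its pre, `non_integer` shifts a post threshold by 0.5 mA
#' (downwards, so no worsening is created), `zero_baseline` zeroes the
#' baseline NPS of patients that had pain.
#'
#' @param cohort an `mmg_cohort`.
#' @param worsening,non_integer,zero_baseline counts to inject.
#' @param seed RNG seed selecting which rows are perturbed.
#' @return a perturbed `mmg_cohort`.
#' @export
inject_anomalies <- function(cohort, worsening = 0, non_integer = 0,
                             zero_baseline = 0, seed = 1L) {
  stopifnot(inherits(cohort, "mmg_cohort"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  nv <- cohort$nerves
  pt <- cohort$patients

  if (worsening > 0) {
    idx <- sample.int(nrow(nv), worsening)
    nv$post_mA[idx] <- nv$pre_mA[idx] + 1
  }
  if (non_integer > 0) {
    pool <- setdiff(which(nv$post_mA > 1), if (worsening > 0) idx else integer())
    jdx <- sample(pool, non_integer)
    nv$post_mA[jdx] <- nv$post_mA[jdx] - 0.5
  }
  if (zero_baseline > 0) {
    pool <- which(pt$nps_pre > 0)
    kdx <- sample(pool, zero_baseline)
    pt$nps_pre[kdx] <- 0L
    pt$nps_6wk[kdx] <- 0L
  }
  as_cohort(pt, nv, provenance = c(cohort$provenance,
                                   list(injected = c(worsening = worsening,
                                                     non_integer = non_integer,
                                                     zero_baseline = zero_baseline))))
}

#' Parameter-recovery experiment
#'
#' Repeatedly generates cohorts, runs the metric and dose-response stages,
#' and compares the estimated TE slope with the generator's `beta_te`:
#' per-replicate estimates, empirical bias, 95% CI coverage, and the
#' rejection rate of the slope's t-test (the empirical size when
#' `beta_te = 0`). Also records whether TRR correlates positively and TE
#' negatively with improvement in each replicate.
#'
#' @param config a [synthetic_config()].
#' @param n_replicates number of simulated cohorts.
#' @param seed base seed; replicate `r` uses `seed + r`.
#' @return list of class `mmg_recovery`: `replicates` (data.frame) and
#'   summary fields `mean_slope`, `bias`, `coverage`, `rejection_rate`,
#'   `true_beta`.
#' @export
recovery_experiment <- function(config = synthetic_config(),
                                n_replicates = 200, seed = 1000L) {
  rows <- lapply(seq_len(n_replicates), function(r) {
    coh <- generate_cohort(config, seed = seed + r)
    m <- compute_metrics(coh, metric_config(reference_mA = config$reference_mA))
    keep <- !is.na(m$pain_improvement_frac)
    fit <- ols_fit(m$pain_improvement_frac[keep],
                   data.frame(te = m$te[keep]))
    sl <- fit$coefficients[fit$coefficients$term == "te", ]
    keep_trr <- keep & !is.na(m$trr)
    data.frame(replicate = r,
               slope = sl$estimate, se = sl$se,
               ci_lo = sl$ci_lo, ci_hi = sl$ci_hi, p = sl$p,
               covered = sl$ci_lo <= config$beta_te &
                 config$beta_te <= sl$ci_hi,
               trr_cor_positive = stats::cor(m$trr[keep_trr],
                                             m$pain_improvement_frac[keep_trr]) > 0,
               te_cor = stats::cor(m$te[keep], m$pain_improvement_frac[keep]))
  })
  reps <- do.call(rbind, rows)
  structure(list(replicates = reps,
                 true_beta = config$beta_te,
                 mean_slope = mean(reps$slope),
                 bias = mean(reps$slope) - config$beta_te,
                 coverage = mean(reps$covered),
                 rejection_rate = mean(reps$p < 0.05)),
            class = "mmg_recovery")
}

#' @export
print.mmg_recovery <- function(x, ...) {
  cat(sprintf("Parameter recovery over %d replicates (true TE slope %.3f)\n",
              nrow(x$replicates), x$true_beta))
  cat(sprintf("  mean slope %.4f (bias %+.4f), CI coverage %.3f, rejection rate %.3f\n",
              x$mean_slope, x$bias, x$coverage, x$rejection_rate))
  invisible(x)
}
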