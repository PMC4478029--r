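# base parameters of a left-truncated normal whose truncated moments match
# a target mean/sd; solved deterministically at generation time
.truncnorm_base <- function(target_mean, target_sd, lower) {
  obj <- function(par) {
    mu <- par[1]
    sig <- exp(par[2])
    alpha <- (lower - mu) / sig
    lam <- stats::dnorm(alpha) / (1 - stats::pnorm(alpha))
    m <- mu + sig * lam
    v <- sig^2 * (1 + alpha * lam - lam^2)
    (m - target_mean)^2 + (sqrt(v) - target_sd)^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 500))
  list(mu = fit$par[1], sigma = exp(fit$par[2]))
}

.rtruncnorm_q <- function(u, mu, sigma, lower) {
  p0 <- stats::pnorm(lower, mu, sigma)
  stats::qnorm(p0 + u * (1 - p0), mu, sigma)
}

# latent correlation matrix for (age, bmi, fs, copd, dd, htn, smoking,
# diabetes); only the configured pairs are non-zero
.copula_sigma <- function(cop) {
  vars <- c("age", "bmi", "fs", "copd", "dd", "htn", "smoking", "diabetes")
  S <- diag(length(vars))
  dimnames(S) <- list(vars, vars)
  set <- function(a, b, r) {
    S[a, b] <<- r
    S[b, a] <<- r
  }
  set("age", "copd", cop$age_copd)
  set("age", "dd", cop$age_dd)
  set("bmi", "htn", cop$bmi_htn)
  set("age", "fs", cop$age_fs)
  S
}

# mitral inflow / tissue-Doppler values consistent with an assigned
# diastolic stage under the default threshold table (inverse of
# stage_diastolic); AF rows carry no A wave
.emit_mitral <- function(stage, af, th = diastolic_thresholds()) {
  n <- length(stage)
  e_prime <- numeric(n)
  ratio <- numeric(n)  # E/E'
  ea <- numeric(n)
  dt <- numeric(n)
  ru <- function(k, a, b) stats::runif(k, a, b)
  for (s in levels(stage)) {
    i <- which(stage == s & !af)
    k <- length(i)
    if (k) {
      if (s == "normal_or_stage1") {
        relax <- stats::runif(k) < 0.5
        ea[i] <- ifelse(relax, ru(k, 0.45, th$ea_low - 0.01),
                        ru(k, th$ea_low + 0.05, 1.5))
        e_prime[i] <- ifelse(relax, ru(k, 5, 10), ru(k, th$eprime_low + 0.5, 14))
        ratio[i] <- ifelse(relax, ru(k, 5, 14), ru(k, 4, th$e_over_eprime - 0.5))
        dt[i] <- ru(k, 160, 260)
      } else if (s == "stage2") {
        ea[i] <- ru(k, th$ea_low + 0.05, th$ea_high - 0.2)
        hi_ratio <- stats::runif(k) < 0.5
        ratio[i] <- ifelse(hi_ratio, ru(k, th$e_over_eprime + 0.5, 16),
                           ru(k, 5, th$e_over_eprime - 0.5))
        e_prime[i] <- ifelse(hi_ratio, ru(k, 5, 12),
                             ru(k, 4, th$eprime_low - 0.1))
        dt[i] <- ru(k, 150, 220)
      } else {
        ea[i] <- ru(k, th$ea_high + 0.05, 3.5)
        e_prime[i] <- ru(k, 3, 7)
        ratio[i] <- ru(k, 10, 20)
        dt[i] <- ru(k, 90, th$dt_low - 1)
      }
    }
    j <- which(stage == s & af)
    k <- length(j)
    if (k) {
      if (s == "normal_or_stage1") {
        dt[j] <- ru(k, th$dt_high + 1, 280)
        e_prime[j] <- ru(k, th$eprime_low + 0.5, 14)
        ratio[j] <- ru(k, 4, th$e_over_eprime - 0.5)
      } else if (s == "stage2") {
        dt[j] <- ru(k, th$dt_low + 1, th$dt_high - 1)
        hi_ratio <- stats::runif(k) < 0.5
        ratio[j] <- ifelse(hi_ratio, ru(k, th$e_over_eprime + 0.5, 16),
                           ru(k, 5, th$e_over_eprime - 0.5))
        e_prime[j] <- ifelse(hi_ratio, ru(k, 5, 12),
                             ru(k, 4, th$eprime_low - 0.1))
      } else {
        dt[j] <- ru(k, 90, th$dt_low - 1)
        e_prime[j] <- ru(k, 3, 7)
        ratio[j] <- ru(k, 10, 20)
      }
      ea[j] <- NA_real_
    }
  }
  e_peak <- ratio * e_prime / 100  # E/E' = 100 * e_peak(m/s) / e_prime(cm/s)
  a_peak <- ifelse(af, NA_real_, e_peak / ea)
  list(e_peak = e_peak, a_peak = a_peak, e_prime = e_prime, dec_time = dt)
}

#' Generate a synthetic echocardiography cohort
#'
#' Draws covariates from the configured marginals (age from a left-truncated
#' normal, weak latent-normal correlations between age and COPD, diastolic
#' stage and fractional shortening, and between BMI and hypertension), builds
#' the true ePASP from the configured linear effect vector plus a
#' (optionally right-skewed) residual, then decomposes it exactly into the
#' echo measurements: RAP is drawn from its three-point guideline
#' distribution, TRV is back-derived as `sqrt((ePASP - RAP) / 4)`, IVC
#' diameter/collapse are emitted consistently with the drawn RAP category,
#' and LV diameters and mitral indices consistently with the assigned
#' fractional shortening and diastolic stage, so the derivation stage
#' recovers the truth to machine precision on unmasked data. Rows whose
#' drawn ePASP would fall below the drawn RAP are floored at RAP (zero
#' gradient); their count is recorded in the `floored` attribute.
#'
#' @param n Cohort size.
#' @param seed Integer seed (optional but recommended).
#' @param config An [eph_config()].
#' @return Object of class `eph_cohort`: list with `data` (visible
#'   participant table, no ground-truth columns), `truth` (id-keyed table
#'   with `epasp_true`, `lp_true`, `rap_true`, `case_true`), `config`,
#'   `seed`, `floored`.
#' @examples
#' ch <- simulate_cohort(1000, seed = 42)
#' mean(ch$truth$epasp_true)
#' @export
simulate_cohort <- function(n, seed = NULL, config = eph_config()) {
  stopifnot(n >= 1)
  validate_config(config)
  if (!is.null(seed)) set.seed(seed)
  mg <- config$marginals

  S <- .copula_sigma(config$copula)
  Z <- matrix(stats::rnorm(n * ncol(S)), n) %*% chol(S)
  colnames(Z) <- colnames(S)
  U <- stats::pnorm(Z)

  base <- .truncnorm_base(mg$age_mean, mg$age_sd, mg$age_min)
  age <- .rtruncnorm_q(U[, "age"], base$mu, base$sigma, mg$age_min)
  sex <- factor(ifelse(stats::runif(n) < mg$p_women, "female", "male"),
                levels = c("male", "female"))
  bmi <- mg$bmi_mean + mg$bmi_sd * Z[, "bmi"]
  fs <- mg$fs_mean + mg$fs_sd * Z[, "fs"]
  fs <- pmin(fs, 65)  # keep LVESD comfortably positive
  smk_br <- cumsum(mg$smoking_p)
  smoking <- factor(names(mg$smoking_p)[1 + findInterval(U[, "smoking"],
                                                         smk_br[-3])],
                    levels = names(mg$smoking_p))
  dd_br <- cumsum(mg$dd_stage_p)
  dd <- factor(names(mg$dd_stage_p)[1 + findInterval(U[, "dd"], dd_br[-3])],
               levels = names(mg$dd_stage_p))
  copd <- U[, "copd"] < mg$copd_p
  diabetes <- U[, "diabetes"] < mg$diabetes_p
  hypertension <- U[, "htn"] < mg$hypertension_p
  af <- stats::runif(n) < mg$af_p

  ef <- config$effects
  lp <- ef$intercept +
    ef$age / 10 * age +
    ef$women * (sex == "female") +
    ef$bmi / 5 * bmi +
    ef$fs / 10 * fs +
    ef$dd_stage2 * (dd == "stage2") +
    ef$dd_stage34 * (dd == "stage3_4") +
    ef$copd * copd +
    ef$diabetes * diabetes +
    ef$hypertension * hypertension +
    ef$smoking_former * (smoking == "former") +
    ef$smoking_current * (smoking == "current")

  zr <- stats::rnorm(n)
  eps <- if (isTRUE(config$residual$skew)) {
    tau <- config$residual$tau
    mlog <- exp(tau^2 / 2)
    slog <- sqrt((exp(tau^2) - 1) * exp(tau^2))
    config$residual$sd * (exp(tau * zr) - mlog) / slog
  } else {
    config$residual$sd * zr
  }
  epasp_true <- lp + eps

  rap_vals <- as.numeric(names(config$rap_p))
  rap <- rap_vals[sample.int(length(rap_vals), n, replace = TRUE,
                             prob = config$rap_p)]
  floored <- sum(epasp_true < rap)
  epasp_true <- pmax(epasp_true, rap)
  trv <- sqrt((epasp_true - rap) / 4)

  ivc_diameter <- numeric(n)
  ivc_collapse <- numeric(n)
  i3 <- rap == 3
  ivc_diameter[i3] <- stats::runif(sum(i3), 12, 21)
  ivc_collapse[i3] <- stats::runif(sum(i3), 0.55, 0.90)
  i8 <- rap == 8
  lowside <- stats::runif(sum(i8)) < 0.5
  ivc_diameter[i8] <- ifelse(lowside, stats::runif(sum(i8), 12, 21),
                             stats::runif(sum(i8), 21.5, 28))
  ivc_collapse[i8] <- ifelse(lowside, stats::runif(sum(i8), 0.10, 0.50),
                             stats::runif(sum(i8), 0.50, 0.85))
  i15 <- rap == 15
  ivc_diameter[i15] <- stats::runif(sum(i15), 21.5, 30)
  ivc_collapse[i15] <- stats::runif(sum(i15), 0.05, 0.45)

  lvedd <- pmax(stats::rnorm(n, mg$lvedd_mean, mg$lvedd_sd), 30)
  lvesd <- lvedd * (1 - fs / 100)
  rvedd <- stats::rnorm(n, ifelse(sex == "female", mg$rvedd_mean_women,
                                  mg$rvedd_mean_men), mg$rvedd_sd)
  mitral <- .emit_mitral(dd, af)

  conc <- function(x, levels_pool) {
    keep <- stats::runif(n) < config$missingness$prior_concordance
    out <- as.character(x)
    alt <- vapply(out, function(v) sample(setdiff(levels_pool, v), 1L), "")
    out[!keep] <- alt[!keep]
    out
  }
  prior_smoking <- factor(conc(smoking, levels(smoking)),
                          levels = levels(smoking))
  prior_copd <- xor(copd, stats::runif(n) >= config$missingness$prior_concordance)

  data <- data.frame(
    id = seq_len(n),
    age = age, sex = sex, bmi = bmi, smoking = smoking,
    copd = copd, diabetes = diabetes, hypertension = hypertension,
    af = af,
    prior_smoking = prior_smoking, prior_copd = prior_copd,
    trv = trv, trv_reason = "",
    ivc_diameter = ivc_diameter, ivc_collapse = ivc_collapse,
    lvedd = lvedd, lvesd = lvesd, rvedd = rvedd,
    e_peak = mitral$e_peak, a_peak = mitral$a_peak,
    e_prime = mitral$e_prime, dec_time = mitral$dec_time,
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    id = data$id,
    epasp_true = epasp_true,
    lp_true = lp,
    rap_true = rap,
    dd_true = dd,
    case_true = epasp_true > 40
  )
  structure(list(data = data, truth = truth, config = config, seed = seed,
                 floored = floored),
            class = "eph_cohort")
}

#' Apply the observed-data missingness pattern to a synthetic cohort
#'
#' Masks the complete cohort into the pattern the analysis has to cope
#' with: (1) a no-TR-data stratum (`trv_reason = "not_recorded"`) drawn
#' completely at random at the configured rate; (2) among the remainder, an
#' unmeasurable regurgitation jet (reason `jet_absent` or `jet_too_small`)
#' with probability decreasing in true ePASP through a logistic link whose
#' intercept is solved at run time so the marginal rate matches the
#' configured one exactly in expectation — encoding the assumption that
#' unmeasurable jets indicate normal pulmonary pressures; (3) missing RAP
#' (IVC measurements removed) completely at random; (4) small
#' completely-at-random covariate missingness, with prior-visit smoking and
#' COPD values available for carry-forward.
#'
#' @param cohort An `eph_cohort` (needs its truth columns).
#' @param config Missingness configuration; defaults to the cohort's own.
#' @param seed Optional seed for the masking draws.
#' @return A new `eph_cohort` with the masked `data` and untouched `truth`.
#' @export
apply_missingness <- function(cohort, config = cohort$config, seed = NULL) {
  stopifnot(inherits(cohort, "eph_cohort"))
  if (!is.null(seed)) set.seed(seed)
  ms <- config$missingness
  d <- cohort$data
  ep <- cohort$truth$epasp_true
  n <- nrow(d)

  no_tr <- stats::runif(n) < ms$no_tr_rate
  d$trv[no_tr] <- NA_real_
  d$trv_reason[no_tr] <- "not_recorded"

  rest <- which(!no_tr)
  s <- ms$trv_mask_steepness
  target <- ms$trv_mask_rate
  a <- stats::uniroot(
    function(a) mean(stats::plogis(a - s * (ep[rest] - 26))) - target,
    interval = c(-20, 20), tol = 1e-10
  )$root
  pmask <- stats::plogis(a - s * (ep[rest] - 26))
  masked <- rest[stats::runif(length(rest)) < pmask]
  d$trv[masked] <- NA_real_
  d$trv_reason[masked] <- sample(c("jet_absent", "jet_too_small"),
                                 length(masked), replace = TRUE)

  rap_gone <- stats::runif(n) < ms$rap_missing_rate
  d$ivc_diameter[rap_gone] <- NA_real_
  d$ivc_collapse[rap_gone] <- NA_real_

  mask_mcar <- function(x, rate) {
    x[stats::runif(n) < rate] <- NA
    x
  }
  cm <- ms$cov_missing
  d$bmi <- mask_mcar(d$bmi, cm[["bmi"]])
  d$diabetes <- mask_mcar(d$diabetes, cm[["diabetes"]])
  d$hypertension <- mask_mcar(d$hypertension, cm[["hypertension"]])
  # FS / diastolic-stage missingness removes the underlying measurements
  fs_gone <- stats::runif(n) < cm[["fs"]]
  d$lvedd[fs_gone] <- NA_real_
  d$lvesd[fs_gone] <- NA_real_
  dd_gone <- stats::runif(n) < cm[["diastolic_stage"]]
  d$e_peak[dd_gone] <- NA_real_
  d$a_peak[dd_gone] <- NA_real_
  d$e_prime[dd_gone] <- NA_real_
  d$dec_time[dd_gone] <- NA_real_
  smk_gone <- stats::runif(n) < cm[["smoking"]]
  d$smoking[smk_gone] <- NA
  copd_gone <- stats::runif(n) < cm[["copd"]]
  d$copd[copd_gone] <- NA
  prior_gone <- stats::runif(n) >= ms$prior_available
  d$prior_smoking[prior_gone] <- NA
  d$prior_copd[prior_gone] <- NA

  out <- cohort
  out$data <- d
  out
}

#' @export
print.eph_cohort <- function(x, ...) {
  cat(sprintf("Synthetic echo cohort: n = %d (seed %s)\n", nrow(x$data),
              x$seed %||% "unset"))
  cat(sprintf("  true ePASP mean %.1f mmHg; %d row(s) floored at RAP\n",
              mean(x$truth$epasp_true), x$floored))
  cat(sprintf("  TRV missing: %.1f%%\n", 100 * mean(is.na(x$data$trv))))
  invisible(x)
}
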