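#' Configure a synthetic cord-blood methylation cohort
#'
#' The generator emulates the statistical structure a gestational age clock
#' assumes: gestational age (GA) drawn from a truncated normal; a sparse set
#' of `n_active` GA-predictive CpGs whose logit-scale methylation moves
#' linearly with GA; the remaining probes pure noise around a probe-specific
#' baseline. Betas come out of an inverse logit, so they are strictly inside
#' (0, 1). ART (assisted reproduction) metadata with internally consistent
#' embryo-transfer dates is generated alongside, and an optional GA
#' acceleration `gaa_shift_days` moves the *methylation-implied* GA of ART
#' samples without touching their clinical GA.
#'
#' GA defaults (mean 281, range 216-301 days) follow the cord-blood cohorts
#' such clocks are trained on. Effect sizes can be given directly
#' (`effect_sd`, logit units per day; active slopes are `+/- effect_sd` with
#' random sign, or `rnorm(0, effect_sd)` when `slope_dist = "normal"`) or
#' derived from a target `signal_fraction`: the squared correlation between
#' GA and the best linear combination of the active-probe logits,
#' `f = 1 / (1 + noise_sd^2 / (var(GA) * n_active * effect_sd^2))`,
#' solved for `effect_sd` using the truncated-normal GA variance.
#'
#' @param n_samples,n_probes cohort dimensions.
#' @param n_active number of GA-predictive CpGs (`<= n_probes`).
#' @param effect_sd magnitude of active-probe slopes, logit-beta units per
#'   day. Ignored when `signal_fraction` is given.
#' @param signal_fraction optional target squared correlation in (0, 1)
#'   between GA and the combined active-probe signal.
#' @param noise_sd per-probe logit-scale noise standard deviation.
#' @param slope_dist `"fixed"` (equal-magnitude slopes, random sign) or
#'   `"normal"`.
#' @param ga_mean_days,ga_sd_days,ga_min,ga_max truncated-normal GA
#'   distribution, days.
#' @param art_fraction,icsi_fraction,frozen_fraction fraction of samples
#'   conceived by ART; among those, fraction ICSI (vs IVF) and fraction
#'   frozen embryo transfer (vs fresh).
#' @param gaa_shift_days GA-acceleration offset (days) added to the
#'   methylation-implied GA of ART samples; 0 simulates the null.
#' @param missing_rate fraction of beta cells set missing at random.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_samples = 400, n_probes = 2000, n_active = 30,
                       effect_sd = 0.01, signal_fraction = NULL,
                       noise_sd = 0.3, slope_dist = c("fixed", "normal"),
                       ga_mean_days = 281, ga_sd_days = 11,
                       ga_min = 216, ga_max = 301,
                       art_fraction = 0.45, icsi_fraction = 0.5,
                       frozen_fraction = 0.25, gaa_shift_days = 0,
                       missing_rate = 0, seed = 1L) {
  slope_dist <- match.arg(slope_dist)
  fracs <- c(art_fraction = art_fraction, icsi_fraction = icsi_fraction,
             frozen_fraction = frozen_fraction, missing_rate = missing_rate)
  if (any(fracs < 0 | fracs > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (n_active > n_probes) stop("n_active exceeds n_probes", call. = FALSE)
  if (ga_min >= ga_max) stop("ga_min must be below ga_max", call. = FALSE)
  if (!is.null(signal_fraction)) {
    if (signal_fraction <= 0 || signal_fraction >= 1) {
      stop("signal_fraction must lie in (0, 1)", call. = FALSE)
    }
    v <- truncnorm_var(ga_mean_days, ga_sd_days, ga_min, ga_max)
    effect_sd <- noise_sd * sqrt(signal_fraction /
                                   ((1 - signal_fraction) * v * n_active))
  }
  structure(list(
    n_samples = as.integer(n_samples), n_probes = as.integer(n_probes),
    n_active = as.integer(n_active), effect_sd = effect_sd,
    signal_fraction = signal_fraction, noise_sd = noise_sd,
    slope_dist = slope_dist, ga_mean_days = ga_mean_days,
    ga_sd_days = ga_sd_days, ga_min = ga_min, ga_max = ga_max,
    art_fraction = art_fraction, icsi_fraction = icsi_fraction,
    frozen_fraction = frozen_fraction, gaa_shift_days = gaa_shift_days,
    missing_rate = missing_rate, seed = as.integer(seed)
  ), class = "sim_config")
}

# Variance of N(mean, sd^2) truncated to [a, b].
truncnorm_var <- function(mean, sd, a, b) {
  al <- (a - mean) / sd
  be <- (b - mean) / sd
  z <- stats::pnorm(be) - stats::pnorm(al)
  da <- stats::dnorm(al)
  db <- stats::dnorm(be)
  sd^2 * (1 + (al * da - be * db) / z - ((da - db) / z)^2)
}

rtruncnorm <- function(n, mean, sd, a, b) {
  lo <- stats::pnorm(a, mean, sd)
  hi <- stats::pnorm(b, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

sim_probe_ids <- function(n) sprintf("cg%08d", seq_len(n))
sim_sample_ids <- function(n) sprintf("s%05d", seq_len(n))

#' Simulate a cord-blood cohort
#'
#' Draws a full cohort under a [sim_config()]: a beta matrix (probes x
#' samples), a sample sheet with ART metadata and consistent embryo-transfer
#' dates (so that the ETD date rules recover the true GA exactly), and the
#' simulation truth used by parameter-recovery tests.
#'
#' @param cfg a [sim_config()].
#' @param sample_seed seed for the sample-level draws (who is sampled: GA,
#'   ART status, noise, missingness, dates). Defaults to `cfg$seed`. The
#'   population probe model — which probes are active, their slopes and
#'   baselines — is keyed to `cfg$seed` alone, so cohorts drawn with
#'   different `sample_seed`s are fresh samples from the *same* population
#'   and a clock trained on one applies to the others.
#' @return A list with elements
#'   * `beta` — a [beta_matrix()];
#'   * `samples` — a sample sheet tibble ([as_sample_sheet()] schema);
#'   * `truth` — list with `active_probe_ids`, `true_effects` (named slope
#'     vector), `true_ga_days` (named by sample), `ga_meth_days` (the
#'     methylation-implied GA, i.e. true GA plus any ART shift) and
#'     `true_gaa_shift`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_samples = 20, n_probes = 50,
#'                                      n_active = 5, seed = 3))
#' dim(cohort$beta)
#' @export
simulate_cohort <- function(cfg, sample_seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$ga_sd_days == 0 && cfg$n_active > 0) {
    warning("ga_sd_days = 0 leaves no GA variation for active probes",
            call. = FALSE)
  }
  n <- cfg$n_samples
  p <- cfg$n_probes
  pid <- sim_probe_ids(p)
  sid <- sim_sample_ids(n)

  # population probe model: fixed by the config seed
  pop <- with_seed(derive_seed(cfg$seed, 21L), {
    active <- sort(sample.int(p, cfg$n_active))
    slopes <- switch(cfg$slope_dist,
      fixed = cfg$effect_sd * sample(c(-1, 1), cfg$n_active, replace = TRUE),
      normal = stats::rnorm(cfg$n_active, 0, cfg$effect_sd))
    baseline <- stats::qlogis(stats::runif(p, 0.05, 0.95))
    list(active = active, slopes = slopes, baseline = baseline)
  })

  with_seed(sample_seed, {
    ga_true <- as.integer(round(rtruncnorm(n, cfg$ga_mean_days, cfg$ga_sd_days,
                                           cfg$ga_min, cfg$ga_max)))
    ga_true <- pmin(pmax(ga_true, as.integer(ceiling(cfg$ga_min))),
                    as.integer(floor(cfg$ga_max)))

    n_art <- round(cfg$art_fraction * n)
    art <- rep(FALSE, n)
    art[sample.int(n, n_art)] <- TRUE
    procedure <- rep("none", n)
    embryo_state <- rep("none", n)
    if (n_art > 0) {
      idx <- which(art)
      n_icsi <- round(cfg$icsi_fraction * n_art)
      icsi <- idx[sample.int(n_art, n_icsi)]
      procedure[idx] <- "IVF"
      procedure[icsi] <- "ICSI"
      n_froz <- round(cfg$frozen_fraction * n_art)
      froz <- idx[sample.int(n_art, n_froz)]
      embryo_state[idx] <- "fresh"
      embryo_state[froz] <- "frozen"
    }

    ga_meth <- ga_true + cfg$gaa_shift_days * art

    logit <- matrix(pop$baseline, nrow = p, ncol = n)
    if (cfg$n_active > 0) {
      logit[pop$active, ] <- logit[pop$active, ] +
        outer(pop$slopes, ga_meth - cfg$ga_mean_days)
    }
    if (cfg$noise_sd > 0) {
      logit <- logit + matrix(stats::rnorm(p * n, 0, cfg$noise_sd), p, n)
    }
    betas <- stats::plogis(logit)
    dimnames(betas) <- list(pid, sid)

    if (cfg$missing_rate > 0) {
      n_miss <- round(cfg$missing_rate * length(betas))
      betas[sample.int(length(betas), n_miss)] <- NA_real_
    }

    sheet <- simulate_dates(sid, ga_true, art, procedure, embryo_state)

    truth <- list(
      active_probe_ids = pid[pop$active],
      true_effects = stats::setNames(pop$slopes, pid[pop$active]),
      true_ga_days = stats::setNames(ga_true, sid),
      ga_meth_days = stats::setNames(ga_meth, sid),
      true_gaa_shift = cfg$gaa_shift_days
    )
    list(beta = beta_matrix(betas), samples = sheet, truth = truth)
  })
}

# Birth and ART procedure dates consistent with the ETD arithmetic:
# fresh transfers happen two days after egg retrieval; frozen embryos are
# frozen a few days after retrieval, stored, then transferred.
simulate_dates <- function(sid, ga_true, art, procedure, embryo_state) {
  n <- length(sid)
  birth <- as.Date("2010-01-01") + sample.int(365, n, replace = TRUE) - 1L
  retrieval <- insertion <- freeze <- as.Date(rep(NA, n))

  fresh <- art & embryo_state == "fresh"
  retrieval[fresh] <- birth[fresh] - (ga_true[fresh] - 14L)
  insertion[fresh] <- retrieval[fresh] + 2L

  froz <- art & embryo_state == "frozen"
  if (any(froz)) {
    d_freeze <- sample(2:6, sum(froz), replace = TRUE)
    storage <- sample(30:365, sum(froz), replace = TRUE)
    insertion[froz] <- birth[froz] - (ga_true[froz] - 14L - d_freeze)
    retrieval[froz] <- insertion[froz] - storage - d_freeze
    freeze[froz] <- retrieval[froz] + d_freeze
  }

  as_sample_sheet(tibble::tibble(
    sample_id = sid,
    ga_ultrasound_days = as.integer(ga_true),
    art = art,
    procedure = procedure,
    embryo_state = embryo_state,
    birth_date = birth,
    egg_retrieval_date = retrieval,
    embryo_insertion_date = insertion,
    freeze_date = freeze,
    ga_etd_days = NA_integer_
  ))
}

#' Simulate a probe annotation table
#'
#' Assigns quality-control flags to the probes of a simulated cohort by
#' seeded sampling; each flag is set on exactly `round(frac * n_probes)`
#' probes.
#'
#' @param cfg a [sim_config()] (only `n_probes` and `seed` are used).
#' @param frac_450k fraction of probes present on the 450K platform.
#' @param frac_cross_reactive fraction flagged cross-reactive.
#' @param frac_snp fraction whose last three bases overlap a SNP.
#' @param frac_non_autosomal fraction on sex chromosomes.
#' @return A probe-annotation tibble ([as_probe_annotation()] schema).
#' @export
make_probe_annotation <- function(cfg, frac_450k = 1, frac_cross_reactive = 0,
                                  frac_snp = 0, frac_non_autosomal = 0) {
  stopifnot(inherits(cfg, "sim_config"))
  fr <- c(frac_450k, frac_cross_reactive, frac_snp, frac_non_autosomal)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]", call. = FALSE)
  p <- cfg$n_probes
  with_seed(derive_seed(cfg$seed, 7L), {
    flag <- function(frac) {
      out <- rep(FALSE, p)
      out[sample.int(p, round(frac * p))] <- TRUE
      out
    }
    tibble::tibble(
      probe_id = sim_probe_ids(p),
      on_450k = flag(frac_450k),
      cross_reactive = flag(frac_cross_reactive),
      snp_overlap = flag(frac_snp),
      autosomal = !flag(frac_non_autosomal)
    )
  })
}
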