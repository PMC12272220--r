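#' Configuration for a synthetic cohort
#'
#' Collects every knob of the generator that plants recoverable ground truth
#' for the downstream measures: per-pair homotopic correlation targets, a
#' baseline same-hemisphere coupling with a left-minus-right asymmetry
#' increment, an optional subject-level coupling between homotopic strength
#' and asymmetry (negative values plant the negative HoFC-LI association the
#' analysis is designed to detect), age drifts, temporal autocorrelation and
#' an additive global confound.
#'
#' @param atlas A `homotopic_atlas`.
#' @param n_subjects Number of subjects.
#' @param n_frames Frames per run; a warning is issued below 2 x regions.
#' @param tr Sampling interval (s).
#' @param rho_homotopic Target homotopic correlation, scalar or per-pair, in
#'   (-1, 1).
#' @param intra_base Baseline same-hemisphere correlation.
#' @param asym Left-minus-right increment to intrahemispheric coupling,
#'   scalar or per-pair; entry (i, j) within the left hemisphere is
#'   `intra_base + (asym_i + asym_j) / 4` and within the right hemisphere the
#'   same with a minus sign, so a common `asym = a` raises left-left
#'   correlations by `a / 2` and lowers right-right ones equally.
#' @param cross_bg Cross-hemisphere non-homotopic correlation level.
#' @param coupling Correlation, in \[-1, 1\], between a subject's homotopic
#'   deviation and asymmetry deviation; negative values plant a negative
#'   across-subject HoFC-LI association.
#' @param rho_sd,asym_sd Across-subject standard deviations of the per-pair
#'   homotopic and asymmetry deviations.
#' @param age_range Uniform age range (years) for the cohort.
#' @param age_slopes List with per-year drifts `rho` and `asym` applied to
#'   the targets around the mid-range age.
#' @param ar1 Lag-1 temporal autocorrelation of the series.
#' @param confound_sd Standard deviation of a global additive confound
#'   signal (0 disables it).
#' @param seed Integer seed (mandatory); per-subject seeds are derived from
#'   it by a fixed counter scheme.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(atlas, n_subjects, n_frames, tr = 0.72,
                              rho_homotopic = 0.5, intra_base = 0.2,
                              asym = 0.1, cross_bg = 0.05, coupling = 0,
                              rho_sd = 0.08, asym_sd = 0.05,
                              age_range = c(22, 36),
                              age_slopes = list(rho = 0, asym = 0),
                              ar1 = 0, confound_sd = 0, seed) {
  stopifnot(inherits(atlas, "homotopic_atlas"))
  if (missing(seed) || !is.finite(seed)) stop("seed is mandatory")
  np <- n_pairs(atlas)
  rho_homotopic <- rep_len(rho_homotopic, np)
  asym <- rep_len(asym, np)
  if (any(abs(rho_homotopic) >= 1)) stop("rho_homotopic must lie in (-1, 1)")
  if (abs(coupling) > 1) stop("coupling must lie in [-1, 1]")
  if (abs(ar1) >= 1) stop("ar1 must lie in (-1, 1)")
  if (n_frames < 2 * n_regions(atlas))
    warning("n_frames < 2 x regions; FC estimates will be noisy")
  structure(list(atlas = atlas, n_subjects = n_subjects, n_frames = n_frames,
                 tr = tr, rho_homotopic = rho_homotopic,
                 intra_base = intra_base, asym = asym, cross_bg = cross_bg,
                 coupling = coupling, rho_sd = rho_sd, asym_sd = asym_sd,
                 age_range = age_range, age_slopes = age_slopes, ar1 = ar1,
                 confound_sd = confound_sd, seed = as.integer(seed)),
            class = "simulation_config")
}

subject_seed <- function(seed, subject, session = 1) {
  as.integer((as.double(seed) + 7919 * subject + 104729 * (session - 1)) %%
               2147483647)
}

#' Target region-by-region correlation matrix
#'
#' Assembles the correlation structure the generator aims for — homotopic
#' correlations on the pair diagonal, asymmetric same-hemisphere coupling,
#' a flat cross-hemisphere background — and projects it to the nearest
#' positive-semidefinite correlation matrix (eigenvalue clipping at zero,
#' then unit-diagonal renormalization) when the target is indefinite. The
#' maximum absolute adjustment applied is attached as attribute
#' `"psd_adjust"`; a deviation of the realized homotopic correlations from
#' their targets above 0.1 triggers a warning.
#'
#' @param atlas A `homotopic_atlas`.
#' @param rho_homotopic Per-pair homotopic correlation targets.
#' @param intra_base Baseline same-hemisphere correlation.
#' @param asym Per-pair asymmetry increments (see [simulation_config()]).
#' @param cross_bg Cross-hemisphere non-homotopic correlation.
#' @return region x region correlation matrix with region labels, in atlas
#'   declaration order.
#' @export
build_region_covariance <- function(atlas, rho_homotopic, intra_base = 0,
                                    asym = 0, cross_bg = 0) {
  np <- n_pairs(atlas)
  rho_homotopic <- rep_len(rho_homotopic, np)
  asym <- rep_len(asym, np)
  p <- n_regions(atlas)
  labels <- names(sort(atlas$region_index))
  left_idx <- atlas$region_index[atlas$pairs$left]
  right_idx <- atlas$region_index[atlas$pairs$right]

  m <- matrix(cross_bg, p, p, dimnames = list(labels, labels))
  half <- outer(asym, asym, function(a, b) (a + b) / 4)
  m[left_idx, left_idx] <- intra_base + half
  m[right_idx, right_idx] <- intra_base - half
  m[cbind(left_idx, right_idx)] <- rho_homotopic
  m[cbind(right_idx, left_idx)] <- rho_homotopic
  diag(m) <- 1

  e <- eigen(m, symmetric = TRUE)
  adjust <- 0
  if (min(e$values) < -1e-12) {
    lam <- pmax(e$values, 0)
    m2 <- e$vectors %*% (lam * t(e$vectors))
    d <- sqrt(diag(m2))
    m2 <- m2 / outer(d, d)
    adjust <- max(abs(m2 - m))
    dimnames(m2) <- dimnames(m)
    m <- (m2 + t(m2)) / 2
    diag(m) <- 1
    dev <- max(abs(m[cbind(left_idx, right_idx)] - rho_homotopic))
    if (dev > 0.1)
      warning("PSD projection moved homotopic correlations by up to ",
              signif(dev, 3))
  }
  attr(m, "psd_adjust") <- adjust
  m
}

#' Simulate a stationary Gaussian BOLD surrogate
#'
#' Draws a frames x regions Gaussian series whose zero-lag cross-correlation
#' equals `cov` exactly in population. Temporal autocorrelation is an AR(1)
#' recursion applied identically to all regions
#' (`x_t = ar1 x_{t-1} + sqrt(1 - ar1^2) e_t`, stationary start), which
#' leaves the zero-lag covariance untouched.
#'
#' @param cov Positive-semidefinite covariance/correlation matrix.
#' @param n_frames Number of frames.
#' @param tr Sampling interval (s).
#' @param ar1 Lag-1 autocorrelation in (-1, 1).
#' @param seed Integer seed.
#' @param run_id Run identifier.
#' @return A `parcel_ts`.
#' @export
simulate_subject_timeseries <- function(cov, n_frames, tr = 0.72, ar1 = 0,
                                        seed, run_id = "sim") {
  cov <- as.matrix(cov)
  e <- eigen(cov, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values)))
    stop("covariance matrix is not positive semidefinite")
  lam <- pmax(e$values, 0)
  E <- e$vectors %*% diag(sqrt(lam), nrow = length(lam))
  set.seed(seed)
  z <- matrix(stats::rnorm(n_frames * ncol(cov)), n_frames)
  innov <- z %*% t(E)
  if (ar1 != 0) {
    s <- sqrt(1 - ar1^2)
    innov <- apply(innov, 2, function(col) {
      as.numeric(stats::filter(c(col[1], s * col[-1]), ar1,
                               method = "recursive"))
    })
  }
  colnames(innov) <- colnames(cov)
  parcel_ts(innov, tr, run_id = run_id)
}

subject_targets <- function(config, age, d, e2) {
  mid <- mean(config$age_range)
  rho <- config$rho_homotopic + config$age_slopes$rho * (age - mid) +
    config$rho_sd * d
  asym <- config$asym + config$age_slopes$asym * (age - mid) +
    config$asym_sd * (config$coupling * d +
                        sqrt(1 - config$coupling^2) * e2)
  list(rho = pmin(pmax(rho, -0.95), 0.95), asym = asym)
}

#' Simulate a full cohort with ground truth
#'
#' For each subject, per-pair homotopic and asymmetry targets are drawn
#' around the configured values (correlated across the two when `coupling`
#' is nonzero), a region covariance is built, and a Gaussian series is
#' generated from it. The ground-truth table holds the population values of
#' every downstream measure, computed from each subject's realized
#' covariance with the same formulas the measurement module applies to data
#' — so measured and true values converge as the run length grows.
#'
#' @param config A `simulation_config`.
#' @param session Session counter; re-simulating with a different session
#'   redraws the time series (new noise) while keeping every subject's
#'   underlying parameters fixed, which is exactly a test-retest design.
#' @param events,betas Optional task design: when an event table is given,
#'   every subject's run is generated by [simulate_task_run()] on top of the
#'   same background covariance (with `betas` activation amplitudes), and
#'   the ground truth still describes the background structure.
#' @return List with `timeseries` (named list of `parcel_ts`), `covariates`
#'   (data.frame), `truth` (data.frame subject_id, pair_id, hofc, L, R, li),
#'   `confounds` (list of per-subject confound matrices or NULL) and the
#'   config.
#' @export
simulate_cohort <- function(config, session = 1, events = NULL,
                            betas = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  atlas <- config$atlas
  n <- config$n_subjects
  np <- n_pairs(atlas)

  set.seed(config$seed)
  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  sex <- stats::rbinom(n, 1, 0.5)
  handedness <- pmin(pmax(round(stats::rnorm(n, 70, 40)), -100), 100)
  d <- matrix(stats::rnorm(n * np), n)     # shared pair-level deviations
  e2 <- matrix(stats::rnorm(n * np), n)    # asymmetry-specific deviations

  ids <- sprintf("S%03d", seq_len(n))
  ts_list <- vector("list", n)
  conf_list <- vector("list", n)
  truth <- vector("list", n)
  for (s in seq_len(n)) {
    tg <- subject_targets(config, age[s], d[s, ], e2[s, ])
    covm <- build_region_covariance(atlas, tg$rho, config$intra_base,
                                    tg$asym, config$cross_bg)
    sseed <- subject_seed(config$seed, s, session)
    rid <- paste0(ids[s], "_ses", session)
    if (is.null(events)) {
      ts <- simulate_subject_timeseries(covm, config$n_frames, config$tr,
                                        config$ar1, seed = sseed,
                                        run_id = rid)
    } else {
      ts <- simulate_task_run(covm, events,
                              if (is.null(betas)) 0 else betas,
                              config$n_frames, config$tr, config$ar1,
                              seed = sseed)$ts
      ts$run_id <- rid
    }
    if (config$confound_sd > 0) {
      conf <- matrix(stats::rnorm(config$n_frames, 0, config$confound_sd),
                     ncol = 1)
      ts$data <- ts$data + conf[, 1]
      conf_list[[s]] <- conf
    }
    ts_list[[s]] <- ts
    zm <- fisher_z(new_fc(covm, "r"))
    tm <- subject_measures(zm, atlas)
    truth[[s]] <- data.frame(subject_id = ids[s],
                             pair_id = atlas$pairs$pair_id,
                             hofc = unname(tm$hofc), L = unname(tm$L),
                             R = unname(tm$R), li = unname(tm$li))
  }
  names(ts_list) <- ids
  list(timeseries = ts_list,
       covariates = data.frame(subject_id = ids, age = age, sex = sex,
                               handedness = handedness),
       truth = do.call(rbind, truth),
       confounds = if (config$confound_sd > 0) conf_list else NULL,
       config = config)
}

#' Canonical double-gamma hemodynamic response
#'
#' The standard shape used to convolve task events: a gamma density peaking
#' near 5 s minus a 1/6-weighted undershoot gamma peaking near 15 s, sampled
#' at the acquisition interval and normalized to unit peak amplitude.
#'
#' @param tr Sampling interval (s), > 0.
#' @param length_s Support of the kernel in seconds.
#' @return Numeric vector of HRF samples starting at t = 0 (value 0 there).
#' @export
double_gamma_hrf <- function(tr, length_s = 32) {
  if (tr <= 0) stop("tr must be positive")
  t <- seq(0, length_s, by = tr)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

#' Simulate a task run with planted activations
#'
#' A background series drawn exactly as a resting run (same seed gives the
#' identical background), plus HRF-convolved boxcar responses scaled by
#' per-region betas. Fixation blocks carry no activation.
#'
#' @param cov Region covariance of the background series.
#' @param events Event table (`onset`, `duration`, `condition`).
#' @param betas regions x conditions matrix of activation amplitudes (or a
#'   scalar applied to all non-fixation conditions).
#' @param n_frames,tr,ar1,seed As in [simulate_subject_timeseries()].
#' @return List with `ts` (`parcel_ts`) and the validated `events`.
#' @export
simulate_task_run <- function(cov, events, betas, n_frames, tr = 0.72,
                              ar1 = 0, seed) {
  bg <- simulate_subject_timeseries(cov, n_frames, tr, ar1, seed,
                                    run_id = "task")
  X <- build_task_regressors(events, tr, n_frames)
  p <- ncol(as_parcel_data(bg))
  if (length(betas) == 1) betas <- matrix(betas, p, ncol(X))
  betas <- as.matrix(betas)
  if (ncol(X) > 0) {
    if (nrow(betas) != p || ncol(betas) != ncol(X))
      stop("betas must be regions x conditions (",
           p, " x ", ncol(X), ")")
    bg$data <- bg$data + X %*% t(betas)
  }
  list(ts = bg, events = validate_events(events))
}

#' Simulate heritable phenotypes on a pedigree
#'
#' Zero-mean, unit-variance traits whose covariance across individuals is
#' `h2 * (2 Phi) + (1 - h2) * I` per trait, with cross-trait genetic
#' covariance `rho_g * sqrt(h2_t h2_u) * (2 Phi)` and environmental
#' cross-covariance `rho_e * sqrt((1-h2_t)(1-h2_u)) * I`.
#'
#' @param phi Kinship matrix (see [kinship_from_pedigree()]).
#' @param h2 Heritability in \[0, 1\], scalar or one per trait.
#' @param n_traits Number of traits.
#' @param rho_g Genetic correlation between traits (scalar applied to all
#'   off-diagonal trait pairs).
#' @param rho_e Environmental correlation between traits.
#' @param seed Integer seed.
#' @return individuals x traits numeric matrix with individual ids as row
#'   names.
#' @export
simulate_family_phenotypes <- function(phi, h2, n_traits = 1, rho_g = 0,
                                       rho_e = 0, seed) {
  K <- 2 * as.matrix(unclass(phi))
  if (any(h2 < 0 | h2 > 1)) stop("h2 must lie in [0, 1]")
  if (abs(rho_g) > 1) stop("rho_g must lie in [-1, 1]")
  h2 <- rep_len(h2, n_traits)
  G <- outer(sqrt(h2), sqrt(h2)) * (diag(n_traits) * (1 - rho_g) + rho_g)
  E <- outer(sqrt(1 - h2), sqrt(1 - h2)) *
    (diag(n_traits) * (1 - rho_e) + rho_e)
  e <- eigen(K, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  n <- nrow(K)
  set.seed(seed)
  ystar <- matrix(0, n, n_traits)
  z <- matrix(stats::rnorm(n * n_traits), n)
  for (i in seq_len(n)) {
    C <- lam[i] * G + E
    ee <- eigen(C, symmetric = TRUE)
    ystar[i, ] <- ee$vectors %*% (sqrt(pmax(ee$values, 0)) *
                                    crossprod(ee$vectors, z[i, ]))
  }
  out <- e$vectors %*% ystar
  rownames(out) <- rownames(K)
  colnames(out) <- paste0("trait", seq_len(n_traits))
  out
}

#' Small synthetic atlas for examples and simulations
#'
#' @param np Number of homotopic pairs.
#' @param zones Zone assignment per pair; defaults to cycling through the
#'   six hierarchy zones.
#' @return A `homotopic_atlas` with labels `L001`/`R001`, ...
#' @export
make_synthetic_atlas <- function(np, zones = NULL) {
  if (is.null(zones)) zones <- rep_len(hierarchy_zones(), np)
  homotopic_atlas(data.frame(
    pair_id = sprintf("P%03d", seq_len(np)),
    left = sprintf("L%03d", seq_len(np)),
    right = sprintf("R%03d", seq_len(np)),
    zone = rep_len(zones, np)))
}
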