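#' Default three-state transition matrix
#'
#' Self-transition probabilities 0.806 (I), 0.626 (N) and 0.947 (D). The
#' off-diagonal mass of each row is not fully determined by those values;
#' it is resolved so that the chain's stationary distribution equals the
#' observed class prevalences (8.2 / 14.5 / 77.3 percent for I / N / D),
#' with a small direct decreased-to-improved rate (0.002) reflecting that
#' recoveries almost always pass through the no-change band.
#'
#' @return 3 x 3 row-stochastic matrix (rows/cols I, N, D).
#' @export
defaultTransitionMatrix <- function() {
  matrix(c(0.806,       0.180573171, 0.013426829,
           0.099048276, 0.626,       0.274951724,
           0.002,       0.051,       0.947),
         3L, 3L, byrow = TRUE,
         dimnames = list(stateLevels(), stateLevels()))
}

#' Default state-dependent feature emission means
#'
#' 3 x 19 matrix (rows I, N, D), zero by default: in the default
#' configuration the class information enters through the quality-walk
#' coupling (\code{\link{defaultWalkCoupling}}) rather than through
#' state-keyed mean shifts, mirroring how the real descriptors relate to
#' model quality. Supplying a non-zero matrix adds state-keyed offsets on
#' top.
#'
#' @return 3 x 19 numeric matrix.
#' @export
defaultEmissionMeans <- function() {
  matrix(0, 3L, 19L, dimnames = list(stateLevels(), canonicalFeatures()))
}

#' Default coupling of features to the quality walk
#'
#' The two distance metrics to the starting model respond to how far the
#' structure has moved from the start regardless of direction:
#' \code{N_RMSD_SM} rises and \code{N_GDTTS_SM} falls with the magnitude
#' of the GDT_TS change (coefficient 1.5 per 0.05 GDT_TS on the
#' standardized scale, against unit noise). Four energy terms carry a
#' weak directional signal (coefficient -0.3 per 0.05: improvement lowers
#' the energy scores). The remaining 13 descriptors are uninformative
#' noise. Separating improved from no-change snapshots therefore requires
#' integrating the weak, noisy evidence about the walk level over time --
#' the regime in which single-snapshot classifiers identify improvements
#' poorly.
#'
#' @return List with numeric 19-vectors \code{magnitude} and
#'   \code{direction}: feature loadings on |dGDTTS|/0.05 and on
#'   dGDTTS/0.05.
#' @export
defaultWalkCoupling <- function() {
  magnitude <- stats::setNames(numeric(19L), canonicalFeatures())
  direction <- magnitude
  magnitude["N_RMSD_SM"] <- 1.5
  magnitude["N_GDTTS_SM"] <- -1.5
  direction[c("N_DDFIRESUM", "N_DOPE", "N_GOAP", "N_MOLPDF")] <- -0.3
  list(magnitude = magnitude, direction = direction)
}

#' Configuration of the synthetic trajectory generator
#'
#' @param n_targets,trajectories_per_target,steps_per_trajectory Shape of
#'   the generated set; a trajectory has \code{steps_per_trajectory + 1}
#'   snapshots (the time-0 starting model plus one every 2 ps). Defaults
#'   mirror the real dataset's 42 targets at roughly 3 percent of its
#'   snapshot count.
#' @param transition_matrix 3 x 3 row-stochastic matrix of the hidden
#'   state chain (default \code{\link{defaultTransitionMatrix}}).
#' @param emission_means 3 x 19 state-dependent feature means (default
#'   \code{\link{defaultEmissionMeans}}).
#' @param walk_coupling Feature loadings on the quality walk (default
#'   \code{\link{defaultWalkCoupling}}).
#' @param emission_sd Length-19 marginal feature standard deviations.
#' @param feature_autocorrelation AR(1) coefficient rho in [0, 1) of the
#'   feature noise around the state mean.
#' @param gdtts_start_range Starting-model GDT_TS is drawn uniformly from
#'   this range (the real targets span roughly 0.3 to 0.9).
#' @param gdtts_step_sd Innovation standard deviation of the quality walk.
#' @param state_targets Mean-reversion targets of the quality walk per
#'   state (GDT_TS change the walk is pulled toward while in I / N / D).
#' @param reversion Mean-reversion rate of the walk per 2 ps step.
#' @param seed Integer seed; a fixed seed reproduces the set bit-exactly.
#' @return A list of class \code{syntheticConfig}.
#' @export
syntheticConfig <- function(n_targets = 42L, trajectories_per_target = 4L,
                            steps_per_trajectory = 300L,
                            transition_matrix = defaultTransitionMatrix(),
                            emission_means = defaultEmissionMeans(),
                            walk_coupling = defaultWalkCoupling(),
                            emission_sd = rep(1, 19L),
                            feature_autocorrelation = 0.5,
                            gdtts_start_range = c(0.3, 0.9),
                            gdtts_step_sd = 0.01,
                            state_targets = c(I = 0.05, N = 0, D = -0.08),
                            reversion = 0.5, seed = 1L) {
  cfg <- list(n_targets = as.integer(n_targets),
              trajectories_per_target = as.integer(trajectories_per_target),
              steps_per_trajectory = as.integer(steps_per_trajectory),
              transition_matrix = transition_matrix,
              emission_means = emission_means,
              walk_coupling = walk_coupling,
              emission_sd = emission_sd,
              feature_autocorrelation = feature_autocorrelation,
              gdtts_start_range = gdtts_start_range,
              gdtts_step_sd = gdtts_step_sd,
              state_targets = state_targets,
              reversion = reversion, seed = as.integer(seed))
  if (any(abs(rowSums(cfg$transition_matrix) - 1) > 1e-8) ||
      any(cfg$transition_matrix < 0)) {
    stop("transition_matrix must be row-stochastic")
  }
  if (cfg$feature_autocorrelation < 0 || cfg$feature_autocorrelation >= 1) {
    stop("feature_autocorrelation must lie in [0, 1)")
  }
  if (any(cfg$emission_sd <= 0) || cfg$gdtts_step_sd <= 0) {
    stop("standard deviations must be positive")
  }
  stopifnot(identical(dim(cfg$emission_means), c(3L, 19L)),
            length(cfg$walk_coupling$magnitude) == 19L,
            length(cfg$walk_coupling$direction) == 19L)
  class(cfg) <- "syntheticConfig"
  cfg
}

# clamp a walk value into the GDT_TS-change band of a state so the label
# derived from the walk coincides with the hidden state
.clampToBand <- function(x, state) {
  eps <- 1e-4
  switch(state,
         I = max(x, 0.01),
         N = min(max(x, -0.01), 0.01 - eps),
         D = min(x, -0.01 - eps))
}

#' Simulate labeled synthetic trajectories
#'
#' Per trajectory: a hidden state follows the three-state Markov chain
#' (starting in N at the time-0 snapshot); the GDT_TS change performs a
#' mean-reverting random walk pulled toward a state-specific level and
#' constrained to the state's band, so the labels re-derived from the
#' walk via \code{\link{assignLabel}} are always consistent with it;
#' features are the state's emission mean plus the walk-coupled signal
#' (\code{\link{defaultWalkCoupling}}) plus AR(1) noise. A fixed seed
#' reproduces the output bit-exactly.
#'
#' @param cfg A \code{\link{syntheticConfig}}.
#' @return A labeled \linkS4class{TrajectorySet}.
#' @export
simulateTrajectories <- function(cfg = syntheticConfig()) {
  stopifnot(inherits(cfg, "syntheticConfig"))
  set.seed(cfg$seed)
  P <- cfg$transition_matrix
  rho <- cfg$feature_autocorrelation
  innov_sd <- cfg$emission_sd * sqrt(1 - rho^2)
  nT <- cfg$steps_per_trajectory + 1L
  pieces <- vector("list", cfg$n_targets * cfg$trajectories_per_target)
  idx <- 0L
  for (g in seq_len(cfg$n_targets)) {
    target <- sprintf("SYN%03d", g)
    g0 <- stats::runif(1L, cfg$gdtts_start_range[1L], cfg$gdtts_start_range[2L])
    for (r in seq_len(cfg$trajectories_per_target)) {
      state <- integer(nT)
      delta <- numeric(nT)
      state[1L] <- 2L                     # N: the starting model itself
      delta[1L] <- 0
      feat <- matrix(0, 19L, nT)
      cpl <- function(d) {
        cfg$walk_coupling$magnitude * (abs(d) / 0.05) +
          cfg$walk_coupling$direction * (d / 0.05)
      }
      dev <- stats::rnorm(19L, 0, cfg$emission_sd)  # stationary AR(1) draw
      feat[, 1L] <- cfg$emission_means[state[1L], ] + cpl(delta[1L]) + dev
      for (t in 2L:nT) {
        state[t] <- sample.int(3L, 1L, prob = P[state[t - 1L], ])
        s <- stateLevels()[state[t]]
        prop <- delta[t - 1L] +
          cfg$reversion * (cfg$state_targets[[s]] - delta[t - 1L]) +
          stats::rnorm(1L, 0, cfg$gdtts_step_sd)
        delta[t] <- .clampToBand(prop, s)
        dev <- rho * dev + stats::rnorm(19L, 0, innov_sd)
        feat[, t] <- cfg$emission_means[state[t], ] + cpl(delta[t]) + dev
      }
      idx <- idx + 1L
      pieces[[idx]] <- list(
        target = target,
        trajectory = sprintf("%s_run%02d", target, r),
        time = 2L * (seq_len(nT) - 1L),
        gd = pmin(pmax(g0 + delta, 0), 1),
        delta = delta, feat = feat)
    }
  }
  makeTrajectorySet(
    features = do.call(cbind, lapply(pieces, `[[`, "feat")),
    target_id = unlist(lapply(pieces, function(p) rep(p$target, length(p$time)))),
    trajectory_id = unlist(lapply(pieces, function(p) rep(p$trajectory, length(p$time)))),
    time_ps = unlist(lapply(pieces, `[[`, "time")),
    gdtts_ref = unlist(lapply(pieces, `[[`, "gd")),
    delta_gdtts = unlist(lapply(pieces, `[[`, "delta")))
}

#' Build the standard desk-scale fixtures
#'
#' \code{"unit"}: 2 targets x 2 trajectories x 200 steps.
#' \code{"integration"}: 42 targets x 4 trajectories x 300 steps, the
#' shape used for the scaled-down temporal-advantage study. When
#' \code{dir} is given, the canonical feature-table CSV (and for the unit
#' level a small synthetic PDB ensemble) is written there.
#'
#' @param level \code{"unit"} or \code{"integration"}.
#' @param dir Optional output directory for fixture files.
#' @param seed Integer seed.
#' @return The \linkS4class{TrajectorySet}; when files are written their
#'   paths are in attribute \code{"files"}.
#' @export
makeFixture <- function(level = c("unit", "integration"), dir = NULL,
                        seed = 42L) {
  level <- match.arg(level)
  cfg <- if (level == "unit") {
    syntheticConfig(n_targets = 2L, trajectories_per_target = 2L,
                    steps_per_trajectory = 199L, seed = seed)
  } else {
    syntheticConfig(seed = seed)
  }
  ts <- simulateTrajectories(cfg)
  files <- character()
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    csv <- file.path(dir, sprintf("%s_features.csv", level))
    writeFeatureTable(ts, csv)
    files <- csv
    if (level == "unit") {
      set.seed(seed)
      ens <- simulateEnsemble(n_res = 20L, n_models = 3L, noise = 0.3)
      for (i in seq_along(ens)) {
        p <- file.path(dir, sprintf("synthetic_model_%d.pdb", i))
        writeStructurePDB(ens[[i]], p)
        files <- c(files, p)
      }
    }
    attr(ts, "files") <- files
  }
  ts
}

#' Simulate a small synthetic structure ensemble
#'
#' An idealized alpha-helical CA/CB trace perturbed by Gaussian coordinate
#' noise; purely synthetic stand-ins for toy-scale structure-metric and
#' restraint calculations.
#'
#' @param n_res Number of residues.
#' @param n_models Ensemble size.
#' @param noise Coordinate noise standard deviation, Angstrom.
#' @param seed Optional integer seed.
#' @return List of \linkS4class{StructureModel}s.
#' @export
simulateEnsemble <- function(n_res = 20L, n_models = 3L, noise = 0.3,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  i <- seq_len(n_res)
  # ideal helix: rise 1.5 A, 100 degrees per residue, radius 2.3 A
  base <- cbind(2.3 * cos(i * 100 * pi / 180),
                2.3 * sin(i * 100 * pi / 180),
                1.5 * i)
  lapply(seq_len(n_models), function(m) {
    ca <- base + matrix(stats::rnorm(3L * n_res, 0, noise), n_res, 3L)
    cb <- ca + 1.5 * cbind(cos(i), sin(i), 0) / 1
    structureModel(resno = rep(i, 2L), atom = rep(c("CA", "CB"), each = n_res),
                   xyz = rbind(ca, cb), id = sprintf("synthetic_%d", m))
  })
}
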