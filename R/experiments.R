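# Sweep driver, window summaries, equilibrium classification, and the
# diffusion-stability measures for the degradation and corruption
# experiments.

#' Configuration for the degradation experiment
#'
#' Cooperative-only initial mix (10 each of TFT, TF2T, AllC, Pavlov,
#' Probabilistic), allowed deceptions {None, Degradation}, population 50,
#' 5001 generations. Non-cooperative strategies and deceivers can only
#' enter by mutation.
#'
#' @param cost Degradation cost per game.
#' @param seed RNG seed.
#' @param ticks Number of generations.
#' @return A \code{\link{sim_config}}.
#' @export
degradation_config <- function(cost = 0, seed = NULL, ticks = 5001) {
  sim_config(cost = cost, seed = seed, ticks = ticks,
             allowed_deceptions = c("None", "Degradation"))
}

#' Configuration for the corruption experiment
#'
#' As \code{\link{degradation_config}} but with the Corruption operator
#' evolvable instead of Degradation.
#'
#' @inheritParams degradation_config
#' @export
corruption_config <- function(cost = 0, seed = NULL, ticks = 5001) {
  sim_config(cost = cost, seed = seed, ticks = ticks,
             allowed_deceptions = c("None", "Corruption"))
}

#' Derive independent per-run seeds from a master seed
#'
#' Counter-style scheme: seeds the RNG with the master seed and draws n
#' distinct 31-bit integers, so runs are independent and the whole sweep is
#' reproducible from one number.
#'
#' @param master_seed Integer master seed.
#' @param n Number of seeds.
#' @return Integer vector of length n.
#' @export
derive_seeds <- function(master_seed, n) {
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max, n)
}

#' Run a parameter sweep of seeded simulations
#'
#' One seeded run per (grid value, replicate). Results are returned
#' in memory and, when \code{outdir} is given, persisted as one CSV per run
#' (named \code{<experiment>_cost<value>_seed<seed>.csv}) plus an index
#' file \code{index.csv} with columns cost, replicate, seed, path and
#' equilibrium_label.
#'
#' @param base_config Function of \code{(cost, seed)} returning a
#'   \code{\link{sim_config}} (e.g. \code{\link{degradation_config}}), or a
#'   \code{sim_config} to be modified per grid value.
#' @param values Numeric grid of swept parameter values (deception costs).
#' @param reps Replicates per value (default 30).
#' @param master_seed Master seed for \code{\link{derive_seeds}}.
#' @param outdir Output directory, or \code{NULL} for in-memory only.
#' @param experiment Label used in file names.
#' @param classify Attach an equilibrium label per run (needs at least 2500
#'   recorded ticks; \code{NA} otherwise).
#' @param verbose Log per-run progress to stderr.
#' @return List with \code{index} (data frame) and \code{runs} (list of
#'   \code{trait_ts}, in index order).
#' @export
run_sweep <- function(base_config, values, reps = 30, master_seed = 1,
                      outdir = NULL, experiment = "sweep", classify = FALSE,
                      verbose = FALSE) {
  stopifnot(length(values) >= 1, reps >= 1)
  make_cfg <- if (is.function(base_config)) base_config
  else function(cost, seed) {
    cfg <- base_config
    cfg$cost <- cost
    cfg$seed <- as.integer(seed)
    cfg
  }
  seeds <- derive_seeds(master_seed, length(values) * reps)
  grid <- expand.grid(replicate = seq_len(reps), cost = values)[, 2:1]
  grid$seed <- seeds
  runs <- vector("list", nrow(grid))
  paths <- character(nrow(grid))
  labels <- rep(NA_character_, nrow(grid))
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  for (i in seq_len(nrow(grid))) {
    cfg <- make_cfg(grid$cost[i], grid$seed[i])
    if (verbose)
      message(sprintf("[%s] run %d/%d cost=%g seed=%d", experiment, i,
                      nrow(grid), grid$cost[i], grid$seed[i]))
    ts <- run_simulation(cfg)
    runs[[i]] <- ts
    if (classify && nrow(ts) >= 2500)
      labels[i] <- classify_equilibrium(ts)
    if (!is.null(outdir)) {
      paths[i] <- file.path(outdir, sprintf("%s_cost%g_seed%d.csv",
                                            experiment, grid$cost[i],
                                            grid$seed[i]))
      tryCatch(write_run_csv(ts, paths[i]),
               error = function(e) stop("failed writing ", paths[i], ": ",
                                        conditionMessage(e)))
    }
  }
  index <- data.frame(cost = grid$cost, replicate = grid$replicate,
                      seed = grid$seed, path = paths,
                      equilibrium_label = labels,
                      stringsAsFactors = FALSE)
  if (!is.null(outdir))
    write.csv(index, file.path(outdir, "index.csv"), row.names = FALSE)
  list(index = index, runs = runs)
}

#' Mean fraction of a behaviour group over a tick window
#'
#' Time mean (and, for a list of runs, replicate mean) of the population
#' fraction of a group over [from_tick, to_tick].
#'
#' @param ts A \code{trait_ts} or a list of them (replicates).
#' @param strategies,deceiving Group definition as in
#'   \code{\link{group_fraction}}.
#' @param from_tick,to_tick Window bounds (inclusive, in tick units).
#' @return Mean fraction.
#' @export
summarize_window <- function(ts, strategies = NULL, deceiving = NULL,
                             from_tick, to_tick) {
  if (inherits(ts, "trait_ts")) ts <- list(ts)
  stopifnot(from_tick <= to_tick)
  vals <- vapply(ts, function(x) {
    sel <- x$tick >= from_tick & x$tick <= to_tick
    if (!any(sel)) stop("empty tick window [", from_tick, ", ", to_tick, "]")
    mean(group_fraction(x, strategies, deceiving)[sel])
  }, numeric(1))
  mean(vals)
}

#' Cooperative-strategy population fraction
#'
#' Fraction of agents (deceiving or not) playing TFT, TF2T, AllC, Pavlov
#' or Probabilistic at each recorded tick.
#'
#' @param ts A \code{trait_ts}.
#' @return Numeric vector.
#' @export
cooperative_fraction <- function(ts) {
  group_fraction(ts, strategy_group("cooperative"))
}

# Narrowband spectral peak detection that is robust to red (autocorrelated)
# noise: smoothed periodogram compared against a running-median local
# baseline, so only peaks that are sharp relative to the local spectral
# level count as a dominant oscillation.
spectral_peak_ratio <- function(x) {
  x <- x - mean(x)
  if (sd(x) == 0 || length(x) < 64) return(0)
  p <- spec.pgram(x, spans = c(9, 9), detrend = TRUE, taper = 0, plot = FALSE)
  spec <- p$spec
  nb <- length(spec)
  if (nb < 40) return(0)
  base <- runmed(spec, k = min(31, 2 * (nb %/% 2) - 1))
  keep <- 6:(nb - 5)
  max(spec[keep] / pmax(base[keep], .Machine$double.eps))
}

#' Classify the dynamical outcome of a run
#'
#' Labels after the four canonical outcomes of evolving strategy mixes:
#' \describe{
#'   \item{collapse_to_non_cooperative}{cooperative fraction below the
#'     collapse threshold throughout the final window;}
#'   \item{stable_cooperative_equilibrium}{cooperative fraction above the
#'     cooperative threshold throughout the final window;}
#'   \item{cyclical_polymorphism}{a dominant narrowband oscillation in the
#'     cooperative-fraction tail (smoothed periodogram peak at least
#'     \code{spectral_ratio} times its local running-median baseline);}
#'   \item{stable_polymorphism}{otherwise -- a mixed, noisy but stationary
#'     census.}
#' }
#'
#' @param ts A \code{trait_ts} with at least 2500 recorded ticks.
#' @param collapse_threshold Cooperative fraction below which the
#'   population counts as collapsed (default 0.05).
#' @param cooperative_threshold Fraction above which it counts as fully
#'   cooperative (default 0.95).
#' @param tail_window Length of the final assessment window in ticks
#'   (default 500; the oscillation test uses up to 1000 ticks of tail).
#' @param spectral_ratio Peak-to-local-baseline ratio declaring a dominant
#'   oscillation (default 3).
#' @return One of the four labels, as a character scalar.
#' @export
classify_equilibrium <- function(ts, collapse_threshold = 0.05,
                                 cooperative_threshold = 0.95,
                                 tail_window = 500, spectral_ratio = 3) {
  f <- cooperative_fraction(ts)
  n <- length(f)
  if (n < 2500) stop("series too short to classify (need >= 2500 ticks)")
  tail_f <- f[(n - tail_window + 1):n]
  if (all(tail_f < collapse_threshold)) return("collapse_to_non_cooperative")
  if (all(tail_f > cooperative_threshold))
    return("stable_cooperative_equilibrium")
  spec_f <- f[(n - min(1000, n) + 1):n]
  if (spectral_peak_ratio(spec_f) >= spectral_ratio)
    return("cyclical_polymorphism")
  "stable_polymorphism"
}

#' First tick of the collapse to a non-cooperative census
#'
#' Tick at which exploitative agents have displaced essentially all
#' cooperative strategies. Collapse to a non-cooperative equilibrium is an
#' absorbing outcome, so by default (\code{terminal = TRUE}) the collapse
#' tick is the start of the final contiguous stretch in which the
#' cooperative fraction stays below the threshold through the end of the
#' series (and for at least \code{persist} ticks); transient dips that
#' recover -- as in the recurring corruption diffusion cycles -- do not
#' count. With \code{terminal = FALSE} the first below-threshold stretch
#' of length \code{persist} is returned.
#'
#' @param ts A \code{trait_ts}.
#' @param threshold Collapse threshold on the cooperative fraction
#'   (default 0.05).
#' @param persist Minimum persistence in ticks (default 100).
#' @param terminal Require the collapse to last through the end of the
#'   series (default \code{TRUE}).
#' @return The collapse tick, or \code{NA} if no collapse occurs.
#' @export
collapse_tick <- function(ts, threshold = 0.05, persist = 100,
                          terminal = TRUE) {
  f <- cooperative_fraction(ts)
  below <- f < threshold
  n <- length(below)
  if (n < persist) return(NA_real_)
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ok <- r$values & r$lengths >= persist
  if (terminal) ok <- ok & ends == n
  i <- which(ok)
  if (!length(i)) return(NA_real_)
  ts$tick[starts[i[1]]]
}

#' Establishment tick of a stable polymorphic equilibrium
#'
#' Scans growing prefixes of the cooperative-fraction series for the
#' earliest tick after which the next \code{window} ticks are stationary:
#' past the founding cooperative phase (window mean cooperative fraction at
#' most \code{mixed_upper}), with no trend (absolute fitted change over the
#' window at most \code{trend_tol}) and no dominant narrowband oscillation.
#' The cooperative fraction is the stationarity statistic; the established
#' equilibrium itself is a mix of strategy-by-deception behaviour groups,
#' which at low deception cost can hold only a small cooperative minority.
#'
#' @param ts A \code{trait_ts}.
#' @param window Assessment window in ticks (default 500).
#' @param step Scan step in ticks (default 25).
#' @param trend_tol Maximum absolute fitted linear change of the
#'   cooperative fraction across the window (default 0.1).
#' @param spectral_ratio As in \code{\link{classify_equilibrium}}.
#' @param mixed_upper Upper bound on the window mean cooperative fraction
#'   for the window to count as past the founding phase (default 0.9).
#' @return Earliest establishment tick, or \code{NA} if the series never
#'   leaves the founding cooperative phase and stabilises.
#' @export
establishment_tick <- function(ts, window = 500, step = 25, trend_tol = 0.1,
                               mixed_upper = 0.9,
                               spectral_ratio = 3) {
  f <- cooperative_fraction(ts)
  n <- length(f)
  if (n < window + 1) stop("series shorter than the assessment window")
  tt <- seq_len(window)
  for (start in seq(1, n - window, by = step)) {
    w <- f[start:(start + window - 1)]
    if (mean(w) > mixed_upper) next
    slope <- coef(lm(w ~ tt))[2]
    if (abs(slope) * window > trend_tol) next
    if (spectral_peak_ratio(w) >= spectral_ratio) next
    return(ts$tick[start])
  }
  NA_real_
}

#' Diffusion episodes of the deceiving trait
#'
#' Maximal contiguous runs of ticks in which the deceiver fraction is at or
#' above the establishment threshold, restricted to ticks after
#' \code{after}. Each episode corresponds to one release-and-decay cycle of
#' the deceiving behaviour diffusing through the population.
#'
#' @param ts A \code{trait_ts}.
#' @param threshold Establishment threshold on the deceiver fraction
#'   (default 0.1).
#' @param after Ignore ticks at or before this tick (default 500).
#' @return Data frame with columns \code{start}, \code{end} (ticks) and
#'   \code{length}.
#' @export
diffusion_episodes <- function(ts, threshold = 0.1, after = 500) {
  d <- group_fraction(ts, deceiving = TRUE)
  sel <- ts$tick > after
  above <- d >= threshold & sel
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  data.frame(start = ts$tick[starts[keep]], end = ts$tick[ends[keep]],
             length = r$lengths[keep])
}

#' Fraction of replicate runs exhibiting stable diffusion behaviour
#'
#' A run exhibits stable diffusion when the deceiving trait recurrently
#' establishes itself: at least \code{min_episodes} diffusion episodes
#' after the burn-in tick, or a single persistent episode covering at
#' least half of the post-burn-in horizon.
#'
#' @param runs List of \code{trait_ts} replicates (one cost value).
#' @param threshold,after As in \code{\link{diffusion_episodes}}.
#' @param min_episodes Episodes required for recurrence (default 2).
#' @return Fraction of runs in [0, 1].
#' @export
stable_diffusion_fraction <- function(runs, threshold = 0.1, after = 500,
                                      min_episodes = 2) {
  if (inherits(runs, "trait_ts")) runs <- list(runs)
  stopifnot(length(runs) >= 1)
  stable <- vapply(runs, function(ts) {
    ep <- diffusion_episodes(ts, threshold, after)
    horizon <- max(ts$tick) - after
    nrow(ep) >= min_episodes ||
      (nrow(ep) >= 1 && max(ep$length) >= horizon / 2)
  }, logical(1))
  mean(stable)
}

#' Locate the abrupt drop in stable-diffusion fraction versus cost
#'
#' Given the per-cost fractions of replicate runs with stable diffusion,
#' returns the cost at which the largest single-step decrease lands (the
#' first grid value of the low regime) -- the cost threshold above which
#' the deceiving behaviour cannot gain a foothold.
#'
#' @param costs Numeric cost grid (ascending).
#' @param fractions Stable-diffusion fraction per cost.
#' @return The threshold cost.
#' @export
diffusion_cost_threshold <- function(costs, fractions) {
  stopifnot(length(costs) == length(fractions), length(costs) >= 2,
            !is.unsorted(costs))
  drops <- -diff(fractions)
  costs[which.max(drops) + 1]
}
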