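# Population container and the per-tick evolutionary loop: random pairing,
# encounters, culling of the two lowest scorers, score-weighted breeding
# with two-point crossover and probabilistic mutation.

#' Simulation configuration
#'
#' Bundles all parameters of one evolutionary run. The defaults are the
#' study conditions used throughout: 50 agents, 5001 ticks, payoffs
#' (5, 3, 1, 0), memory depth 3. One tick is one generation: the population
#' is randomly paired (25 pairs of 50), each pair plays a match of
#' \code{rounds_per_encounter} PD rounds, then the two lowest scorers are
#' removed and replaced by two offspring.
#'
#' @param population_size Even number of agents (default 50).
#' @param ticks Number of generations to simulate (default 5001).
#' @param payoffs A \code{\link{payoff_matrix}}.
#' @param cost Deception cost per game, charged to every deceiving player.
#' @param allowed_deceptions Deception kinds reachable by mutation in this
#'   run (a subset of \code{\link{deception_levels}()}, normally including
#'   \code{"None"}).
#' @param initial_mix Named integer vector: non-deceiving agents per
#'   strategy at tick 0.
#' @param initial_deceivers Optional data frame with columns
#'   \code{strategy}, \code{deception}, \code{count}: deceiving agents at
#'   tick 0.
#' @param memory_depth Opponent moves remembered (default 3).
#' @param rounds_per_encounter Consecutive PD rounds each pair plays in its
#'   per-tick match (default 6). Within-match retaliation by the
#'   memory-driven strategies is what allows cooperation to persist under
#'   identity-free memory; deceivers deceive, pay the cost and are
#'   success-scored on every round.
#' @param initial_mutation_prob Mutation probability shared by all founding
#'   agents (default 0.02).
#' @param mutation_sigma Standard deviation of the Gaussian perturbation
#'   applied to the mutation-probability locus when it mutates
#'   (default 0.01).
#' @param newborn_score How offspring scores are initialised:
#'   \code{"parent_mean"} (default; offspring start at the mean of their two
#'   parents' cumulative scores, the reading under which lineage turnover
#'   and strategy invasion remain possible once incumbent scores have grown)
#'   or \code{"zero"}.
#' @param seed Integer RNG seed, or \code{NULL} to use the current RNG
#'   state.
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(population_size = 50, ticks = 5001,
                       payoffs = payoff_matrix(), cost = 0,
                       allowed_deceptions = c("None", "Degradation"),
                       initial_mix = NULL, initial_deceivers = NULL,
                       memory_depth = 3, rounds_per_encounter = 6,
                       initial_mutation_prob = 0.02,
                       mutation_sigma = 0.01,
                       newborn_score = c("parent_mean", "zero"),
                       seed = NULL) {
  newborn_score <- match.arg(newborn_score)
  stopifnot(population_size >= 4, population_size %% 2 == 0, ticks >= 0,
            inherits(payoffs, "payoff_matrix"), cost >= 0,
            memory_depth >= 1,
            initial_mutation_prob >= 0, initial_mutation_prob <= 1,
            mutation_sigma >= 0)
  deception_code(allowed_deceptions)
  if (is.null(initial_mix)) {
    # cooperative-only initialisation: equal mix of the five cooperative
    # strategies, no deceivers
    initial_mix <- stats::setNames(rep(population_size / 5, 5),
                                   c("TFT", "TF2T", "AllC", "Pavlov",
                                     "Probabilistic"))
  }
  strategy_code(names(initial_mix))
  n_dec <- 0L
  if (!is.null(initial_deceivers)) {
    stopifnot(is.data.frame(initial_deceivers),
              all(c("strategy", "deception", "count") %in%
                    names(initial_deceivers)))
    strategy_code(initial_deceivers$strategy)
    deception_code(initial_deceivers$deception)
    n_dec <- sum(initial_deceivers$count)
  }
  if (sum(initial_mix) + n_dec != population_size)
    stop("initial_mix and initial_deceivers counts must sum to population_size")
  structure(list(population_size = as.integer(population_size),
                 ticks = as.integer(ticks), payoffs = payoffs, cost = cost,
                 allowed_deceptions = allowed_deceptions,
                 initial_mix = initial_mix,
                 initial_deceivers = initial_deceivers,
                 memory_depth = as.integer(memory_depth),
                 rounds_per_encounter = as.integer(rounds_per_encounter),
                 initial_mutation_prob = initial_mutation_prob,
                 mutation_sigma = mutation_sigma,
                 newborn_score = newborn_score,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("IPD simulation config: n=%d, ticks=%d, cost=%g\n",
              x$population_size, x$ticks, x$cost))
  cat("  allowed deceptions:", paste(x$allowed_deceptions, collapse = ", "), "\n")
  cat("  initial mix:",
      paste(sprintf("%s=%d", names(x$initial_mix), x$initial_mix),
            collapse = ", "), "\n")
  invisible(x)
}

#' Create the founding population of a run
#'
#' Founders have empty memories, score 0 and the configured common mutation
#' probability. The population is stored column-wise (one vector per field)
#' for the compiled engine.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @return An object of class \code{ipd_population}.
#' @export
new_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  strat <- rep(strategy_code(names(cfg$initial_mix)),
               times = as.integer(cfg$initial_mix))
  dec <- rep(0L, length(strat))
  if (!is.null(cfg$initial_deceivers)) {
    strat <- c(strat, rep(strategy_code(cfg$initial_deceivers$strategy),
                          times = as.integer(cfg$initial_deceivers$count)))
    dec <- c(dec, rep(deception_code(cfg$initial_deceivers$deception),
                      times = as.integer(cfg$initial_deceivers$count)))
  }
  n <- length(strat)
  structure(list(strategy = strat, deception = dec,
                 mutation_prob = rep(cfg$initial_mutation_prob, n),
                 score = rep(0, n),
                 mem = matrix(-1L, n, cfg$memory_depth),
                 mem_len = rep(0L, n), own_last = rep(-1L, n)),
            class = "ipd_population")
}

#' @export
print.ipd_population <- function(x, ...) {
  tab <- table(strategy_levels()[x$strategy + 1L],
               ifelse(x$deception == 0L, "plain", "deceiving"))
  cat(sprintf("<population of %d agents>\n", length(x$strategy)))
  print(tab)
  invisible(x)
}

as_pop_list <- function(pop) unclass(pop)
pop_from_engine <- function(pl) structure(pl, class = "ipd_population")

#' One generation of random pairing and encounters
#'
#' Draws a uniformly random perfect matching of the population; each pair
#' plays one match of \code{cfg$rounds_per_encounter} consecutive PD rounds
#' (deceptions applied per each agent's deception locus on every round),
#' updating scores and memories in place.
#'
#' @param pop An \code{\link{new_population}} population.
#' @param cfg A \code{\link{sim_config}}.
#' @return A list with the updated \code{population} and the tick's
#'   deception \code{successes} and \code{failures} counts.
#' @export
pair_and_play <- function(pop, cfg) {
  stopifnot(inherits(pop, "ipd_population"), inherits(cfg, "sim_config"))
  if (length(pop$strategy) %% 2 != 0)
    stop("population size must be even for random pairing")
  r <- cpp_pair_and_play(as_pop_list(pop), payoff_vec(cfg$payoffs), cfg$cost,
                         cfg$memory_depth, cfg$rounds_per_encounter)
  list(population = pop_from_engine(r$population),
       successes = r$successes, failures = r$failures)
}

#' Cull the two lowest scorers and breed replacements
#'
#' Removes the two agents with the lowest cumulative score (ties broken
#' uniformly at random), selects parent 1 with probability proportional to
#' max(score, 0) among the survivors (uniformly if all weights are zero)
#' and parent 2 uniformly among the remaining survivors, and replaces the
#' removed agents with two offspring from
#' \code{\link{crossover_mutate}}. Offspring have empty memories; their
#' starting score follows \code{cfg$newborn_score}.
#'
#' @inheritParams pair_and_play
#' @return The updated population (same size).
#' @export
cull_and_breed <- function(pop, cfg) {
  stopifnot(inherits(pop, "ipd_population"), inherits(cfg, "sim_config"))
  pop_from_engine(cpp_cull_and_breed(
    as_pop_list(pop), deception_code(cfg$allowed_deceptions),
    cfg$mutation_sigma,
    if (cfg$newborn_score == "parent_mean") 1L else 0L,
    cfg$memory_depth))
}

#' Two-point crossover and probabilistic mutation of two genomes
#'
#' The genome is the ordered 3-locus vector (strategy, deception,
#' mutation_prob). Two cut points are drawn uniformly from positions
#' {0, 1, 2, 3}; loci between them are swapped between copies of the
#' parents. Each offspring locus then mutates independently with
#' probability equal to that offspring's (post-crossover) mutation
#' probability: strategy to a uniform draw over all seven strategies,
#' deception to a uniform draw over \code{cfg$allowed_deceptions}, and
#' mutation_prob by additive Gaussian noise with standard deviation
#' \code{cfg$mutation_sigma}, clipped to [0, 1].
#'
#' @param g1,g2 Parent genomes: lists with elements \code{strategy},
#'   \code{deception}, \code{mutation_prob}.
#' @param cfg A \code{\link{sim_config}}.
#' @return List of two offspring genomes.
#' @export
crossover_mutate <- function(g1, g2, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  enc <- function(g) list(strategy = strategy_code(g$strategy),
                          deception = deception_code(g$deception),
                          mutation_prob = g$mutation_prob)
  decn <- function(g) list(strategy = strategy_levels()[g$strategy + 1L],
                           deception = deception_levels()[g$deception + 1L],
                           mutation_prob = g$mutation_prob)
  r <- cpp_crossover_mutate(enc(g1), enc(g2),
                            deception_code(cfg$allowed_deceptions),
                            cfg$mutation_sigma)
  list(decn(r$offspring1), decn(r$offspring2))
}

trait_columns <- function() {
  as.vector(t(outer(strategy_levels(), c("plain", "dec"),
                    function(s, d) paste0("count_", s, "_", d))))
}

#' Run a full evolutionary simulation
#'
#' Initialises the population from the config, then repeats
#' (\code{\link{pair_and_play}}, \code{\link{cull_and_breed}}) for
#' \code{cfg$ticks} generations inside the compiled engine, recording the
#' behaviour-group census at tick 0 and after every generation. Fully
#' reproducible from \code{cfg$seed}.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @return A \code{trait_ts} data frame with columns \code{tick}, the 14
#'   per-(strategy x deceiving) counts (\code{count_<strategy>_plain},
#'   \code{count_<strategy>_dec}), \code{mean_score},
#'   \code{deception_successes} and \code{deception_failures}, one row per
#'   recorded tick (\code{ticks + 1} rows). The population size and config
#'   are attached as attributes.
#' @examples
#' ts <- run_simulation(sim_config(ticks = 10, seed = 1))
#' head(ts)
#' @export
run_simulation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  pop <- new_population(cfg)
  m <- cpp_run_simulation(as_pop_list(pop), cfg$ticks,
                          payoff_vec(cfg$payoffs), cfg$cost,
                          cfg$memory_depth, cfg$rounds_per_encounter,
                          deception_code(cfg$allowed_deceptions),
                          cfg$mutation_sigma,
                          if (cfg$newborn_score == "parent_mean") 1L else 0L)
  df <- as.data.frame(m)
  names(df) <- c("tick", trait_columns(), "mean_score",
                 "deception_successes", "deception_failures")
  structure(df, population_size = cfg$population_size, config = cfg,
            class = c("trait_ts", "data.frame"))
}

#' Population size of a trait time series
#' @param ts A \code{trait_ts}.
#' @return Integer population size.
#' @export
population_size <- function(ts) {
  n <- attr(ts, "population_size")
  if (is.null(n)) n <- as.integer(round(sum(ts[1, trait_columns()])))
  n
}

count_cols <- function(ts, strategies = NULL, deceiving = NULL) {
  if (is.null(strategies)) strategies <- strategy_levels()
  suffix <- if (is.null(deceiving)) c("plain", "dec")
            else if (deceiving) "dec" else "plain"
  intersect(as.vector(outer(paste0("count_", strategies, "_"), suffix,
                            paste0)), names(ts))
}

#' Per-tick population fraction of a behaviour group
#'
#' @param ts A \code{trait_ts} from \code{\link{run_simulation}}.
#' @param strategies Strategies in the group (default all seven).
#' @param deceiving \code{TRUE} for deceivers only, \code{FALSE} for
#'   non-deceivers only, \code{NULL} for both.
#' @return Numeric vector, one fraction per recorded tick.
#' @export
group_fraction <- function(ts, strategies = NULL, deceiving = NULL) {
  cols <- count_cols(ts, strategies, deceiving)
  rowSums(ts[, cols, drop = FALSE]) / population_size(ts)
}

#' Cooperative and exploitative strategy groups
#'
#' The cooperative strategies are TFT, TF2T, AllC, Pavlov and
#' Probabilistic; the exploitative (non-cooperative) strategies are AllD
#' and Random.
#'
#' @param which \code{"cooperative"} or \code{"exploitative"}.
#' @return Character vector of strategy names.
#' @export
strategy_group <- function(which = c("cooperative", "exploitative")) {
  which <- match.arg(which)
  if (which == "cooperative") c("TFT", "TF2T", "AllC", "Pavlov", "Probabilistic")
  else c("AllD", "Random")
}

#' Trait-fraction matrix for compartment-model fitting
#'
#' Converts the census to per-tick fractions. Groupings:
#' \describe{
#'   \item{six}{cooperative/exploitative/Random-control, each split by
#'     deceiving or not, where "exploitative" here is AllD (Random is kept
#'     as its own control group). These are the six compartments used for
#'     diffusion-model fits.}
#'   \item{fourteen}{all strategy-by-deception cells.}
#' }
#' Fractions at every tick sum to 1.
#'
#' @param ts A \code{trait_ts}.
#' @param groups \code{"six"} or \code{"fourteen"}.
#' @return Numeric matrix, rows = ticks, named columns = groups.
#' @export
trait_fractions <- function(ts, groups = c("six", "fourteen")) {
  groups <- match.arg(groups)
  n <- population_size(ts)
  if (groups == "fourteen") {
    m <- as.matrix(ts[, trait_columns()]) / n
    colnames(m) <- sub("^count_", "", trait_columns())
    return(m)
  }
  coop <- strategy_group("cooperative")
  m <- cbind(
    coop_plain = rowSums(ts[, count_cols(ts, coop, FALSE), drop = FALSE]),
    coop_dec = rowSums(ts[, count_cols(ts, coop, TRUE), drop = FALSE]),
    exploit_plain = ts[["count_AllD_plain"]],
    exploit_dec = ts[["count_AllD_dec"]],
    random_plain = ts[["count_Random_plain"]],
    random_dec = ts[["count_Random_dec"]])
  m / n
}

#' Write a run to CSV
#'
#' Plain-text persistence of a \code{trait_ts} (tick, the 14 count columns,
#' mean score and per-tick deception success/failure counts).
#'
#' @param ts A \code{trait_ts}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_run_csv <- function(ts, path) {
  write.csv(as.data.frame(ts), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a run CSV written by \code{\link{write_run_csv}}
#'
#' @param path CSV file path.
#' @return A \code{trait_ts} data frame.
#' @export
read_run_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  structure(df,
            population_size = as.integer(round(sum(df[1, trait_columns()]))),
            class = c("trait_ts", "data.frame"))
}
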