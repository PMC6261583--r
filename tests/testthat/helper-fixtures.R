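# Shared fixtures: enumerations of memory states and hand-built populations.

# all memory states of length 0..depth over C/D
all_memories <- function(depth = 3) {
  out <- list(character(0))
  for (len in seq_len(depth)) {
    grids <- do.call(expand.grid, rep(list(c("C", "D")), len))
    out <- c(out, lapply(seq_len(nrow(grids)),
                         function(i) as.character(unlist(grids[i, ]))))
  }
  out
}

# a population with prescribed per-agent fields (defaults: plain TFT)
fixture_population <- function(strategy, deception = NULL, score = NULL,
                               mutation_prob = 0.02, memory_depth = 3) {
  n <- length(strategy)
  if (is.null(deception)) deception <- rep("None", n)
  if (is.null(score)) score <- rep(0, n)
  structure(list(
    strategy = deceptIPD:::strategy_code(strategy),
    deception = deceptIPD:::deception_code(deception),
    mutation_prob = rep_len(mutation_prob, n),
    score = as.double(score),
    mem = matrix(-1L, n, memory_depth),
    mem_len = rep(0L, n),
    own_last = rep(-1L, n)), class = "ipd_population")
}

# minimal config for fast tests
quick_config <- function(...) {
  args <- list(...)
  defaults <- list(population_size = 10, ticks = 50,
                   initial_mix = c(TFT = 4, AllC = 2, TF2T = 2,
                                   Pavlov = 1, Probabilistic = 1))
  do.call(sim_config, utils::modifyList(defaults, args))
}

# synthetic trait_ts with prescribed cooperative/deceiver count series
synthetic_trait_ts <- function(coop_counts, dec_counts = NULL, n = 50) {
  ticks <- length(coop_counts)
  if (is.null(dec_counts)) dec_counts <- rep(0, ticks)
  stopifnot(all(dec_counts <= coop_counts | dec_counts <= n - coop_counts))
  df <- as.data.frame(matrix(0, ticks, 18))
  names(df) <- c("tick", deceptIPD:::trait_columns(), "mean_score",
                 "deception_successes", "deception_failures")
  df$tick <- seq_len(ticks) - 1
  # cooperative agents are TFT; deceivers drawn from the AllD pool
  df$count_TFT_plain <- coop_counts
  df$count_AllD_dec <- dec_counts
  df$count_AllD_plain <- n - coop_counts - dec_counts
  stopifnot(all(df$count_AllD_plain >= 0))
  structure(df, population_size = n, class = c("trait_ts", "data.frame"))
}
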