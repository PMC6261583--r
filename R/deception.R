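# The four deception operators and the four-case encounter protocol with
# cost accounting and counterfactual success scoring.

#' Construct an agent
#'
#' An agent carries a heritable genome (strategy, deception behaviour,
#' mutation probability), an experiential bounded memory and a cumulative
#' score. Newly created agents default to an empty memory and score 0.
#'
#' @param strategy One of \code{\link{strategy_levels}()}.
#' @param deception One of \code{\link{deception_levels}()}; \code{"None"}
#'   for a non-deceiving agent.
#' @param mutation_prob Per-locus mutation probability in [0, 1].
#' @param score Cumulative score.
#' @param memory An \code{\link{agent_memory}}.
#' @return An object of class \code{ipd_agent}.
#' @export
make_agent <- function(strategy, deception = "None", mutation_prob = 0.05,
                       score = 0, memory = agent_memory()) {
  strategy_code(strategy)
  deception_code(deception)
  stopifnot(mutation_prob >= 0, mutation_prob <= 1,
            inherits(memory, "agent_memory"))
  structure(list(strategy = strategy, deception = deception,
                 mutation_prob = mutation_prob, score = score,
                 memory = memory),
            class = "ipd_agent")
}

#' @export
print.ipd_agent <- function(x, ...) {
  cat(sprintf("<agent %s/%s mp=%.3f score=%.2f mem=[%s] own_last=%s>\n",
              x$strategy, x$deception, x$mutation_prob, x$score,
              paste(x$memory$opponent_moves, collapse = ","),
              if (is.null(x$memory$own_last)) "-" else x$memory$own_last))
  invisible(x)
}

agent_to_cpp <- function(a) {
  list(strategy = strategy_code(a$strategy),
       deception = deception_code(a$deception),
       mutation_prob = a$mutation_prob, score = a$score,
       memory = move_to_int(a$memory$opponent_moves),
       own_last = if (is.null(a$memory$own_last)) -1L
                  else move_to_int(a$memory$own_last))
}

agent_from_cpp <- function(al, memory_depth) {
  make_agent(strategy = strategy_levels()[al$strategy + 1L],
             deception = deception_levels()[al$deception + 1L],
             mutation_prob = al$mutation_prob, score = al$score,
             memory = agent_memory(
               if (length(al$memory)) int_to_move(al$memory) else character(0),
               own_last = if (al$own_last < 0) NULL else int_to_move(al$own_last),
               memory_depth = memory_depth))
}

#' Corruption operator on a victim memory
#'
#' Overwrites every remembered opponent Defect with a Cooperate, producing a
#' false belief that past opponents cooperated. Length and the victim's own
#' last move are unchanged; the operator is idempotent and never increases
#' the number of remembered defections.
#'
#' @param memory An \code{\link{agent_memory}}.
#' @return The corrupted \code{agent_memory}.
#' @examples
#' apply_corruption(agent_memory(c("D", "D", "C")))$opponent_moves # all "C"
#' @export
apply_corruption <- function(memory) {
  stopifnot(inherits(memory, "agent_memory"))
  memory$opponent_moves <-
    if (length(memory$opponent_moves))
      int_to_move(cpp_apply_corruption(move_to_int(memory$opponent_moves)))
    else character(0)
  memory
}

#' Degradation operator on a victim memory
#'
#' Replaces every remembered opponent move with an independent fair coin
#' flip between Cooperate and Defect, hiding the true history in noise.
#' Memory length is preserved. Uses R's RNG.
#'
#' @param memory An \code{\link{agent_memory}}.
#' @return The degraded \code{agent_memory}.
#' @export
apply_degradation <- function(memory) {
  stopifnot(inherits(memory, "agent_memory"))
  memory$opponent_moves <-
    if (length(memory$opponent_moves))
      int_to_move(cpp_apply_degradation(move_to_int(memory$opponent_moves)))
    else character(0)
  memory
}

#' Subversion operator on a victim agent
#'
#' Permanently sets the victim's (heritable) strategy to Always Cooperate,
#' altering its processing algorithm rather than its memory. Idempotent.
#'
#' @param agent An \code{\link{make_agent}} agent.
#' @return The subverted agent.
#' @export
apply_subversion <- function(agent) {
  stopifnot(inherits(agent, "ipd_agent"))
  agent$strategy <- "AllC"
  agent
}

#' Denial operator
#'
#' Denial disables the victim's information collection for a single round:
#' the attacker's move of the current round is not appended to the victim's
#' memory. The operator itself changes no state; it returns a suppression
#' flag consumed by the encounter protocol, which skips the memory append
#' for that round only.
#'
#' @param victim An \code{\link{make_agent}} agent (validated, unchanged).
#' @return \code{TRUE}, the observation-suppression flag for this round.
#' @export
apply_denial <- function(victim) {
  stopifnot(inherits(victim, "ipd_agent"))
  TRUE
}

#' Play one encounter between two agents
#'
#' One round of the PD under the four-case deception protocol:
#' \describe{
#'   \item{no deception}{both agents select moves from their true memories;
#'     gross payoffs are assigned and no cost is charged.}
#'   \item{one deceiver}{the victim's counterfactual move is computed from
#'     its unaltered memory and the resulting baseline payoffs saved; the
#'     deceiver's operator is then applied to the victim's stored state
#'     (edits persist beyond the round), the victim selects from the altered
#'     state, gross payoffs follow from the actual moves, the deceiver pays
#'     the cost, and the deception is recorded successful iff the deceiver's
#'     gross payoff strictly exceeds its baseline payoff.}
#'   \item{mutual deception}{baseline payoffs for both players are computed
#'     from the unaltered states and saved; both operators are applied
#'     simultaneously; both players then select from their altered states;
#'     both pay the cost; success is judged per player against the saved
#'     baseline.}
#' }
#' After payoff resolution each agent appends the opponent's actual move to
#' its memory (unless suppressed by Denial), records its own move, and adds
#' its net payoff to its cumulative score. The cost is charged on every game
#' a deceiver plays, successful or not.
#'
#' @param a,b Agents from \code{\link{make_agent}}.
#' @param m A \code{\link{payoff_matrix}}.
#' @param cost Deception cost in score units per game, charged to each
#'   deceiving player.
#' @param memory_depth Memory bound used when appending this round's move.
#' @return A list of class \code{encounter_result} with elements
#'   \code{moves} (named "a","b"), \code{payoffs} (net of cost),
#'   \code{gross}, \code{baseline} (counterfactual gross payoffs),
#'   \code{success} (logical, \code{NA} for a non-deceiving player) and the
#'   updated agents \code{a} and \code{b}.
#' @examples
#' set.seed(1)
#' tft <- make_agent("TFT", memory = agent_memory(c("C", "C", "D")))
#' att <- make_agent("AllD", "Corruption")
#' play_encounter(tft, att, cost = 0.1)$payoffs # victim 0, attacker 4.9
#' @export
play_encounter <- function(a, b, m = payoff_matrix(), cost = 0,
                           memory_depth = 3) {
  stopifnot(inherits(a, "ipd_agent"), inherits(b, "ipd_agent"), cost >= 0)
  r <- cpp_play_encounter(agent_to_cpp(a), agent_to_cpp(b), payoff_vec(m),
                          cost, memory_depth)
  structure(list(
    moves = c(a = int_to_move(r$move_a), b = int_to_move(r$move_b)),
    payoffs = c(a = r$payoff_a, b = r$payoff_b),
    gross = c(a = r$gross_a, b = r$gross_b),
    baseline = c(a = r$baseline_a, b = r$baseline_b),
    success = c(a = r$success_a, b = r$success_b),
    cost = c(a = if (a$deception != "None") cost else 0,
             b = if (b$deception != "None") cost else 0),
    a = agent_from_cpp(r$agent_a, memory_depth),
    b = agent_from_cpp(r$agent_b, memory_depth)),
    class = "encounter_result")
}

#' @export
print.encounter_result <- function(x, ...) {
  cat(sprintf("moves (%s,%s)  net payoffs (%.2f, %.2f)  success (%s, %s)\n",
              x$moves["a"], x$moves["b"], x$payoffs["a"], x$payoffs["b"],
              x$success["a"], x$success["b"]))
  invisible(x)
}
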