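# Prisoner's dilemma payoffs and the seven memory-driven strategy rules.

#' The seven IPD strategy names
#'
#' Closed enumeration, in the fixed order used throughout the package and in
#' run CSV columns: TFT, TF2T, Pavlov, AllC, AllD, Random, Probabilistic.
#'
#' @return Character vector of length 7.
#' @export
strategy_levels <- function() {
  c("TFT", "TF2T", "Pavlov", "AllC", "AllD", "Random", "Probabilistic")
}

#' The deception behaviour names
#'
#' Closed enumeration: "None" plus the four information-theoretic deception
#' operators. Degradation randomises the victim's remembered opponent moves;
#' Corruption rewrites remembered Defects as Cooperates; Denial suppresses
#' the victim's observation of the attacker's move for one round; Subversion
#' permanently sets the victim's strategy to Always Cooperate.
#'
#' @return Character vector of length 5.
#' @export
deception_levels <- function() {
  c("None", "Degradation", "Corruption", "Denial", "Subversion")
}

strategy_code <- function(strategy) {
  i <- match(strategy, strategy_levels())
  if (anyNA(i)) stop("unknown strategy: ", paste(strategy[is.na(i)], collapse = ", "))
  i - 1L
}

deception_code <- function(deception) {
  i <- match(deception, deception_levels())
  if (anyNA(i)) stop("unknown deception: ", paste(deception[is.na(i)], collapse = ", "))
  i - 1L
}

move_to_int <- function(moves) {
  if (is.null(moves) || length(moves) == 0) return(integer(0))
  i <- match(moves, c("C", "D"))
  if (anyNA(i)) stop("moves must be \"C\" or \"D\"")
  i - 1L
}

int_to_move <- function(x) c("C", "D")[x + 1L]

#' Construct a prisoner's dilemma payoff matrix
#'
#' Holds the Temptation, Reward, Punishment and Sucker payoffs. The defaults
#' are the classic non-negative NetLogo values (5, 3, 1, 0), which can be
#' remapped to donation-game parameters as T = b, R = b - c. The PD ordering
#' T > R > P > S is enforced, as is non-negativity of all four payoffs.
#'
#' @param T Temptation payoff (defector against a cooperator).
#' @param R Reward payoff (mutual cooperation).
#' @param P Punishment payoff (mutual defection).
#' @param S Sucker payoff (cooperator against a defector).
#' @return An object of class \code{payoff_matrix}.
#' @examples
#' payoff_matrix()
#' payoff_pair("D", "C", payoff_matrix()) # c(5, 0)
#' @export
payoff_matrix <- function(T = 5, R = 3, P = 1, S = 0) {
  stopifnot(is.numeric(T), is.numeric(R), is.numeric(P), is.numeric(S))
  if (!(T > R && R > P && P > S))
    stop("payoffs must satisfy T > R > P > S")
  if (S < 0) stop("payoffs must be non-negative")
  structure(list(T = T, R = R, P = P, S = S), class = "payoff_matrix")
}

#' @export
print.payoff_matrix <- function(x, ...) {
  cat(sprintf("PD payoffs: T=%g R=%g P=%g S=%g\n", x$T, x$R, x$P, x$S))
  invisible(x)
}

payoff_vec <- function(m) c(m$T, m$R, m$P, m$S)

#' Payoffs for one round of the prisoner's dilemma
#'
#' @param move_a,move_b Moves, \code{"C"} or \code{"D"}.
#' @param m A \code{\link{payoff_matrix}}.
#' @return Numeric vector \code{c(payoff_a, payoff_b)}: (T, S) for (D, C),
#'   (S, T) for (C, D), (R, R) for (C, C) and (P, P) for (D, D).
#' @export
payoff_pair <- function(move_a, move_b, m = payoff_matrix()) {
  a <- move_to_int(move_a)
  b <- move_to_int(move_b)
  stopifnot(length(a) == 1, length(b) == 1)
  if (a == 1 && b == 0) c(m$T, m$S)
  else if (a == 0 && b == 1) c(m$S, m$T)
  else if (a == 0 && b == 0) c(m$R, m$R)
  else c(m$P, m$P)
}

#' Construct an agent's bounded memory
#'
#' An agent remembers up to \code{memory_depth} opponent moves (most recent
#' last, identity-free: moves from different opponents are interleaved) and
#' its own last move. Appending to a full memory evicts the oldest entry.
#'
#' @param opponent_moves Character vector of \code{"C"}/\code{"D"}, most
#'   recent last; length at most \code{memory_depth}.
#' @param own_last Own previous move (\code{"C"}, \code{"D"}) or \code{NULL}.
#' @param memory_depth Maximum number of remembered opponent moves.
#' @return An object of class \code{agent_memory}.
#' @export
agent_memory <- function(opponent_moves = character(0), own_last = NULL,
                         memory_depth = 3) {
  if (length(opponent_moves) > memory_depth)
    stop("memory holds at most ", memory_depth, " opponent moves")
  move_to_int(opponent_moves)  # validates
  if (!is.null(own_last)) stopifnot(own_last %in% c("C", "D"))
  structure(list(opponent_moves = as.character(opponent_moves),
                 own_last = own_last, memory_depth = memory_depth),
            class = "agent_memory")
}

#' Select the next move of an IPD strategy
#'
#' Implements the seven strategy rules. AllC/AllD/Random ignore the memory;
#' TFT copies the most recent opponent move (cooperating when the memory is
#' empty); TF2T defects only when the two most recent opponent moves were
#' both defections; Pavlov plays win-stay/lose-shift (a "win" is having
#' received T or R last round, i.e. the opponent cooperated), cooperating
#' when it has no history; Probabilistic cooperates with probability equal
#' to the fraction of cooperations among the remembered opponent moves (1/2
#' when the memory is empty).
#'
#' Random and Probabilistic draw from R's RNG; set the seed for
#' reproducibility. The other five strategies are pure functions of
#' (strategy, memory).
#'
#' @param strategy One of \code{\link{strategy_levels}()}.
#' @param memory An \code{\link{agent_memory}}.
#' @return \code{"C"} or \code{"D"}.
#' @examples
#' select_move("TFT", agent_memory(c("C", "C", "D"))) # "D"
#' @export
select_move <- function(strategy, memory = agent_memory()) {
  stopifnot(inherits(memory, "agent_memory"))
  own <- if (is.null(memory$own_last)) -1L else move_to_int(memory$own_last)
  int_to_move(cpp_select_move(strategy_code(strategy),
                              move_to_int(memory$opponent_moves), own))
}
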