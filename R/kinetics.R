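# Kinetic schemes for receptors and transporters. Rates are data, not code:
# the defaults live in the registry functions below and can be modified
# before being handed to the simulator.

#' Construct a kinetic scheme
#'
#' A scheme is a connected set of named states with first-order transitions
#' (per ms) and glutamate-dependent binding transitions whose effective rate
#' is realised by the particle engine through encounter probabilities.
#'
#' @param name Scheme name.
#' @param states Character vector of state names.
#' @param transitions Data frame with columns `from`, `to`, `rate` (per ms;
#'   nominal on-rates per mM ms for glutamate-dependent steps) and
#'   `glu_dependent` (logical).
#' @param bound_states States in which a glutamate molecule is held.
#' @param open_states States counted as "open"/"captured" in summaries.
#' @export
kinetic_scheme <- function(name, states, transitions, bound_states,
                           open_states = character(0)) {
  stopifnot(is.data.frame(transitions),
            all(c("from", "to", "rate", "glu_dependent") %in%
                  names(transitions)))
  if (any(transitions$rate < 0, na.rm = TRUE))
    stop("scheme error: negative rate")
  if (!any(transitions$glu_dependent))
    stop("scheme error: scheme needs at least one glutamate-dependent transition")
  bad <- setdiff(c(transitions$from, transitions$to), states)
  if (length(bad))
    stop("scheme error: unknown state(s): ", paste(bad, collapse = ", "))
  # connectivity (undirected reachability from the first state)
  reach <- states[1]
  repeat {
    nxt <- unique(c(transitions$to[transitions$from %in% reach],
                    transitions$from[transitions$to %in% reach]))
    nxt <- setdiff(nxt, reach)
    if (!length(nxt)) break
    reach <- c(reach, nxt)
  }
  if (!setequal(reach, states))
    stop("scheme error: kinetic scheme is not connected")
  out <- list(name = name, states = states, transitions = transitions,
              bound_states = bound_states, open_states = open_states)
  class(out) <- "papsim_scheme"
  out
}

#' Default kinetic scheme registry
#'
#' Returns the two schemes used by the simulator:
#' \describe{
#'   \item{transporter}{a simplified 3-state glial transporter cycle,
#'     free -> bound -> translocated, with stochastic unbinding (bound ->
#'     free) dominant over translocation, so that transporters act largely as
#'     glutamate buffers on the millisecond scale.}
#'   \item{nmdar}{a reduced two-glutamate-binding NMDAR scheme
#'     C0 <-> C1 <-> C2 <-> O with compressed (fast-gating) rate constants
#'     appropriate for the few-millisecond simulation window.}
#' }
#' All rates are per ms (on-rates nominal per mM ms).
#'
#' @export
default_schemes <- function() {
  transporter <- kinetic_scheme(
    "transporter",
    states = c("free", "bound", "translocated"),
    transitions = data.frame(
      from = c("free", "bound", "bound"),
      to = c("bound", "free", "translocated"),
      rate = c(10, 3.0, 0.33),
      glu_dependent = c(TRUE, FALSE, FALSE)),
    bound_states = "bound")
  nmdar <- kinetic_scheme(
    "nmdar",
    states = c("C0", "C1", "C2", "O"),
    transitions = data.frame(
      from = c("C0", "C1", "C1", "C2", "C2", "O"),
      to = c("C1", "C2", "C0", "C1", "O", "C2"),
      rate = c(5, 5, 0.6, 1.2, 0.5, 0.25),
      glu_dependent = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)),
    bound_states = c("C1", "C2", "O"),
    open_states = "O")
  list(transporter = transporter, nmdar = nmdar)
}

# extract the named rates the engine consumes; errors if the scheme topology
# does not match the supported canonical forms
scheme_rates <- function(schemes) {
  tr <- schemes$transporter
  nm <- schemes$nmdar
  pick <- function(sch, from, to) {
    i <- which(sch$transitions$from == from & sch$transitions$to == to)
    if (length(i) != 1)
      stop("scheme error: expected transition ", from, " -> ", to,
           " in scheme '", sch$name, "'")
    sch$transitions$rate[i]
  }
  c(t_unbind = pick(tr, "bound", "free"),
    t_uptake = pick(tr, "bound", "translocated"),
    r_unbind1 = pick(nm, "C1", "C0"),
    r_unbind2 = pick(nm, "C2", "C1"),
    r_open = pick(nm, "C2", "O"),
    r_close = pick(nm, "O", "C2"))
}
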