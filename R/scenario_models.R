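# Builders for the three networks used in the database-search analysis:
# the island network (no database), the two-member database network
# (suspect + one other profile), and the general database network with an
# aggregate exclusion node, optionally extended by a binary summary node
# used for likelihood-ratio evaluation.
#
# Indexing convention throughout: person 1 is the suspect, persons 2..n are
# the other database members, persons n+1..N are outside the database.

#' Define a database-search scenario
#'
#' A scenario is the triple (N, n, gamma) plus an optional prior vector:
#' `N` potential sources of the crime stain, of whom `n` (including the
#' suspect, person 1) have profiles in the searched database, and a random
#' match probability `gamma` -- the probability that a person other than the
#' true source exhibits the crime-stain profile.
#'
#' @param N population of potential sources (integer >= 1).
#' @param n database size including the suspect (integer, 1 <= n <= N);
#'   default 1 (no one but the suspect typed, the island setting).
#' @param gamma random match probability in \[0, 1\].
#' @param priors optional numeric vector of length `N` of prior source
#'   probabilities (person i is the source); must be non-negative and sum
#'   to 1 within 1e-9. `NULL` (default) means the uniform prior 1/N.
#' @return an object of class `scenario`.
#' @export
#' @examples
#' scenario(N = 100, n = 2, gamma = 0.01)
scenario <- function(N, n = 1, gamma, priors = NULL) {
  if (!is.numeric(N) || length(N) != 1L || N < 1 || N != round(N)) {
    stop_bn("invalid_scenario", "N must be a single integer >= 1")
  }
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n) || n > N) {
    stop_bn("invalid_scenario", "n must be a single integer with 1 <= n <= N")
  }
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma < 0 || gamma > 1) {
    stop_bn("invalid_scenario", "gamma must be a probability in [0, 1]")
  }
  if (!is.null(priors)) {
    priors <- as.numeric(priors)
    if (length(priors) != N) {
      stop_bn("invalid_scenario", sprintf("priors must have length N = %d", N))
    }
    if (any(priors < 0)) stop_bn("invalid_scenario", "priors must be non-negative")
    if (abs(sum(priors) - 1) > 1e-9) stop_bn("invalid_scenario", "priors must sum to 1")
  }
  structure(list(N = as.integer(N), n = as.integer(n), gamma = gamma, priors = priors),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> N = %d, n = %d, gamma = %g, priors = %s\n",
              x$N, x$n, x$gamma,
              if (is.null(x$priors)) "uniform 1/N" else "custom"))
  invisible(x)
}

#' Prior source probabilities of a scenario
#'
#' @param sc a `scenario`.
#' @return numeric vector of length `N`; uniform 1/N when no explicit priors.
#' @export
scenario_priors <- function(sc) {
  if (is.null(sc$priors)) rep(1 / sc$N, sc$N) else sc$priors
}

# prior mass of the three proposition groups: suspect / other db / outside
grouped_priors <- function(sc) {
  pri <- scenario_priors(sc)
  c(suspect = pri[1],
    other_db = if (sc$n >= 2) sum(pri[2:sc$n]) else 0,
    outside = if (sc$n < sc$N) sum(pri[(sc$n + 1):sc$N]) else 0)
}

# exemplary numeric root-node states (as displayed in expanded node views),
# extended with the scenario's own value; point-mass prior on that value
numeric_root <- function(name, exemplary, value) {
  states <- as.character(sort(unique(c(exemplary, value))))
  bn_node(name, states,
          cpt = stats::setNames(as.numeric(states == as.character(value)), states))
}

#' Build the island-problem network
#'
#' One typed suspect in a closed population of `N` equally suspected
#' persons; no database. Node `H` holds the source proposition with states
#' `H1` ("the suspect is the source", prior `priors[1]`) and `H1_bar` ("one
#' of the other N-1 persons is"); node `M1` ("the suspect's profile
#' corresponds") matches with certainty under `H1` and with probability
#' `gamma` otherwise.
#'
#' @param sc a [scenario()]; `n` is ignored (no database in this model).
#' @param explicit_roots if `TRUE`, `N` and `gamma` are represented as
#'   discrete root nodes enumerating the exemplary values shown in expanded
#'   network views (N in 2, 10, 100, 1000; gamma in 0.01, 0.1) plus the
#'   scenario's own values, with a point-mass prior on the latter; if
#'   `FALSE` (default) the constants are folded into the CPTs. Both
#'   representations yield identical posteriors.
#' @return a `bn_network` with nodes `H` and `M1` (plus `N`, `gamma` when
#'   `explicit_roots = TRUE`).
#' @export
#' @examples
#' net <- build_island_network(scenario(N = 100, gamma = 0.01))
#' infer_posterior(net, "H", c(M1 = "match"))$probabilities[["H1"]]  # 0.5025
build_island_network <- function(sc, explicit_roots = FALSE) {
  stopifnot(inherits(sc, "scenario"))
  pi1 <- scenario_priors(sc)[1]
  m_states <- c("match", "no-match")
  if (!explicit_roots) {
    h <- bn_node("H", c("H1", "H1_bar"), cpt = c(pi1, 1 - pi1))
    m1 <- bn_node("M1", m_states, parents = "H",
                  cpt = list("H1" = c(1, 0),
                             "H1_bar" = c(sc$gamma, 1 - sc$gamma)))
    return(bn_network(h, m1))
  }
  n_node <- numeric_root("N", c(2, 10, 100, 1000), sc$N)
  g_node <- numeric_root("gamma", c(0.01, 0.1), sc$gamma)
  h_cpt <- lapply(stats::setNames(n_node$states, n_node$states), function(s) {
    p1 <- if (identical(s, as.character(sc$N))) pi1 else 1 / as.numeric(s)
    c(p1, 1 - p1)
  })
  h <- bn_node("H", c("H1", "H1_bar"), parents = "N", cpt = h_cpt)
  m_cpt <- list()
  for (hs in c("H1", "H1_bar")) {
    for (gs in g_node$states) {
      p <- if (hs == "H1") 1 else as.numeric(gs)
      m_cpt[[cpt_key(c(hs, gs))]] <- c(p, 1 - p)
    }
  }
  m1 <- bn_node("M1", m_states, parents = c("H", "gamma"), cpt = m_cpt)
  bn_network(n_node, g_node, h, m1)
}

#' Build the two-member database network
#'
#' The suspect and exactly one other person (individual 2) are in the
#' database. Node `H` has three states: `H1` (the suspect is the source),
#' `H2` (individual 2 is), and `H3_N` (the source is one of the N-2 persons
#' outside the database). Node `X2` represents the finding that individual
#' 2's profile does *not* correspond to the crime stain (state "no-match"
#' first), impossible under `H2` and of probability `1 - gamma` otherwise;
#' node `M1` is the suspect's correspondence.
#'
#' @inheritParams build_island_network
#' @param sc a [scenario()] with `n = 2` (anything else errors, pointing to
#'   [build_general_db_network()]).
#' @return a `bn_network` with nodes `H`, `M1`, `X2` (plus roots if
#'   requested).
#' @export
build_two_member_db_network <- function(sc, explicit_roots = FALSE) {
  stopifnot(inherits(sc, "scenario"))
  if (sc$n != 2L) {
    stop_bn("wrong_builder",
            "build_two_member_db_network requires n = 2; use build_general_db_network for other database sizes")
  }
  pri <- scenario_priors(sc)
  h_states <- c("H1", "H2", "H3_N")
  h_prior <- c(pri[1], pri[2], if (sc$N > 2) sum(pri[3:sc$N]) else 0)
  m_states <- c("match", "no-match")
  x_states <- c("no-match", "match")
  g <- sc$gamma

  if (!explicit_roots) {
    h <- bn_node("H", h_states, cpt = h_prior)
    m1 <- bn_node("M1", m_states, parents = "H",
                  cpt = list("H1" = c(1, 0),
                             "H2" = c(g, 1 - g),
                             "H3_N" = c(g, 1 - g)))
    x2 <- bn_node("X2", x_states, parents = "H",
                  cpt = list("H1" = c(1 - g, g),
                             "H2" = c(0, 1),
                             "H3_N" = c(1 - g, g)))
    return(bn_network(h, m1, x2))
  }
  n_node <- numeric_root("N", c(2, 10, 100, 1000), sc$N)
  g_node <- numeric_root("gamma", c(0.01, 0.1), sc$gamma)
  h_cpt <- lapply(stats::setNames(n_node$states, n_node$states), function(s) {
    nv <- as.numeric(s)
    if (identical(s, as.character(sc$N))) h_prior else c(1 / nv, 1 / nv, (nv - 2) / nv)
  })
  h <- bn_node("H", h_states, parents = "N", cpt = h_cpt)
  m_cpt <- list(); x_cpt <- list()
  for (hs in h_states) {
    for (gs in g_node$states) {
      gv <- as.numeric(gs)
      pm <- if (hs == "H1") 1 else gv
      m_cpt[[cpt_key(c(hs, gs))]] <- c(pm, 1 - pm)
      px <- if (hs == "H2") 0 else 1 - gv
      x_cpt[[cpt_key(c(hs, gs))]] <- c(px, 1 - px)
    }
  }
  m1 <- bn_node("M1", m_states, parents = c("H", "gamma"), cpt = m_cpt)
  x2 <- bn_node("X2", x_states, parents = c("H", "gamma"), cpt = x_cpt)
  bn_network(n_node, g_node, h, m1, x2)
}

#' Build the general database-search network
#'
#' Arbitrary database size `1 <= n <= N`. Node `H` has three states: `H1`
#' (the suspect is the source), `H2_n` (one of the other n-1 database
#' members is), and `Hn+1_N` (someone outside the database is). The n-1
#' individual exclusion findings are aggregated in one binary node
#' `X2_Xn` with states "no-match-all" (none of the other database members
#' corresponds) and "some-match":
#' `P(no-match-all | H1) = P(no-match-all | Hn+1_N) = (1 - gamma)^(n-1)` and
#' `P(no-match-all | H2_n) = 0`. With `n = 1` the exclusion node is vacuous
#' (the empty product makes "no-match-all" certain under every state).
#' When `n = N` the state `Hn+1_N` is retained with prior 0 so the CPT shape
#' does not depend on the scenario.
#'
#' @inheritParams build_island_network
#' @param sc a [scenario()].
#' @return a `bn_network` with nodes `H`, `M1`, `X2_Xn` (plus roots `N`,
#'   `n`, `gamma` when `explicit_roots = TRUE`).
#' @export
#' @examples
#' net <- build_general_db_network(scenario(N = 1000, n = 100, gamma = 0.01))
#' # exclusion evidence alone: posterior 1/(N - n + 1)
#' infer_posterior(net, "H", c(X2_Xn = "no-match-all"))$probabilities[["H1"]]
build_general_db_network <- function(sc, explicit_roots = FALSE) {
  stopifnot(inherits(sc, "scenario"))
  gp <- grouped_priors(sc)
  h_states <- c("H1", "H2_n", "Hn+1_N")
  m_states <- c("match", "no-match")
  x_states <- c("no-match-all", "some-match")
  g <- sc$gamma

  # P(no-match-all | H state) for database size nv at match rate gv
  x_nomatch <- function(hs, nv, gv) {
    if (nv <= 1) 1 else if (hs == "H2_n") 0 else (1 - gv)^(nv - 1)
  }

  if (!explicit_roots) {
    h <- bn_node("H", h_states, cpt = unname(gp))
    m1 <- bn_node("M1", m_states, parents = "H",
                  cpt = list("H1" = c(1, 0),
                             "H2_n" = c(g, 1 - g),
                             "Hn+1_N" = c(g, 1 - g)))
    x_cpt <- lapply(stats::setNames(h_states, h_states), function(hs) {
      p <- x_nomatch(hs, sc$n, g)
      c(p, 1 - p)
    })
    x <- bn_node("X2_Xn", x_states, parents = "H", cpt = x_cpt)
    return(bn_network(h, m1, x))
  }
  n_big <- numeric_root("N", c(2, 10, 100, 1000), sc$N)
  n_small <- numeric_root("n", c(2, 10, 100), sc$n)
  g_node <- numeric_root("gamma", c(0.01, 0.1), sc$gamma)
  h_cpt <- list()
  for (Ns in n_big$states) {
    for (ns in n_small$states) {
      Nv <- as.numeric(Ns); nv <- as.numeric(ns)
      h_cpt[[cpt_key(c(Ns, ns))]] <-
        if (nv > Nv) {
          rep(1 / 3, 3)  # unreachable combination; uniform keeps the CPT valid
        } else if (identical(Ns, as.character(sc$N)) && identical(ns, as.character(sc$n))) {
          unname(gp)
        } else {
          c(1 / Nv, (nv - 1) / Nv, (Nv - nv) / Nv)
        }
    }
  }
  h <- bn_node("H", h_states, parents = c("N", "n"), cpt = h_cpt)
  m_cpt <- list()
  for (hs in h_states) {
    for (gs in g_node$states) {
      p <- if (hs == "H1") 1 else as.numeric(gs)
      m_cpt[[cpt_key(c(hs, gs))]] <- c(p, 1 - p)
    }
  }
  m1 <- bn_node("M1", m_states, parents = c("H", "gamma"), cpt = m_cpt)
  x_cpt <- list()
  for (hs in h_states) {
    for (ns in n_small$states) {
      for (gs in g_node$states) {
        p <- x_nomatch(hs, as.numeric(ns), as.numeric(gs))
        x_cpt[[cpt_key(c(hs, ns, gs))]] <- c(p, 1 - p)
      }
    }
  }
  x <- bn_node("X2_Xn", x_states, parents = c("H", "n", "gamma"), cpt = x_cpt)
  bn_network(n_big, n_small, g_node, h, m1, x)
}

#' Attach the binary summary node used for likelihood-ratio evaluation
#'
#' Adds a deterministic child `H1` of `H` with states `H1` (the suspect is
#' the source) and `H1_bar` (someone else is -- inside or outside the
#' database), a purely logical regrouping of the states of `H`.
#' Conditioning on `H1 = "H1_bar"` redistributes the mass of `H`
#' proportionally over `H2_n` and `Hn+1_N`, which is how the numerator and
#' denominator of the database likelihood ratio are read off the exclusion
#' node.
#'
#' @param net a `bn_network` built by [build_general_db_network()].
#' @return the network with the summary node added.
#' @export
#' @examples
#' net <- attach_summary_node(
#'   build_general_db_network(scenario(N = 1000, n = 100, gamma = 0.01)))
#' # P(none of the other 99 match | suspect NOT the source) = 0.3331
#' probability_of_evidence(net, c(H1 = "H1_bar", X2_Xn = "no-match-all")) /
#'   probability_of_evidence(net, c(H1 = "H1_bar"))
attach_summary_node <- function(net) {
  stopifnot(inherits(net, "bn_network"))
  if ("H1" %in% node_names(net)) {
    stop_bn("summary_exists", "summary node 'H1' is already present in this network")
  }
  h <- net$nodes[["H"]]
  if (is.null(h) || !"H1" %in% h$states) {
    stop_bn("wrong_builder", "attach_summary_node expects a network with an 'H' node built by build_general_db_network")
  }
  cpt <- lapply(stats::setNames(h$states, h$states), function(hs) {
    if (hs == "H1") c(1, 0) else c(0, 1)
  })
  summary_node <- bn_node("H1", c("H1", "H1_bar"), parents = "H", cpt = cpt)
  bn_network(c(unname(net$nodes), list(summary_node)))
}
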