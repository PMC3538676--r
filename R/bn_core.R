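# Exact inference on small discrete Bayesian networks by full enumeration.
# Networks in this package have 3-6 nodes with 2-6 states each, so the joint
# is tiny and enumeration is both the contract and the implementation.

#' Signal a classed package error
#'
#' @param class condition subclass, e.g. "impossible_evidence".
#' @param message human-readable message.
#' @param ... further fields stored on the condition.
#' @noRd
stop_bn <- function(class, message, ...) {
  stop(errorCondition(message, ..., class = c(class, "bn_error")))
}

#' Key of a CPT column for a combination of parent states
#'
#' Parent state labels are joined with "|" in parent order; root nodes
#' (no parents) use the sentinel key ".".
#' @noRd
cpt_key <- function(parent_states) {
  if (length(parent_states) == 0L) "." else paste(parent_states, collapse = "|")
}

#' Create a discrete network node
#'
#' A node has a name, an ordered set of at least two state labels, an ordered
#' list of parent node names, and a conditional probability table (CPT) with
#' one probability vector over the node's states per combination of parent
#' states.
#'
#' @param name node name (single string).
#' @param states character vector of state labels (length >= 2), kept in the
#'   order given; posterior vectors are always reported keyed by these labels.
#' @param parents character vector of parent node names (may be empty).
#' @param cpt for a root node, a numeric probability vector over `states` (or
#'   a list with the single key `"."`); for a child node, a named list with
#'   one entry per combination of parent states, keyed by the "|"-joined
#'   parent state labels in parent order, each entry a probability vector
#'   over `states`. Vectors may be named by state or given in state order.
#' @return an object of class `bn_node`.
#' @seealso [bn_network()], [validate_network()]
#' @export
#' @examples
#' h <- bn_node("H", c("H1", "H1_bar"), cpt = c(0.01, 0.99))
#' m <- bn_node("M1", c("match", "no-match"), parents = "H",
#'              cpt = list("H1" = c(1, 0), "H1_bar" = c(0.01, 0.99)))
bn_node <- function(name, states, parents = character(), cpt) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  states <- as.character(states)
  parents <- as.character(parents)
  if (!is.list(cpt)) {
    if (length(parents) > 0L) {
      stop_bn("invalid_cpt", sprintf(
        "node '%s' has parents; its cpt must be a list keyed by parent state combinations", name))
    }
    cpt <- stats::setNames(list(cpt), ".")
  }
  cpt <- lapply(cpt, function(p) {
    p <- as.numeric(p)
    if (length(p) == length(states) && is.null(names(p))) names(p) <- states
    p
  })
  structure(list(name = name, states = states, parents = parents, cpt = cpt),
            class = "bn_node")
}

#' @export
print.bn_node <- function(x, ...) {
  cat(sprintf("<bn_node> %s {%s}", x$name, paste(x$states, collapse = ", ")))
  if (length(x$parents)) cat(" <- ", paste(x$parents, collapse = ", "), sep = "")
  cat("\n")
  invisible(x)
}

#' Assemble nodes into a Bayesian network
#'
#' @param ... `bn_node` objects, or a single list of them.
#' @return an object of class `bn_network`: a named list of nodes (edges are
#'   implied by the nodes' parent lists).
#' @export
bn_network <- function(...) {
  nodes <- list(...)
  if (length(nodes) == 1L && is.list(nodes[[1]]) && !inherits(nodes[[1]], "bn_node")) {
    nodes <- nodes[[1]]
  }
  for (nd in nodes) {
    if (!inherits(nd, "bn_node")) stop_bn("invalid_network", "all elements must be bn_node objects")
  }
  nms <- vapply(nodes, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop_bn("invalid_network",
            sprintf("duplicate node names: %s", paste(unique(nms[duplicated(nms)]), collapse = ", ")))
  }
  structure(list(nodes = stats::setNames(nodes, nms)), class = "bn_network")
}

#' @export
print.bn_network <- function(x, ...) {
  cat(sprintf("<bn_network> %d nodes\n", length(x$nodes)))
  for (nd in x$nodes) print(nd)
  invisible(x)
}

node_names <- function(net) names(net$nodes)

#' Validate evidence against a network
#'
#' Evidence is a named character vector mapping node names to observed state
#' labels, e.g. `c(M1 = "match", X2 = "no-match")`.
#'
#' @param net a `bn_network`.
#' @param ev named character vector of node = state assignments (at most one
#'   per node).
#' @return the validated evidence vector (invisibly unchanged).
#' @export
bn_evidence <- function(net, ev) {
  if (length(ev) == 0L) return(stats::setNames(character(0), character(0)))
  ev <- unlist(ev)
  storage.mode(ev) <- "character"
  if (is.null(names(ev)) || any(!nzchar(names(ev)))) {
    stop_bn("invalid_evidence", "evidence must be a named character vector")
  }
  if (anyDuplicated(names(ev))) {
    stop_bn("invalid_evidence", sprintf(
      "multiple assignments for node(s): %s",
      paste(unique(names(ev)[duplicated(names(ev))]), collapse = ", ")))
  }
  missing <- setdiff(names(ev), node_names(net))
  if (length(missing)) {
    stop_bn("invalid_evidence", sprintf("unknown node(s): %s", paste(missing, collapse = ", ")))
  }
  for (nm in names(ev)) {
    if (!ev[[nm]] %in% net$nodes[[nm]]$states) {
      stop_bn("invalid_evidence", sprintf(
        "'%s' is not a state of node '%s' (states: %s)",
        ev[[nm]], nm, paste(net$nodes[[nm]]$states, collapse = ", ")))
    }
  }
  ev
}

#' Check a network against its structural invariants
#'
#' Diagnostic: runs every node- and graph-level invariant and reports one
#' violation record per failure, rather than stopping at the first.
#' Checked are: parent references resolve; the graph is acyclic; each CPT
#' covers exactly the Cartesian product of its parents' states (no missing or
#' duplicate combinations); every probability vector has one entry per state,
#' all entries in \[0, 1\], and sums to 1 within `tol`.
#'
#' @param net a `bn_network`.
#' @param tol normalization tolerance for CPT columns (default 1e-9).
#' @return a data frame with columns `node`, `context` (the offending parent
#'   combination or ""), and `defect`; zero rows iff the network is valid.
#' @export
validate_network <- function(net, tol = 1e-9) {
  out <- list()
  flag <- function(node, context, defect) {
    out[[length(out) + 1L]] <<- data.frame(node = node, context = context,
                                           defect = defect, stringsAsFactors = FALSE)
  }
  nms <- node_names(net)

  for (nd in net$nodes) {
    if (length(nd$states) < 2L) flag(nd$name, "", "fewer than 2 states")
    bad_parents <- setdiff(nd$parents, nms)
    for (p in bad_parents) flag(nd$name, p, "unresolved parent reference")
    if (length(bad_parents)) next

    expected <- if (length(nd$parents) == 0L) "." else {
      grid <- do.call(expand.grid, c(lapply(net$nodes[nd$parents], `[[`, "states"),
                                     list(stringsAsFactors = FALSE)))
      apply(grid, 1L, paste, collapse = "|")
    }
    have <- names(nd$cpt)
    for (k in setdiff(expected, have)) flag(nd$name, k, "missing parent combination")
    for (k in setdiff(have, expected)) flag(nd$name, k, "unexpected parent combination")
    if (anyDuplicated(have)) {
      for (k in unique(have[duplicated(have)])) flag(nd$name, k, "duplicate parent combination")
    }
    for (k in intersect(have, expected)) {
      p <- nd$cpt[[k]]
      if (length(p) != length(nd$states)) {
        flag(nd$name, k, "probability vector length does not match number of states")
        next
      }
      if (!is.null(names(p)) && !identical(sort(names(p)), sort(nd$states))) {
        flag(nd$name, k, "probability vector names do not match states")
        next
      }
      if (any(p < -tol | p > 1 + tol)) flag(nd$name, k, "entry outside [0, 1]")
      if (abs(sum(p) - 1) > tol) flag(nd$name, k, "column not normalized")
    }
  }

  # acyclicity by Kahn's algorithm over the parent lists
  ok_parents <- vapply(net$nodes, function(nd) all(nd$parents %in% nms), logical(1))
  if (all(ok_parents)) {
    remaining <- nms
    repeat {
      roots <- remaining[vapply(remaining, function(nm) {
        length(intersect(net$nodes[[nm]]$parents, remaining)) == 0L
      }, logical(1))]
      if (length(roots) == 0L) break
      remaining <- setdiff(remaining, roots)
    }
    if (length(remaining)) {
      flag(paste(remaining, collapse = ","), "", "cycle among these nodes")
    }
  }

  if (length(out) == 0L) {
    data.frame(node = character(0), context = character(0), defect = character(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, out)
  }
}

cpt_lookup <- function(net, node_name, assignment) {
  nd <- net$nodes[[node_name]]
  key <- cpt_key(unname(assignment[nd$parents]))
  p <- nd$cpt[[key]]
  if (is.null(p)) {
    stop_bn("invalid_cpt", sprintf("node '%s': no CPT column for parent combination '%s'",
                                   node_name, key))
  }
  unname(p[[assignment[[node_name]]]])
}

#' Joint probability of a full assignment
#'
#' Chain-rule factorization: the product over nodes of
#' `P(node = state | parents' states)` read from the CPTs.
#'
#' @param net a `bn_network`.
#' @param assignment named character vector assigning exactly one state to
#'   every node of the network.
#' @return a single probability.
#' @export
#' @examples
#' net <- build_island_network(scenario(N = 100, gamma = 0.01))
#' joint_probability(net, c(H = "H1", M1 = "match"))       # 0.01
#' joint_probability(net, c(H = "H1_bar", M1 = "match"))   # 0.0099
joint_probability <- function(net, assignment) {
  assignment <- bn_evidence(net, assignment)
  unassigned <- setdiff(node_names(net), names(assignment))
  if (length(unassigned)) {
    stop_bn("incomplete_assignment", sprintf(
      "joint_probability requires a full assignment; missing: %s",
      paste(unassigned, collapse = ", ")))
  }
  prod(vapply(node_names(net), cpt_lookup, numeric(1), net = net, assignment = assignment))
}

# all completions of ev as a data.frame of full assignments (one row each)
completion_grid <- function(net, ev) {
  free <- setdiff(node_names(net), names(ev))
  if (length(free) == 0L) {
    return(as.data.frame(as.list(ev), stringsAsFactors = FALSE))
  }
  grid <- do.call(expand.grid, c(lapply(net$nodes[free], `[[`, "states"),
                                 list(stringsAsFactors = FALSE)))
  for (nm in names(ev)) grid[[nm]] <- ev[[nm]]
  grid
}

#' Marginal probability of evidence
#'
#' Sums [joint_probability()] over every completion of the unobserved nodes.
#' Returns 1 for empty evidence and 0 for impossible (but well-formed)
#' evidence.
#'
#' @inheritParams bn_evidence
#' @return a probability in \[0, 1\].
#' @export
#' @examples
#' net <- build_two_member_db_network(scenario(N = 3, n = 2, gamma = 0.01))
#' probability_of_evidence(net, c(M1 = "match"))     # 1/3 + 2/3 * 0.01 = 0.34
#' probability_of_evidence(net, c(X2 = "no-match"))  # 2/3 * 0.99 = 0.66
probability_of_evidence <- function(net, ev) {
  ev <- bn_evidence(net, ev)
  grid <- completion_grid(net, ev)
  nms <- node_names(net)
  total <- 0
  for (r in seq_len(nrow(grid))) {
    a <- stats::setNames(as.character(grid[r, nms]), nms)
    total <- total + prod(vapply(nms, cpt_lookup, numeric(1), net = net, assignment = a))
  }
  total
}

#' Construct a posterior/marginal distribution object
#' @noRd
bn_distribution <- function(variable, probabilities) {
  structure(list(variable = variable, probabilities = probabilities),
            class = "bn_distribution")
}

#' @export
print.bn_distribution <- function(x, digits = 4, ...) {
  cat(sprintf("<distribution over %s>\n", x$variable))
  print(round(x$probabilities, digits))
  invisible(x)
}

#' Posterior distribution of a query node given evidence
#'
#' Exact conditioning by enumeration: for each state s of the query node,
#' `P(query = s | ev) = P(ev & query = s) / P(ev)`.
#'
#' @param net a `bn_network`.
#' @param query name of the node whose posterior is wanted.
#' @param ev named character vector of observed node = state assignments
#'   (may be empty, giving the query's marginal prior).
#' @return a `bn_distribution`: list with `variable` and a `probabilities`
#'   vector keyed by the query node's state labels (in insertion order).
#' @export
#' @examples
#' net <- build_island_network(scenario(N = 100, gamma = 0.01))
#' infer_posterior(net, "H", c(M1 = "match"))$probabilities[["H1"]]  # 0.5025
infer_posterior <- function(net, query, ev = character()) {
  ev <- bn_evidence(net, ev)
  if (!query %in% node_names(net)) {
    stop_bn("invalid_evidence", sprintf("unknown query node '%s'", query))
  }
  p_ev <- probability_of_evidence(net, ev)
  if (p_ev <= 0) {
    stop_bn("impossible_evidence", sprintf(
      "evidence has probability zero: {%s}",
      paste(sprintf("%s=%s", names(ev), ev), collapse = ", ")),
      assignments = ev)
  }
  states <- net$nodes[[query]]$states
  probs <- vapply(states, function(s) {
    if (query %in% names(ev)) {
      if (identical(ev[[query]], s)) p_ev else 0
    } else {
      probability_of_evidence(net, c(ev, stats::setNames(s, query)))
    }
  }, numeric(1))
  bn_distribution(query, probs / p_ev)
}

#' Sequential (stepwise) posterior updating
#'
#' Applies an ordered sequence of evidence batches cumulatively and returns
#' the posterior of the query node after each prefix. Conditioning is order
#' invariant, so the final distribution equals [infer_posterior()] with all
#' evidence supplied at once.
#'
#' @param net a `bn_network`.
#' @param query name of the query node.
#' @param evidence_sequence list of evidence batches (each a named character
#'   vector); batches must not reassign a node to a different state.
#' @return a list of `bn_distribution`, one per cumulative prefix.
#' @export
#' @examples
#' net <- build_two_member_db_network(scenario(N = 3, n = 2, gamma = 0.01))
#' steps <- sequential_update(net, "H",
#'                            list(c(X2 = "no-match"), c(M1 = "match")))
#' steps[[1]]$probabilities[["H1"]]  # 0.5
#' steps[[2]]$probabilities[["H1"]]  # 0.990099
sequential_update <- function(net, query, evidence_sequence) {
  stopifnot(is.list(evidence_sequence))
  cumulative <- stats::setNames(character(0), character(0))
  out <- vector("list", length(evidence_sequence))
  for (i in seq_along(evidence_sequence)) {
    batch <- bn_evidence(net, evidence_sequence[[i]])
    overlap <- intersect(names(batch), names(cumulative))
    conflicting <- overlap[cumulative[overlap] != batch[overlap]]
    if (length(conflicting)) {
      stop_bn("conflicting_evidence", sprintf(
        "node(s) %s reassigned to a different state", paste(conflicting, collapse = ", ")))
    }
    cumulative <- c(cumulative, batch[setdiff(names(batch), names(cumulative))])
    out[[i]] <- infer_posterior(net, query, cumulative)
  }
  out
}

#' Serialize a network to JSON
#'
#' The document is `{"nodes": [{name, states, parents, cpt}, ...]}` with each
#' CPT an object keyed by the "|"-joined parent state labels (root nodes use
#' the key "."), mapping to arrays of probabilities in state order.
#' Probabilities are written with 17 significant digits so the round-trip via
#' [network_from_json()] is lossless.
#'
#' @param net a `bn_network`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return `path` invisibly, or the JSON string when `path` is `NULL`.
#' @export
network_to_json <- function(net, path = NULL) {
  doc <- list(nodes = lapply(unname(net$nodes), function(nd) {
    list(name = jsonlite::unbox(nd$name),
         states = nd$states,
         parents = nd$parents,
         cpt = lapply(nd$cpt, unname))
  }))
  txt <- jsonlite::toJSON(doc, digits = I(17), auto_unbox = FALSE, pretty = TRUE)
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path)
  invisible(path)
}

#' Deserialize a network from JSON
#'
#' @param x a file path or a JSON string produced by [network_to_json()].
#' @return a `bn_network`.
#' @export
network_from_json <- function(x) {
  doc <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  nodes <- lapply(doc$nodes, function(nd) {
    bn_node(name = nd$name,
            states = unlist(nd$states),
            parents = as.character(unlist(nd$parents)),
            cpt = lapply(nd$cpt, unlist))
  })
  bn_network(nodes)
}
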