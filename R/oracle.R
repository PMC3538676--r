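# Individual-level brute-force reference. Every person i in 1..N is a
# distinct source hypothesis and every typed (database) member j in 1..n
# gets an explicit match/no-match outcome bit; the full joint over
# (source, outcomes) is tabulated and any posterior is obtained by
# summation. Outcomes of untyped persons (n+1..N) are never observed and
# marginalize out exactly, so they are not enumerated: the table has
# N * 2^n rows. This validates the grouped 3-state networks and every
# closed form on small instances.

#' Enumerate the full individual-level joint table
#'
#' Row probability for source i and outcome vector (m_1, ..., m_n):
#' `priors[i] * prod_j P(m_j | source = i)` with
#' `P(match_j | source = j) = 1` and `P(match_j | source != j) = gamma`.
#' In particular every row in which a database member is the source but
#' fails to match itself has probability 0.
#'
#' @param sc a [scenario()].
#' @param cap guard on problem size: errors if `N > cap` or `n > cap`
#'   (default 12, i.e. at most `12 * 2^12` rows); raise deliberately for
#'   larger exact checks.
#' @return a data frame of class `joint_table` with columns `source`
#'   (integer 1..N), `m1` ... `mn` (each "match"/"no-match") and
#'   `probability`; rows sum to 1. The scenario is attached as
#'   `attr(, "scenario")`.
#' @export
#' @examples
#' jt <- enumerate_joint(scenario(N = 3, n = 2, gamma = 0.01))
#' sum(jt$probability)  # 1
enumerate_joint <- function(sc, cap = 12) {
  stopifnot(inherits(sc, "scenario"))
  if (sc$N > cap || sc$n > cap) {
    stop_bn("size", sprintf(
      "N = %d, n = %d exceeds the enumeration cap (%d); use the grouped network model or raise `cap`",
      sc$N, sc$n, cap))
  }
  pri <- scenario_priors(sc)
  g <- sc$gamma
  outcomes <- do.call(expand.grid, c(rep(list(c("match", "no-match")), sc$n),
                                     list(stringsAsFactors = FALSE)))
  names(outcomes) <- paste0("m", seq_len(sc$n))
  is_match <- as.matrix(outcomes) == "match"

  rows <- lapply(seq_len(sc$N), function(i) {
    if (i <= sc$n) {
      others <- is_match[, -i, drop = FALSE]
      k <- rowSums(others)
      p <- pri[i] * ifelse(is_match[, i], 1, 0) * g^k * (1 - g)^(ncol(others) - k)
    } else {
      k <- rowSums(is_match)
      p <- pri[i] * g^k * (1 - g)^(sc$n - k)
    }
    cbind(data.frame(source = i), outcomes, data.frame(probability = p))
  })
  jt <- do.call(rbind, rows)
  rownames(jt) <- NULL
  attr(jt, "scenario") <- sc
  class(jt) <- c("joint_table", class(jt))
  jt
}

#' Exact posterior over individuals from the joint table
#'
#' Conditions the enumerated joint on observed match outcomes and returns
#' the posterior over the source index 1..N. Aggregating indices \{1\},
#' \{2..n\} and \{n+1..N\} reproduces the grouped network's `H`
#' distribution.
#'
#' @param jt a `joint_table` from [enumerate_joint()].
#' @param ev named character vector over outcome columns, e.g.
#'   `c(m1 = "match", m2 = "no-match")`; may be empty (prior recovery).
#' @return a `bn_distribution` over `"source"` with states `"1"` ... `"N"`.
#' @export
#' @examples
#' jt <- enumerate_joint(scenario(N = 3, n = 2, gamma = 0.01))
#' oracle_posterior(jt, c(m1 = "match", m2 = "no-match"))$probabilities[["1"]]
#' # 0.990099
oracle_posterior <- function(jt, ev = character()) {
  stopifnot(inherits(jt, "joint_table"))
  ev <- unlist(ev)
  if (length(ev)) {
    storage.mode(ev) <- "character"
    bad <- setdiff(names(ev), grep("^m[0-9]+$", names(jt), value = TRUE))
    if (length(bad)) {
      stop_bn("invalid_evidence", sprintf("unknown outcome column(s): %s", paste(bad, collapse = ", ")))
    }
    keep <- rep(TRUE, nrow(jt))
    for (nm in names(ev)) keep <- keep & (jt[[nm]] == ev[[nm]])
    jt <- jt[keep, , drop = FALSE]
  }
  p_ev <- sum(jt$probability)
  if (p_ev <= 0) {
    stop_bn("impossible_evidence", sprintf(
      "evidence has probability zero: {%s}",
      paste(sprintf("%s=%s", names(ev), ev), collapse = ", ")))
  }
  sc <- attr(jt, "scenario")
  mass <- vapply(seq_len(sc$N), function(i) sum(jt$probability[jt$source == i]), numeric(1))
  bn_distribution("source", stats::setNames(mass / p_ev, as.character(seq_len(sc$N))))
}

#' Aggregate an individual-level posterior into the three H propositions
#'
#' @param dist a `bn_distribution` over `"source"` from [oracle_posterior()].
#' @param n database size used for the grouping.
#' @return a named numeric vector `c(H1, H2_n, "Hn+1_N")`.
#' @export
aggregate_posterior <- function(dist, n) {
  stopifnot(inherits(dist, "bn_distribution"), identical(dist$variable, "source"))
  p <- dist$probabilities
  N <- length(p)
  c("H1" = unname(p[1]),
    "H2_n" = if (n >= 2) sum(p[2:n]) else 0,
    "Hn+1_N" = if (n < N) sum(p[(n + 1):N]) else 0)
}

#' Export a joint table to CSV
#'
#' Plain CSV with columns `source`, the outcome bits `m1..mn`, and
#' `probability`, for external inspection.
#'
#' @param jt a `joint_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_joint_table <- function(jt, path) {
  stopifnot(inherits(jt, "joint_table"))
  utils::write.csv(as.data.frame(jt)[, , drop = FALSE], path, row.names = FALSE)
  invisible(path)
}
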