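# Closed-form posterior and likelihood-ratio calculators. These implement
# the algebraic solutions directly and serve as an independent check on the
# network builders (and vice versa): cli_io::run_analysis() always computes
# both routes and compares them.

posterior_report <- function(sc, evidence_label, suspect, other_db, outside) {
  structure(list(scenario = sc, evidence_label = evidence_label,
                 posterior_suspect = suspect, posterior_other_db = other_db,
                 posterior_outside = outside),
            class = "posterior_report")
}

#' @export
print.posterior_report <- function(x, digits = 4, ...) {
  cat(sprintf("<posterior_report> evidence {%s}\n", x$evidence_label))
  cat(sprintf("  P(suspect is source)        = %s\n", format(round(x$posterior_suspect, digits))))
  cat(sprintf("  P(other database member is) = %s\n", format(round(x$posterior_other_db, digits))))
  cat(sprintf("  P(someone outside is)       = %s\n", format(round(x$posterior_outside, digits))))
  invisible(x)
}

#' Island-problem posterior: suspect's match only
#'
#' The posterior probability that the suspect is the source of the crime
#' stain given only the correspondence of his profile:
#' `P(H1 | M1) = pi1 / (pi1 + gamma * (1 - pi1))`, where `pi1` is the
#' suspect's prior source probability. The suspect is assumed to match with
#' certainty if he is the source.
#'
#' @param sc a [scenario()]; `n` plays no role here.
#' @return a `posterior_report` with `posterior_suspect`,
#'   `posterior_other_db` (always 0: no exclusion evidence is used) and
#'   `posterior_outside`.
#' @export
#' @examples
#' island_posterior(scenario(N = 100, gamma = 0.01))$posterior_suspect  # 0.5025
island_posterior <- function(sc) {
  stopifnot(inherits(sc, "scenario"))
  pi1 <- scenario_priors(sc)[1]
  denom <- pi1 + sc$gamma * (1 - pi1)
  if (denom <= 0) {
    stop_bn("impossible_evidence",
            "a match has probability zero when the suspect's prior is 0 and gamma = 0")
  }
  ps <- pi1 / denom
  posterior_report(sc, "M1", ps, 0, 1 - ps)
}

#' Database-search posterior: match plus exclusions
#'
#' Posterior for the suspect given the full database-search evidence (the
#' suspect matches; the other n-1 database members do not):
#' `P(H1 | E_n) = pi1 / (pi1 + gamma * sum(priors[(n+1):N]))`. The common
#' factor `(1 - gamma)^(n-1)` cancels between numerator and denominator, so
#' the result depends on `gamma` only through the remaining unexcluded
#' alternatives outside the database; the other database members carry zero
#' posterior mass (their exclusion is certain evidence against them).
#'
#' @param sc a [scenario()].
#' @return a `posterior_report` with `posterior_other_db = 0`.
#' @export
#' @examples
#' db_posterior(scenario(N = 100, n = 2, gamma = 0.01))$posterior_suspect  # 0.5051
#' db_posterior(scenario(N = 3, n = 2, gamma = 0.01))$posterior_suspect    # 0.990099
db_posterior <- function(sc) {
  stopifnot(inherits(sc, "scenario"))
  gp <- grouped_priors(sc)
  denom <- gp[["suspect"]] + sc$gamma * gp[["outside"]]
  if (denom <= 0) {
    stop_bn("impossible_evidence",
            "the database-search evidence has probability zero under this scenario")
  }
  ps <- gp[["suspect"]] / denom
  posterior_report(sc, "M1, X2..Xn", ps, 0, 1 - ps)
}

#' Exclusion-only posterior
#'
#' Posterior for the suspect given only that the other n-1 database members
#' are excluded (nothing yet about the suspect's own profile). The excluded
#' members' prior mass is redistributed proportionally over the survivors
#' (the suspect and the N-n persons outside the database); with uniform
#' priors this is `1 / (N - n + 1)`.
#'
#' @param sc a [scenario()].
#' @return a `posterior_report`.
#' @export
#' @examples
#' exclusion_posterior(scenario(N = 3, n = 2, gamma = 0.01))$posterior_suspect   # 0.5
#' exclusion_posterior(scenario(N = 1000, n = 100, gamma = 0.01))$posterior_suspect  # 1/901
exclusion_posterior <- function(sc) {
  stopifnot(inherits(sc, "scenario"))
  gp <- grouped_priors(sc)
  denom <- gp[["suspect"]] + gp[["outside"]]
  if (denom <= 0) {
    stop_bn("impossible_evidence",
            "excluding all database members leaves no possible source (suspect and outsiders have zero prior)")
  }
  ps <- gp[["suspect"]] / denom
  posterior_report(sc, "X2..Xn", ps, 0, 1 - ps)
}

#' Predictive (pre-posterior) probabilities of the evidence items
#'
#' Marginal and conditional probabilities of the two evidence items before
#' they are observed, by extension of the conversation over the source
#' propositions:
#' \describe{
#'   \item{p_match}{`P(M1)`, the suspect's profile corresponds.}
#'   \item{p_exclusion}{`P(X2..Xn)`, none of the other n-1 database members
#'     corresponds (for `n = 2` this is `P(X2)`).}
#'   \item{p_exclusion_given_match}{`P(X2..Xn | M1)`.}
#'   \item{p_match_given_exclusion}{`P(M1 | X2..Xn)`.}
#' }
#'
#' @param sc a [scenario()].
#' @return a named list of the four probabilities.
#' @export
#' @examples
#' p <- predictive_probabilities(scenario(N = 3, n = 2, gamma = 0.01))
#' p$p_match                  # 1/3 + 2/3 * 0.01 = 0.34
#' p$p_exclusion              # 2/3 * 0.99 = 0.66
#' p$p_match_given_exclusion  # 0.505
predictive_probabilities <- function(sc) {
  stopifnot(inherits(sc, "scenario"))
  gp <- grouped_priors(sc)
  g <- sc$gamma
  excl1 <- (1 - g)^(sc$n - 1)                       # P(X2..Xn | H1) = P(.. | outside)
  p_match <- gp[["suspect"]] + g * (1 - gp[["suspect"]])
  p_excl <- excl1 * (gp[["suspect"]] + gp[["outside"]])
  p_joint <- excl1 * (gp[["suspect"]] + g * gp[["outside"]])
  if (p_match <= 0 || p_excl <= 0) {
    stop_bn("undefined_conditional",
            "a conditioning event has probability zero under this scenario")
  }
  list(p_match = p_match,
       p_exclusion = p_excl,
       p_exclusion_given_match = p_joint / p_match,
       p_match_given_exclusion = p_joint / p_excl)
}

#' Database-search likelihood ratio
#'
#' The Bayes factor for the exclusion evidence (none of the other n-1
#' database members corresponds) comparing "the suspect is the source"
#' against "someone else is":
#' numerator `P(X2..Xn | H1) = (1 - gamma)^(n-1)`; denominator
#' `P(X2..Xn | not H1)`, which for uniform priors is
#' `(1 - gamma)^(n-1) * (N - n) / (N - 1)`. The ratio therefore reduces to
#' `(N - 1) / (N - n)`: it does not depend on `gamma`, only on how much of
#' the population the database covers. With `n = 1` there are no exclusions
#' and the ratio is 1; with `n = N` every alternative is excluded, the
#' denominator is 0 and the ratio is reported as unbounded
#' (`finite = FALSE`, `ratio = Inf`) rather than as an error, since this is
#' the meaningful limiting case.
#'
#' @param sc a [scenario()] with `N >= 2` (with a single person there is no
#'   alternative proposition to compare).
#' @return an `lr_report`: list with `scenario`, `numerator`, `denominator`,
#'   `ratio` and logical `finite`.
#' @export
#' @examples
#' lr <- db_likelihood_ratio(scenario(N = 1000, n = 100, gamma = 0.01))
#' round(lr$numerator, 4)    # 0.3697
#' round(lr$denominator, 4)  # 0.3331
#' lr$ratio                  # 999/900
db_likelihood_ratio <- function(sc) {
  stopifnot(inherits(sc, "scenario"))
  if (sc$N < 2) {
    stop_bn("invalid_scenario",
            "the likelihood ratio compares H1 against at least one alternative; need N >= 2")
  }
  gp <- grouped_priors(sc)
  alt <- gp[["other_db"]] + gp[["outside"]]     # prior mass of "not the suspect"
  numerator <- (1 - sc$gamma)^(sc$n - 1)
  denominator <- if (alt > 0) numerator * gp[["outside"]] / alt else 0
  finite <- denominator > 0
  ratio <- if (finite) numerator / denominator else Inf
  structure(list(scenario = sc, numerator = numerator, denominator = denominator,
                 ratio = ratio, finite = finite),
            class = "lr_report")
}

#' @export
print.lr_report <- function(x, digits = 4, ...) {
  cat("<lr_report> database-search likelihood ratio\n")
  cat(sprintf("  numerator   P(X2..Xn | H1)     = %s\n", format(round(x$numerator, digits))))
  cat(sprintf("  denominator P(X2..Xn | not H1) = %s\n", format(round(x$denominator, digits))))
  cat(sprintf("  ratio = %s%s\n",
              if (x$finite) format(round(x$ratio, digits)) else "Inf",
              if (x$finite) "" else " (all alternatives excluded: unbounded)"))
  invisible(x)
}
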