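# Shared fixtures: the worked scenarios and a grouped-vs-oracle comparator.

sc_island100 <- function() scenario(N = 100, gamma = 0.01)
sc_pair100 <- function() scenario(N = 100, n = 2, gamma = 0.01)
sc_three <- function() scenario(N = 3, n = 2, gamma = 0.01)
sc_big_db <- function() scenario(N = 1000, n = 100, gamma = 0.01)

# grouped H posterior of the general network vs the aggregated full-joint
# oracle, under matching evidence; returns max absolute discrepancy
grouped_vs_oracle <- function(sc, suspect_matches = TRUE, others_excluded = TRUE) {
  net <- build_general_db_network(sc)
  jt <- enumerate_joint(sc)
  ev_net <- character(0)
  ev_jt <- character(0)
  if (suspect_matches) {
    ev_net <- c(ev_net, M1 = "match")
    ev_jt <- c(ev_jt, m1 = "match")
  }
  if (others_excluded && sc$n >= 2) {
    ev_net <- c(ev_net, X2_Xn = "no-match-all")
    ev_jt <- c(ev_jt, stats::setNames(rep("no-match", sc$n - 1), paste0("m", 2:sc$n)))
  }
  grouped <- infer_posterior(net, "H", ev_net)$probabilities
  oracle <- aggregate_posterior(oracle_posterior(jt, ev_jt), sc$n)
  max(abs(grouped - oracle))
}
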