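# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and stats::p.adjust / stats::phyper), so each
# check compares two separately derived routes.

# Benjamini-Hochberg step-up, written out as the textbook procedure.
bh_step_up <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, p[o[i]] * m / i)
    adj[o[i]] <- running
  }
  adj
}

# Upper-tail hypergeometric by exhaustive enumeration of overlap outcomes.
hyper_upper_brute <- function(k, K, n, N) {
  top <- min(K, n)
  if (k > top) return(0)
  j <- k:top
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Product-limit estimator written out by hand over distinct event times.
km_by_hand <- function(time, event, at) {
  s <- 1
  for (t in sort(unique(time[event == 1]))) {
    if (t > at) break
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_risk)
  }
  s
}

# AUC by brute-force pairwise counting (ties count one half).
auc_brute <- function(cases, controls) {
  s <- 0
  for (a in cases) for (b in controls) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(cases) * length(controls))
}

# Small expression_matrix from explicit rows (3 vs 3 design).
tiny_em <- function(rows, biotype) {
  m <- do.call(rbind, rows)
  colnames(m) <- paste0("S", seq_len(ncol(m)))
  expression_matrix(m,
                    design = factor(rep(c("sensitive", "resistant"),
                                        each = ncol(m) / 2),
                                    levels = c("sensitive", "resistant")),
                    biotype = biotype)
}
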