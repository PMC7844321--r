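# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (double loops, full enumeration) so they cannot share
# a defect with the vectorized implementations they check.

# out-degree of one miRNA by direct edge scanning
oracle_ntg <- function(net, mirna) {
  length(which(net$edges$mirna == mirna))
}

# single-line regulations: loop over the miRNA's targets, counting each
# target's full in-degree by scanning the edge list again
oracle_nsr <- function(net, mirna) {
  targets <- net$edges$mrna[net$edges$mirna == mirna]
  n <- 0L
  for (g in targets)
    if (length(which(net$edges$mrna == g)) == 1L) n <- n + 1L
  n
}

# exact signed-rank p by enumerating all 2^n sign patterns (handles ties
# via midranks of |d|)
oracle_signed_rank_p <- function(d, alternative) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  ws <- vapply(0:(2^n - 1), function(mask) {
    signs <- bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L
    sum(r[signs])
  }, numeric(1))
  p_greater <- mean(ws >= w_obs)
  p_less <- mean(ws <= w_obs)
  switch(alternative,
         greater = p_greater,
         less = p_less,
         two.sided = min(1, 2 * min(p_greater, p_less)))
}

# AUC by counting concordant pairs, ties half
oracle_auc <- function(scores, pos) {
  num <- 0
  for (i in which(pos)) for (j in which(!pos)) {
    if (scores[i] > scores[j]) num <- num + 1
    else if (scores[i] == scores[j]) num <- num + 0.5
  }
  num / (sum(pos) * sum(!pos))
}

# BH step-up written directly from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) m * p[o[j]] / j, numeric(1))
    q[o[i]] <- min(1, min(vals))
  }
  q
}

# random bipartite network with given dimensions and density
random_network <- function(n_mirna, n_mrna, density, seed) {
  set.seed(seed)
  mir <- sprintf("m%02d", seq_len(n_mirna))
  gene <- sprintf("g%03d", seq_len(n_mrna))
  adj <- matrix(rbinom(n_mirna * n_mrna, 1, density), n_mirna,
                dimnames = list(mir, gene))
  idx <- which(adj == 1, arr.ind = TRUE)
  suppressMessages(bipartite_network(
    data.frame(mirna = mir[idx[, 1]], mrna = gene[idx[, 2]]),
    mirna_nodes = mir, mrna_nodes = gene))
}

# small three-group expression fixture with planted shifts
small_matrix <- function(n_feat = 40, n_per = c(8, 10, 6), shift = 0,
                         n_shift = 0, sd = 1, seed = 1) {
  set.seed(seed)
  groups <- rep(c("normal", "pPCa", "mPCa"), n_per)
  samples <- sprintf("s%02d", seq_along(groups))
  vals <- matrix(rnorm(n_feat * length(groups), 7, sd), n_feat,
                 dimnames = list(sprintf("f%03d", seq_len(n_feat)), samples))
  if (n_shift > 0)
    vals[seq_len(n_shift), groups != "normal"] <-
      vals[seq_len(n_shift), groups != "normal"] + shift
  expression_matrix(vals, stats::setNames(groups, samples))
}

# reduced-size synthetic configuration for fast unit tests; any field may
# be overridden through ...
small_config <- function(seed = 1, ...) {
  args <- list(n_normal = 10, n_ppca = 20, n_mpca = 8,
               n_normal_mrna = 10, n_ppca_mrna = 24, n_mpca_mrna = 8,
               n_mirna = 60, n_mrna = 500, n_planted_biomarkers = 3,
               de_fraction = 0.25, seed = seed)
  args <- utils::modifyList(args, list(...))
  do.call(synthetic_config, args)
}
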