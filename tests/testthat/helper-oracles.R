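# Independent brute-force oracles used to verify the package's statistics.
# These deliberately use naive, literal arithmetic (incremental walks,
# quadratic passes, exhaustive sums) so they share no code path with the
# implementation they check.

# single-pass incremental running-sum walk
oracle_running_es <- function(scores, hit, weight_exponent) {
  n <- length(scores)
  nh <- sum(hit)
  wsum <- 0
  for (i in seq_len(n)) if (hit[i]) wsum <- wsum + abs(scores[i])^weight_exponent
  cur <- 0
  curve <- numeric(n)
  for (i in seq_len(n)) {
    if (hit[i]) cur <- cur + abs(scores[i])^weight_exponent / wsum
    else cur <- cur - 1 / (n - nh)
    curve[i] <- cur
  }
  peak <- which.max(abs(curve))
  list(es = curve[peak], peak = peak, curve = curve)
}

# signed two-sample ECDF supremum difference (classic KS), computed from
# counts at each position
oracle_ks_es <- function(hit) {
  n <- length(hit)
  hitpos <- which(hit)
  misspos <- which(!hit)
  d <- vapply(seq_len(n), function(i)
    sum(hitpos <= i) / length(hitpos) - sum(misspos <= i) / length(misspos),
    numeric(1))
  d[which.max(abs(d))]
}

# quadratic two-pass ssGSEA integral: at every position, re-sum the member
# weights and non-member counts from scratch
oracle_ssgsea_es <- function(values, members, alpha) {
  genes <- toupper(names(values))
  ord <- order(-values, genes, method = "radix")
  g <- genes[ord]
  hit <- g %in% toupper(members)
  n <- length(g)
  rw <- (n - seq_len(n) + 1)^alpha
  total_in <- sum(rw[hit])
  total_out <- sum(!hit)
  es <- 0
  for (i in seq_len(n)) {
    p_in <- sum(rw[seq_len(i)][hit[seq_len(i)]]) / total_in
    p_out <- sum(!hit[seq_len(i)]) / total_out
    es <- es + (p_in - p_out)
  }
  es
}

# exhaustive hypergeometric upper-tail sum via log binomial coefficients
oracle_hyper_tail <- function(k, K, n, N) {
  hi <- min(n, K)
  if (k > hi) return(0)
  x <- k:hi
  sum(exp(lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)))
}

# Mann-Whitney AUC of scores for separating a binary truth
oracle_auc <- function(scores, truth) {
  pos <- scores[truth]
  neg <- scores[!truth]
  (sum(outer(pos, neg, ">")) + 0.5 * sum(outer(pos, neg, "=="))) /
    (length(pos) * length(neg))
}

# random prerank instance: descending normal scores + a random member subset
random_instance <- function(n_genes, n_members) {
  genes <- sprintf("R%04d", sample.int(9999, n_genes))
  ranked <- ranked_list(genes, rnorm(n_genes))
  members <- sample(ranked$gene, n_members)
  list(ranked = ranked, members = members,
       hit = ranked$gene %in% members)
}

# run cli_main silently, returning the exit code
run_cli <- function(args) {
  code <- NA_integer_
  suppressMessages(code <- cli_main(args))
  code
}
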