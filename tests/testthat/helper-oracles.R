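# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package internals they check.

# multiset triplet matching by greedy removal: for each triplet of a, find
# and consume one matching triplet of b
oracle_triplet_match <- function(a, b) {
  ta <- substring(a, 1:(nchar(a) - 2), 3:nchar(a))
  tb <- substring(b, 1:(nchar(b) - 2), 3:nchar(b))
  hits <- 0L
  for (t in ta) {
    j <- match(t, tb)
    if (!is.na(j)) {
      tb <- tb[-j]
      hits <- hits + 1L
    }
  }
  hits
}

oracle_revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# O(n^2) palindrome scan: per start position, the longest even-length
# substring equal to its own reverse complement
oracle_palindromes <- function(seq, min_len = 6L) {
  n <- nchar(seq)
  count <- 0L
  for (s in seq_len(n)) {
    best <- 0L
    L <- min_len
    while (s + L - 1L <= n) {
      sub <- substr(seq, s, s + L - 1L)
      if (sub == oracle_revcomp(sub)) best <- L
      L <- L + 2L
    }
    if (best >= min_len) count <- count + 1L
  }
  count
}

random_primer <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# two-sided permutation p-value for Spearman rho (midranks), B sampled perms
oracle_perm_spearman <- function(x, y, B = 1e5, seed = 1) {
  set.seed(seed)
  obs <- abs(cor(rank(x), rank(y)))
  rx <- rank(x)
  ry <- rank(y)
  hits <- sum(replicate(B, abs(cor(rx, sample(ry))) >= obs - 1e-12))
  (hits + 1) / (B + 1)
}

# two-sided permutation p-value for the Mann-Whitney rank-sum statistic
oracle_perm_mw <- function(a, b, B = 1e5, seed = 1) {
  set.seed(seed)
  n1 <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  obs <- abs(sum(r[seq_len(n1)]) - n1 * (length(pooled) + 1) / 2)
  hits <- sum(replicate(B, {
    idx <- sample(length(pooled), n1)
    abs(sum(r[idx]) - n1 * (length(pooled) + 1) / 2) >= obs - 1e-12
  }))
  (hits + 1) / (B + 1)
}

# exhaustive ROC point sweep + rank-based AUC (Mann-Whitney identity)
oracle_roc_points <- function(scores, labels) {
  labels <- as.logical(labels)
  pts <- unique(do.call(rbind, lapply(c(Inf, sort(unique(scores),
                                                  decreasing = TRUE), -Inf),
    function(t) c(fpr = sum(!labels & scores >= t) / sum(!labels),
                  tpr = sum(labels & scores >= t) / sum(labels)))))
  pts
}

oracle_auc_mw <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

oracle_pr_points <- function(scores, labels) {
  labels <- as.logical(labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  do.call(rbind, lapply(thr, function(t) {
    pp <- sum(scores >= t)
    c(recall = sum(labels & scores >= t) / sum(labels),
      precision = if (pp == 0) 1 else sum(labels & scores >= t) / pp)
  }))
}
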