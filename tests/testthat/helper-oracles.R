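# Independent brute-force oracles. Each uses a different algorithm from the
# package implementation it checks: BLEU via dense base-A n-gram code
# enumeration (the package hashes n-gram strings), LCS via memoized
# recursion (the package uses iterative dynamic programming), AC1 via a
# literal transcription of the published formula from an expanded rating
# matrix, and BERTScore via nested scalar loops.

# sequences are integer vectors over 1..alphabet
oracle_bleu <- function(cand, ref, alphabet = 3L, max_n = 4L) {
  if (length(cand) == 0L || length(ref) == 0L) return(0)
  log_p <- numeric(0)
  for (n in seq_len(max_n)) {
    mc <- length(cand) - n + 1L
    if (mc < 1L) return(0)   # no candidate n-grams of this order
    codes <- function(s, m) {
      out <- integer(m)
      for (i in seq_len(m)) {
        code <- 0L
        for (k in 0:(n - 1L)) code <- code + (s[i + k] - 1L) * alphabet^k
        out[i] <- code + 1L
      }
      out
    }
    cc <- tabulate(codes(cand, mc), nbins = alphabet^n)
    mr <- length(ref) - n + 1L
    rc <- if (mr >= 1L) tabulate(codes(ref, mr), nbins = alphabet^n) else
      integer(alphabet^n)
    clipped <- sum(pmin(cc, rc))
    if (clipped == 0L) return(0)
    log_p <- c(log_p, log(clipped / sum(cc)))
  }
  bp <- if (length(cand) < length(ref)) exp(1 - length(ref) / length(cand)) else 1
  bp * exp(mean(log_p))
}

oracle_lcs <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0L || j == 0L) return(0L)
    key <- paste0(i, ",", j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (a[i] == b[j]) rec(i - 1L, j - 1L) + 1L else
      max(rec(i - 1L, j), rec(i, j - 1L))
    memo[[key]] <- val
    val
  }
  rec(length(a), length(b))
}

oracle_rouge_l <- function(cand, ref, beta = 1) {
  l <- oracle_lcs(cand, ref)
  p <- l / length(cand)
  r <- l / length(ref)
  f <- if (p + r == 0) 0 else (1 + beta^2) * p * r / (r + beta^2 * p)
  c(precision = p, recall = r, f = f)
}

# literal AC1 formula over an items x categories count matrix
oracle_ac1 <- function(counts) {
  counts <- counts[rowSums(counts) >= 2, , drop = FALSE]
  n <- nrow(counts)
  q <- ncol(counts)
  pa_sum <- 0
  pi_sum <- numeric(q)
  for (i in seq_len(n)) {
    ri <- sum(counts[i, ])
    agree_i <- 0
    for (cat in seq_len(q)) {
      agree_i <- agree_i + counts[i, cat] * (counts[i, cat] - 1)
      pi_sum[cat] <- pi_sum[cat] + counts[i, cat] / ri
    }
    pa_sum <- pa_sum + agree_i / (ri * (ri - 1))
  }
  pa <- pa_sum / n
  pi_q <- pi_sum / n
  pe <- 0
  for (cat in seq_len(q)) pe <- pe + pi_q[cat] * (1 - pi_q[cat])
  pe <- pe / (q - 1)
  (pa - pe) / (1 - pe)
}

# nested-loop greedy-matching BERTScore from an embedding function
oracle_bert_score <- function(cand, ref, embedder) {
  ce <- embedder(cand)
  re <- embedder(ref)
  cos <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  p_terms <- numeric(nrow(ce))
  for (i in seq_len(nrow(ce))) {
    best <- -Inf
    for (j in seq_len(nrow(re))) best <- max(best, cos(ce[i, ], re[j, ]))
    p_terms[i] <- best
  }
  r_terms <- numeric(nrow(re))
  for (j in seq_len(nrow(re))) {
    best <- -Inf
    for (i in seq_len(nrow(ce))) best <- max(best, cos(ce[i, ], re[j, ]))
    r_terms[j] <- best
  }
  p <- mean(p_terms)
  r <- mean(r_terms)
  c(precision = p, recall = r, f1 = 2 * p * r / (p + r))
}

# all integer sequences of length 1..max_len over 1..alphabet
all_sequences <- function(max_len, alphabet = 3L) {
  out <- list()
  for (len in seq_len(max_len)) {
    grid <- as.matrix(expand.grid(rep(list(seq_len(alphabet)), len)))
    for (i in seq_len(nrow(grid))) out[[length(out) + 1L]] <- unname(grid[i, ])
  }
  out
}
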