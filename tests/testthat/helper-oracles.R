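# Independent brute-force oracles and small fixture builders. Everything here
# is deliberately naive (position-by-position loops) so it cannot share a bug
# with the vectorized implementation it checks.

random_replicon <- function(n, seed, id = "rnd") {
  set.seed(seed)
  replicon(id, paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                     collapse = ""))
}

# random feature table; overlaps allowed unless disjoint = TRUE
random_features <- function(id, n, k, seed, disjoint = FALSE) {
  set.seed(seed)
  if (disjoint) {
    cuts <- sort(sample(0:(n - 1), 2 * k))
    starts <- cuts[seq(1, 2 * k, 2)]
    ends <- cuts[seq(2, 2 * k, 2)]
    keep <- ends - starts >= 3
    starts <- starts[keep]; ends <- ends[keep]
  } else {
    starts <- sample(0:(n - 4), k, replace = TRUE)
    lens <- sample(3:max(3, n %/% 3), k, replace = TRUE)
    ends <- pmin(starts + lens, n)
  }
  m <- length(starts)
  feature_table(rep(id, m), starts, ends,
                sample(c("+", "-"), m, replace = TRUE),
                sample(0:2, m, replace = TRUE))
}

# the stated overlap-priority rule applied independently per position:
# label from the longest covering feature (tie: smallest start)
brute_labels <- function(rep_, features) {
  n <- rep_$length
  codon <- integer(n); cover <- integer(n)
  for (p in seq_len(n)) {
    g <- p - 1L   # 0-based
    cov <- which(features$start <= g & g < features$end)
    if (!length(cov)) next
    plus <- any(features$strand[cov] == "+")
    minus <- any(features$strand[cov] == "-")
    cover[p] <- if (plus && !minus) 1L else if (minus && !plus) -1L else 0L
    w <- features$end[cov] - features$start[cov]
    pri <- cov[order(-w, features$start[cov])][1L]
    s <- features$start[pri]; e <- features$end[pri]
    fo <- features$frame_offset[pri]
    if (e - s - fo < 3L) next
    if (features$strand[pri] == "+") {
      if (g >= s + fo) codon[p] <- 1L + ((g - s - fo) %% 3L)
    } else {
      if (g < e - fo) codon[p] <- 1L + ((e - 1L - fo - g) %% 3L)
    }
  }
  list(codon_label = codon, strand_cover = cover)
}

# position-by-position window skew counter
brute_window_skew <- function(rep_, codon_label, skew_class, window_size) {
  chars <- strsplit(rep_$sequence, "")[[1L]]
  n_win <- rep_$length %/% window_size
  vals <- numeric(n_win); gs <- cs <- integer(n_win)
  for (w in seq_len(n_win)) {
    g <- c_ <- 0L
    for (p in ((w - 1L) * window_size + 1L):(w * window_size)) {
      keep <- switch(skew_class,
                     total = TRUE,
                     codon1 = codon_label[p] == 1L,
                     codon2 = codon_label[p] == 2L,
                     codon3 = codon_label[p] == 3L,
                     noncoding = codon_label[p] == 0L)
      if (!keep) next
      if (chars[p] == "G") g <- g + 1L
      if (chars[p] == "C") c_ <- c_ + 1L
    }
    gs[w] <- g; cs[w] <- c_
    vals[w] <- if (g + c_ > 0L) (g - c_) / (g + c_) else 0
  }
  list(values = vals, g = gs, c = cs)
}

# brute-force search over all ordered breakpoint pairs using lm(); the
# independent route for the div-fit oracle-equivalence check
brute_div_search <- function(y) {
  n <- length(y); x <- seq_len(n) - 1
  best <- list(rss = Inf)
  for (ori in 0:(n - 1)) for (ter in 0:(n - 1)) {
    L1 <- (ter - ori) %% n
    if (L1 < 1 || L1 > n - 1) next
    u <- (x - ori) %% n
    Tri <- ifelse(u <= L1, u, L1 - (L1 / (n - L1)) * (u - L1))
    fit <- lm(y ~ x + Tri)
    a1 <- coef(fit)[["Tri"]]
    if (is.na(a1) || a1 <= 0) next
    rss <- sum(fit$residuals^2)
    if (rss < best$rss) best <- list(rss = rss, ori = ori, ter = ter,
                                    div = L1 / n)
  }
  best
}

write_fasta_tmp <- function(named_seqs) {
  path <- tempfile(fileext = ".fasta")
  writeLines(unlist(lapply(names(named_seqs), function(id)
    c(paste0(">", id), named_seqs[[id]]))), path)
  path
}

small_sim <- function(seed = 1, length = 262144L, ...) {
  simulate_replicon(synthetic_config(length = length, seed = seed, ...))
}
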