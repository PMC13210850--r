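# Independent oracles used across tests. These are deliberately naive
# re-derivations (brute force, enumeration, hand formulas) kept separate
# from the package implementation paths they check.

# brute-force covariance PCA via eigen(): returns eigenvalues and scores
oracle_pca <- function(X) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(Xc), symmetric = TRUE)
  list(values = ev$values, scores = Xc %*% ev$vectors, vectors = ev$vectors)
}

# hand step-up BH adjustment
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# naive sliding-window IUPAC matcher; subject N matches nothing
oracle_scan <- function(seq, pattern) {
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))
  s <- strsplit(seq, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  w <- length(p)
  L <- length(s)
  if (L < w) return(integer(0))
  ok <- rep(TRUE, L - w + 1)
  for (k in seq_len(w)) {             # position-wise IUPAC set membership
    ok <- ok & (s[k:(L - w + k)] %in% sets[[p[k]]])
  }
  which(ok) - 1L  # 0-based
}

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A",
            R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
            B = "V", V = "B", D = "H", H = "D", N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# enumerate all single-base mutants of a codon and count the synonymous
# fraction per position, excluding mutations to stops from the denominator
oracle_ng86_sites <- function(codon) {
  gc_tab <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  cod <- strsplit(codon, "")[[1]]
  aa <- gc_tab[codon]
  s <- 0
  for (pos in 1:3) {
    muts <- vapply(setdiff(bases, cod[pos]), function(b) {
      m <- cod; m[pos] <- b; paste(m, collapse = "")
    }, character(1))
    maa <- gc_tab[muts]
    nonstop <- maa != "*"
    if (any(nonstop)) s <- s + sum(maa == aa & nonstop) / sum(nonstop)
  }
  c(syn = s, nonsyn = 3 - s)
}

# Jukes-Cantor correction
oracle_jc <- function(p) -0.75 * log(1 - 4 * p / 3)

# exhaustive longest valid monotone chain over <= ~15 anchors: checks every
# index subset for validity
oracle_longest_chain <- function(o_a, o_b, max_gap) {
  n <- length(o_a)
  ord <- order(o_a, o_b)
  o_a <- o_a[ord]; o_b <- o_b[ord]
  best <- 0L
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) <= best) next
    a <- o_a[idx]; b <- o_b[idx]
    if (any(diff(a) <= 0) || any(diff(a) > max_gap)) next
    db <- diff(b)
    rising <- all(db > 0) && all(db <= max_gap)
    falling <- all(db < 0) && all(-db <= max_gap)
    if (rising || falling) best <- length(idx)
  }
  best
}

# exact Kruskal-Wallis permutation p by enumerating label permutations of
# the rank vector (multiset permutations, depth-first over label sequences)
oracle_kw_exact <- function(x, g) {
  r <- rank(x)
  g <- as.integer(factor(g))
  N <- length(r)
  ties <- table(x)
  tie_div <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H <- function(labels) {
    h <- 12 / (N * (N + 1)) *
      sum(tapply(r, labels, sum)^2 / tabulate(labels)) - 3 * (N + 1)
    if (tie_div > 0) h / tie_div else 0
  }
  obs <- H(g)
  counts0 <- tabulate(g)
  n_hit <- 0L; n_tot <- 0L
  labels <- integer(N)
  walk <- function(pos, counts) {
    if (pos > N) {
      n_tot <<- n_tot + 1L
      if (H(labels) >= obs - 1e-9) n_hit <<- n_hit + 1L
      return(invisible())
    }
    for (lab in seq_along(counts)) {
      if (counts[lab] > 0) {
        labels[pos] <<- lab
        counts[lab] <- counts[lab] - 1L
        walk(pos + 1L, counts)
        counts[lab] <- counts[lab] + 1L
      }
    }
  }
  walk(1L, counts0)
  n_hit / n_tot
}
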