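# Independent oracles used across the suite; kept deliberately naive and
# separate from the package's own computation paths.

# upper-tail binomial by direct pmf summation (log-space terms)
oracle_binom_tail <- function(s, S, r) {
  if (s <= 0) return(1)
  if (r <= 0) return(0)
  if (r >= 1) return(1)
  k <- s:S
  sum(exp(lchoose(S, k) + k * log(r) + (S - k) * log1p(-r)))
}

# two-sided Fisher p by exhaustive fixed-margin enumeration with explicit
# log-binomial-coefficient probabilities (no dhyper)
oracle_fisher <- function(a, b, c, d) {
  if (a + b + c + d == 0) return(1)
  m <- a + c; n_ <- b + d; k <- a + b
  x <- max(0, k - n_):min(k, m)
  logp <- lchoose(m, x) + lchoose(n_, k - x) - lchoose(m + n_, k)
  lobs <- lchoose(m, a) + lchoose(n_, k - a) - lchoose(m + n_, k)
  sum(exp(logp[logp <= lobs + log1p(1e-7)]))
}

# greedy non-overlap selection using explicit position sets
oracle_greedy <- function(df, alpha_evalue = 10) {
  df <- df[df$evalue <= alpha_evalue, , drop = FALSE]
  df <- df[order(df$p_raw, df$width, df$start), , drop = FALSE]
  taken <- integer(0)
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    span <- seq(df$start[i], df$start[i] + df$width[i] - 1L)
    if (!length(intersect(span, taken))) {
      keep[i] <- TRUE
      taken <- c(taken, span)
    }
  }
  df[keep, , drop = FALSE]
}

# brute-force best match over every (start, strand) of one sequence
oracle_best_site <- function(seq, sm) {
  w <- nrow(sm)
  L <- nchar(seq)
  letters <- strsplit(seq, "")[[1]]
  rc <- motifzoom::reverse_complement_matrix(sm)
  score_at <- function(mat, st) {
    win <- letters[st:(st + w - 1)]
    idx <- match(win, colnames(mat))
    if (anyNA(idx)) return(-1e30 * w)
    sum(mat[cbind(seq_len(w), idx)])
  }
  best <- -Inf; where <- NULL
  for (st in 1:(L - w + 1)) {
    for (strand in c("+", "-")) {
      sc <- score_at(if (strand == "+") sm else rc, st)
      if (sc > best) {
        best <- sc
        where <- list(start = st - 1L, strand = strand, score = sc)
      }
    }
  }
  where
}

random_motif <- function(width = 6, id = "rnd") {
  probs <- t(vapply(seq_len(width), function(i) {
    p <- runif(4)
    p / sum(p)
  }, numeric(4)))
  motifzoom::motif(id, probs, nsites = 50)
}

random_dna <- function(n, L) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
}

meme_fixture_text <- function() {
  c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
    "Background letter frequencies", "A 0.25 C 0.25 G 0.25 T 0.25", "",
    "MOTIF m1 first", "letter-probability matrix: alength= 4 w= 2 nsites= 20",
    " 1.000000 0.000000 0.000000 0.000000",
    " 0.000000 1.000000 0.000000 0.000000", "",
    "MOTIF m2", "letter-probability matrix: alength= 4 w= 3",
    " 0.250000 0.250000 0.250000 0.250000",
    " 0.970000 0.010000 0.010000 0.010000",
    " 0.100000 0.200000 0.300000 0.400000")
}
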