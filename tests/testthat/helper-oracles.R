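# Independent brute-force oracles used across the suite. These deliberately
# re-derive quantities by naive enumeration, not by calling package internals.

rand_seqs <- function(n, len, gc = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "T", "G", "C"), len, replace = TRUE,
                 prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
          collapse = "")
  }, character(1))
}

revcomp_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

# occurrences of a fixed k-mer in a sequence, sliding windows, N never matches
count_occurrences <- function(seq, kmer) {
  k <- nchar(kmer)
  L <- nchar(seq)
  if (L < k) return(0L)
  sum(vapply(seq_len(L - k + 1L),
             function(i) substr(seq, i, i + k - 1L) == kmer, logical(1)))
}

# per-sequence mean canonical k-mer counts by naive enumeration
brute_mean_counts <- function(seqs, k) {
  all_km <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), k),
                                        stringsAsFactors = FALSE)[, k:1, drop = FALSE])
  all_km <- sort(all_km)
  rc <- vapply(all_km, revcomp_chr, character(1))
  canon <- all_km[all_km <= rc]
  out <- vapply(canon, function(s) {
    r <- revcomp_chr(s)
    mean(vapply(seqs, function(x) {
      count_occurrences(x, s) + if (r != s) count_occurrences(x, r) else 0L
    }, numeric(1)))
  }, numeric(1))
  out
}

# tie-corrected Mann-Whitney AUC over all pairs
brute_auc <- function(p, b) {
  cmp <- outer(p, b, "<") + 0.5 * outer(p, b, "==")
  mean(cmp)
}

# exact permutation expectation of pair counts (composition null), no N case
brute_pair_expectation <- function(seq, alpha, beta, x) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  n_a <- sum(chars == alpha)
  n_b <- sum(chars == beta)
  if (alpha == beta) (L - x) * n_a * (n_a - 1) / (L * (L - 1))
  else (L - x) * n_a * n_b / (L * (L - 1))
}

# Grid-refinement solver for the competition equilibrium, independent of the
# package's root finder: nested 1-D grid refinement on the two conservation
# residuals, which are monotone in their own free concentration. Each level
# evaluates the residual on an evenly spaced grid, keeps the sign-change
# cell, and refines it; no Brent/Newton steps anywhere.
grid_refine_equilibrium <- function(params, n_grid = 7L, n_iter = 20L) {
  p <- params
  # Myc conservation residual, vectorized in m
  f1 <- function(m, s) {
    l <- p$DNAL_tot / (1 + m / p$K_L + s^2 / p$Ktilde_L)
    bq <- 1 + m / p$K1 + s^2 / p$Ktilde_H
    a <- if (p$tetramer) 2 * m^2 / (p$K1^2 * p$K2) else m * 0
    h <- ifelse(a > 0, 2 * p$DNAH_tot / (bq + sqrt(bq^2 + 4 * a * p$DNAH_tot)),
                p$DNAH_tot / bq)
    mh <- m * h / p$K1
    tet <- if (p$tetramer) mh^2 / p$K2 else m * 0
    m + mh + 2 * tet + m * l / p$K_L - p$Myc_tot
  }
  refine <- function(f, hi) {
    lo_b <- 0
    hi_b <- hi
    for (it in seq_len(n_iter)) {
      g <- seq(lo_b, hi_b, length.out = n_grid)
      v <- f(g)
      i <- max(which(v <= 0))           # monotone: sign change after i
      lo_b <- g[i]
      hi_b <- if (i < n_grid) g[i + 1L] else g[i]
      if (lo_b == hi_b) break
    }
    (lo_b + hi_b) / 2
  }
  solve_m <- function(s) {
    if (p$Myc_tot == 0) return(0)
    refine(function(m) f1(m, s), p$Myc_tot)
  }
  # Smad conservation residual at the inner-solved free Myc, vectorized in s
  f2 <- function(s) {
    vapply(s, function(si) {
      m <- solve_m(si)
      l <- p$DNAL_tot / (1 + m / p$K_L + si^2 / p$Ktilde_L)
      bq <- 1 + m / p$K1 + si^2 / p$Ktilde_H
      a <- if (p$tetramer) 2 * m^2 / (p$K1^2 * p$K2) else 0
      h <- if (a > 0) 2 * p$DNAH_tot / (bq + sqrt(bq^2 + 4 * a * p$DNAH_tot))
        else p$DNAH_tot / bq
      si + 2 * si^2 * h / p$Ktilde_H + 2 * si^2 * l / p$Ktilde_L - p$Smad_tot
    }, numeric(1))
  }
  s <- if (p$Smad_tot == 0) 0 else refine(f2, p$Smad_tot)
  m <- solve_m(s)
  l <- p$DNAL_tot / (1 + m / p$K_L + s^2 / p$Ktilde_L)
  bq <- 1 + m / p$K1 + s^2 / p$Ktilde_H
  a <- if (p$tetramer) 2 * m^2 / (p$K1^2 * p$K2) else 0
  h <- if (a > 0) 2 * p$DNAH_tot / (bq + sqrt(bq^2 + 4 * a * p$DNAH_tot)) else
    p$DNAH_tot / bq
  mh <- m * h / p$K1
  list(Myc = m, Smad = s, DNAH = h, DNAL = l, Myc_DNAH = mh,
       Myc_DNAH_2 = if (p$tetramer) mh^2 / p$K2 else 0,
       Myc_DNAL = m * l / p$K_L,
       Smad2_DNAH = s^2 * h / p$Ktilde_H, Smad2_DNAL = s^2 * l / p$Ktilde_L)
}
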