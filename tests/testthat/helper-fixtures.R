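# Small programmatic fixtures shared across test files.

make_counts <- function(n_samples, n_otus, seed = 1, lambda = 5) {
  set.seed(seed)
  m <- matrix(stats::rpois(n_samples * n_otus, lambda), n_samples, n_otus,
              dimnames = list(paste0("S", seq_len(n_samples)),
                              paste0("OTU", seq_len(n_otus))))
  # guarantee positive row totals
  m[, 1L] <- m[, 1L] + 1L
  m
}

# Independent brute-force re-implementation of the six abundance rules,
# written per-OTU from the category definitions (not shared with the
# vectorized implementation): rare means <= t_r, abundant means >= t_a.
brute_force_classify <- function(ra, t_r = 1e-4, t_a = 0.01) {
  out <- character(ncol(ra))
  for (i in seq_len(ncol(ra))) {
    x <- ra[, i]
    rare_somewhere <- any(x <= t_r)
    abundant_somewhere <- any(x >= t_a)
    rare_everywhere <- all(x <= t_r)
    abundant_everywhere <- all(x >= t_a)
    out[i] <-
      if (rare_everywhere) "RT"
      else if (abundant_everywhere) "AAT"
      else if (rare_somewhere && abundant_somewhere) "CRAT"
      else if (rare_somewhere) "CRT"
      else if (abundant_somewhere) "CAT"
      else "MT"
  }
  names(out) <- colnames(ra)
  out
}

# 2-sample, 6-OTU table containing exactly one OTU per category at the
# default cutoffs (depth 10000: 1 read = the rare cutoff, 100 reads = the
# abundant cutoff).
category_fixture <- function() {
  cnt <- rbind(
    S1 = c(AATo = 9399L, CRATo = 500L, CATo = 50L, MTo = 50L, CRTo = 1L,
           RTo = 0L),
    S2 = c(AATo = 9398L, CRATo = 1L, CATo = 500L, MTo = 50L, CRTo = 50L,
           RTo = 1L))
  otu_table(cnt)
}
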