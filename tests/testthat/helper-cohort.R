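# Shared fixtures, generated in code.

tiny_spec <- function(seed = 11L, ...) {
  args <- list(breeds = c(A = 4L, B = 4L), chrom_lengths_bp = c(20e6, 20e6),
               n_cnvr_loci = 8L, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(cohort_spec, args)
}

# A signal with implanted segments and optional noise, on a regular map.
flat_map <- function(n = 100L, spacing = 49000L, chrom = 1L, gc = 0.5) {
  data.frame(probe_id = sprintf("p%03d", seq_len(n)), chrom = chrom,
             pos_bp = spacing * seq_len(n), gc_frac = gc,
             stringsAsFactors = FALSE)
}

# states: integer vector per probe; emission means follow noise_spec defaults
signal_from_states <- function(states, lrr_sd = 0, baf_sd = 0,
                               sample_id = "S1", seed = 1L) {
  set.seed(seed)
  means <- c(`0` = -3.0, `1` = -0.66, `2` = 0, `3` = 0.40, `4` = 0.68)
  baf_pick <- function(s) {
    cl <- switch(as.character(s), `0` = runif(1), `1` = sample(c(0, 1), 1),
                 `2` = sample(c(0, 0.5, 1), 1),
                 `3` = sample(c(0, 1/3, 2/3, 1), 1),
                 `4` = sample(c(0, 0.25, 0.5, 0.75, 1), 1))
    min(1, max(0, cl + rnorm(1, sd = baf_sd)))
  }
  list(sample_id = sample_id, breed = "A",
       lrr = means[as.character(states)] + rnorm(length(states), sd = lrr_sd),
       baf = vapply(states, baf_pick, 0))
}

# O(n^2) union-find connected components over >=1 bp interval overlap;
# independent oracle for build_cnvrs
brute_force_components <- function(chrom, start, end) {
  n <- length(chrom)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && chrom[i] == chrom[j] && start[i] <= end[j] &&
          end[i] >= start[j]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  vapply(seq_len(n), find, 0L)
}

# exhaustive two-sided rank-sum p (no ties), mirroring the exact test
exact_ranksum_p <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  sets <- utils::combn(n + m, n)
  W <- apply(sets, 2, function(s) sum(r[s])) - n * (n + 1) / 2
  if (w_obs > n * m / 2) {
    p <- 2 * mean(W >= w_obs)
  } else {
    p <- 2 * mean(W <= w_obs)
  }
  min(1, p)
}
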