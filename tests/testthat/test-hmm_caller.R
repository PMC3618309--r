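params_a <- hmm_params("A")

test_that("emission log-likelihoods peak at the state signatures", {
  # diploid modal data favors state 2 over every alternative
  e <- vapply(0:4, function(s) emission_loglik(0, 0.5, s, params_a), 0)
  expect_equal(which.max(e) - 1L, 2L)
  # heterozygous-deletion signature favors state 1
  e1 <- emission_loglik(-0.66, 1.0, 1L, params_a)
  e2 <- emission_loglik(-0.66, 1.0, 2L, params_a)
  expect_gt(e1, e2)
  # missing BAF contributes nothing beyond the LRR term
  expect_equal(emission_loglik(0.1, NA_real_, 3L, params_a),
               dnorm(0.1, params_a$lrr_mean[4], params_a$lrr_sd[4],
                     log = TRUE))
  expect_error(emission_loglik(Inf, 0.5, 2L, params_a), "non-finite")
})

test_that("transition matrices are stochastic with the right limits", {
  for (d in c(1, 49000, 5e6)) {
    M <- transition_matrix(d, params_a)
    expect_equal(rowSums(M), rep(1, 5), tolerance = 1e-12)
    expect_true(all(M >= 0))
  }
  # d -> 0: stay probability approaches the base
  M0 <- transition_matrix(1, params_a)
  expect_equal(diag(M0), params_a$stay_prob_base * 1 +
                 params_a$stationary * 0, tolerance = 1e-3)
  # d -> infinity: rows approach the stationary distribution
  Minf <- transition_matrix(1e12, params_a)
  for (s in 1:5)
    expect_equal(Minf[s, ], params_a$stationary, tolerance = 1e-6)
})

test_that("Viterbi decodes implanted events exactly on clean signals", {
  map <- flat_map(100)
  states <- rep(2L, 100); states[40:60] <- 1L
  sig <- signal_from_states(states, lrr_sd = 0, baf_sd = 0, seed = 5)
  path <- viterbi_path(sig, map, params_a)
  expect_identical(path, states)
  # all-diploid signal decodes to the all-2 path
  calm <- signal_from_states(rep(2L, 100), seed = 6)
  expect_identical(viterbi_path(calm, map, params_a), rep(2L, 100))
  # determinism
  expect_identical(viterbi_path(sig, map, params_a),
                   viterbi_path(sig, map, params_a))
})

test_that("Viterbi matches an exhaustive-path oracle on short chromosomes", {
  n <- 7L
  map <- flat_map(n)
  set.seed(77)
  for (rep in 1:5) {
    states <- sample(c(1L, 2L, 3L), n, replace = TRUE, prob = c(2, 6, 2))
    sig <- signal_from_states(states, lrr_sd = 0.1, baf_sd = 0.02,
                              seed = 700 + rep)
    E <- vapply(0:4, function(s)
      emission_loglik(sig$lrr, sig$baf, s, params_a), numeric(n))
    # brute force over all 5^n paths
    paths <- as.matrix(expand.grid(rep(list(1:5), n)))
    logT <- lapply(diff(map$pos_bp), function(d)
      log(transition_matrix(d, params_a)))
    score <- log(params_a$stationary)[paths[, 1]] + E[cbind(1L, paths[, 1])]
    for (i in 2:n)
      score <- score + logT[[i - 1]][cbind(paths[, i - 1], paths[, i])] +
        E[cbind(i, paths[, i])]
    best <- paths[which.max(score), ] - 1L
    expect_identical(viterbi_path(sig, map, params_a), unname(best))
  }
})

test_that("state runs convert to calls with the probe floor applied", {
  map <- flat_map(30)
  path <- rep(2L, 30)
  path[5:10] <- 1L            # 6-probe loss
  path[12:13] <- 3L           # 2-probe gain: below the floor
  path[20:26] <- 4L           # 7-probe gain
  calls <- path_to_calls(path, map, "S1")
  expect_equal(nrow(calls), 2)
  expect_equal(calls$cn, c(1L, 4L))
  expect_equal(calls$n_probes, c(6L, 7L))
  expect_equal(calls$start_bp[1], map$pos_bp[5])
  expect_equal(calls$end_bp[1], map$pos_bp[10])
  # two runs separated by a single diploid probe stay distinct
  path2 <- rep(2L, 30); path2[5:8] <- 1L; path2[10:13] <- 1L
  expect_equal(nrow(path_to_calls(path2, map, "S1")), 2)
  expect_equal(nrow(path_to_calls(rep(2L, 30), map, "S1")), 0)
})

test_that("Bayes factors grow with evidence and ignore flanking data", {
  map <- flat_map(100)
  for (k in c(3, 10, 30)) {
    states <- rep(2L, 100); states[10:(9 + k)] <- 1L
    sig <- signal_from_states(states, seed = 8)
    call <- list(chrom = 1L, start_bp = map$pos_bp[10],
                 end_bp = map$pos_bp[9 + k], cn = 1L)
    bf <- bayes_factor(call, sig, map, params_a)
    if (k > 3) expect_gt(bf, last_bf)
    last_bf <- bf
  }
  # diploid-modal segment scores zero after clipping
  calm <- signal_from_states(rep(2L, 100), seed = 9)
  call2 <- list(chrom = 1L, start_bp = map$pos_bp[10],
                end_bp = map$pos_bp[20], cn = 1L)
  expect_equal(bayes_factor(call2, calm, map, params_a), 0)
  # perturbing data outside the call leaves bf unchanged
  states <- rep(2L, 100); states[40:50] <- 1L
  sig <- signal_from_states(states, seed = 10)
  call3 <- list(chrom = 1L, start_bp = map$pos_bp[40],
                end_bp = map$pos_bp[50], cn = 1L)
  bf1 <- bayes_factor(call3, sig, map, params_a)
  sig$lrr[1:30] <- rnorm(30, sd = 2)
  expect_identical(bayes_factor(call3, sig, map, params_a), bf1)
  expect_error(bayes_factor(list(chrom = 9L, start_bp = 1, end_bp = 2,
                                 cn = 1L), sig, map, params_a),
               "zero probes")
})

test_that("whole-sample calling recovers implanted CNVs and is quiet on nulls", {
  spec <- cohort_spec(breeds = c(A = 1L), chrom_lengths_bp = 30e6,
                      n_cnvr_loci = 5L, singleton_mass = 1, seed = 55L)
  map <- make_probe_map(spec)
  truth <- make_truth_set(spec, map)
  truth <- truth[truth$n_probes >= 10, ]
  sig <- simulate_signals(truth, map, data.frame(sample_id = "S001",
                                                 breed = "A"),
                          noise_spec(), seed = 56)[[1]]
  calls <- call_sample(sig, map, params_a)
  rec <- vapply(seq_len(nrow(truth)), function(i)
    any(calls$chrom == truth$chrom[i] & calls$start_bp <= truth$end_bp[i] &
          calls$end_bp >= truth$start_bp[i] &
          calls$cn == truth$cn[i]), TRUE)
  expect_gte(sum(rec), nrow(truth) - 1)
  # CNV-free sample at default noise: at most one confident false call
  null_sig <- simulate_signals(cnv_calls(), map,
                               data.frame(sample_id = "N1", breed = "A"),
                               noise_spec(), seed = 57)[[1]]
  null_calls <- call_sample(null_sig, map, params_a)
  expect_lte(nrow(apply_bf_threshold(null_calls, 15)), 1)
  # determinism of the full composition
  expect_identical(call_sample(sig, map, params_a),
                   call_sample(sig, map, params_a))
})
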