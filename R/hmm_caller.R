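#' HMM caller parameters
#'
#' One five-state (CN 0..4) distance-aware HMM engine run under two presets
#' stands in for the common practice of calling with two independent tools
#' and merging. The presets differ in emission width and transition decay:
#' preset "A" is tighter and favors shorter events; preset "B" is wider
#' with a longer expected event length. Emission means follow the usual
#' SNP-array convention and the null state is CN 2.
#'
#' @param preset "A" or "B".
#' @param lrr_mean LRR emission means per state (strictly increasing).
#' @param lrr_sd LRR emission SDs per state (state 0 is wide: homozygous
#'   deletions have noisy intensity).
#' @param baf_sd BAF cluster SD.
#' @param expected_event_length_bp transition distance-decay scale.
#' @param stay_prob_base stay probability in the zero-distance limit.
#' @param stationary stationary state weights (favoring CN 2).
#' @return list of class `hmm_params`.
#' @export
hmm_params <- function(preset = c("A", "B"),
                       lrr_mean = c(-3.0, -0.66, 0, 0.40, 0.68),
                       lrr_sd = NULL, baf_sd = NULL,
                       expected_event_length_bp = NULL,
                       stay_prob_base = NULL,
                       stationary = c(0.005, 0.05, 0.89, 0.04, 0.015)) {
  preset <- match.arg(preset)
  defaults <- if (preset == "A") {
    list(lrr_sd = c(1.0, 0.20, 0.20, 0.20, 0.20), baf_sd = 0.04,
         expected_event_length_bp = 5e5, stay_prob_base = 0.95)
  } else {
    list(lrr_sd = c(1.2, 0.25, 0.25, 0.25, 0.25), baf_sd = 0.06,
         expected_event_length_bp = 2e6, stay_prob_base = 0.90)
  }
  lrr_sd <- lrr_sd %||% defaults$lrr_sd
  baf_sd <- baf_sd %||% defaults$baf_sd
  expected_event_length_bp <- expected_event_length_bp %||%
    defaults$expected_event_length_bp
  stay_prob_base <- stay_prob_base %||% defaults$stay_prob_base
  stopifnot(all(diff(lrr_mean) > 0), all(lrr_sd > 0), baf_sd > 0,
            expected_event_length_bp > 0,
            stay_prob_base > 0, stay_prob_base < 1,
            length(stationary) == 5, all(stationary > 0))
  structure(list(
    preset = preset, states = 0:4, lrr_mean = lrr_mean, lrr_sd = lrr_sd,
    baf_clusters = list(NULL, c(0, 1), c(0, 0.5, 1), c(0, 1/3, 2/3, 1),
                        c(0, 0.25, 0.5, 0.75, 1)),
    baf_sd = baf_sd,
    expected_event_length_bp = expected_event_length_bp,
    stay_prob_base = stay_prob_base,
    stationary = stationary / sum(stationary), null_state = 2L
  ), class = "hmm_params")
}

#' Per-probe emission log-likelihood for one state
#'
#' Gaussian log-density of LRR at the state's (mean, sd) plus the log of an
#' equal-weight Gaussian mixture over the state's BAF genotype clusters.
#' The CN 0 BAF term is uniform on \[0, 1\] (log-density 0); missing BAF
#' (or LRR) contributes 0.
#'
#' @param lrr,baf numeric vectors (parallel).
#' @param state integer in 0..4.
#' @param params [hmm_params()].
#' @return vector of log-likelihoods (natural log).
#' @export
emission_loglik <- function(lrr, baf, state, params) {
  if (any(!is.finite(lrr) & !is.na(lrr)) || any(!is.finite(baf) & !is.na(baf)))
    stop("non-finite signal values")
  s <- state + 1L
  ll_lrr <- dnorm(lrr, params$lrr_mean[s], params$lrr_sd[s], log = TRUE)
  ll_lrr[is.na(ll_lrr)] <- 0
  mus <- params$baf_clusters[[s]]
  if (is.null(mus)) {
    ll_baf <- rep(0, length(baf))            # uniform on [0, 1]
  } else {
    d <- vapply(mus, function(mu)
      dnorm(baf, mu, params$baf_sd), numeric(length(baf)))
    if (is.null(dim(d))) d <- matrix(d, nrow = length(baf))
    ll_baf <- log(rowMeans(d))
    ll_baf[is.na(baf)] <- 0
  }
  ll_lrr + ll_baf
}

#' Distance-dependent transition matrix
#'
#' Stay probability decays with inter-probe distance d toward the
#' stationary weight: p_stay(d) = base * exp(-d/L) + pi_s * (1 -
#' exp(-d/L)). Off-diagonal mass is distributed proportional to the
#' stationary weights of the other states; every row sums to 1.
#'
#' @param distance_bp positive inter-probe distance.
#' @param params [hmm_params()].
#' @return 5x5 row-stochastic matrix (states 0..4).
#' @export
transition_matrix <- function(distance_bp, params) {
  stopifnot(distance_bp > 0)
  w <- exp(-distance_bp / params$expected_event_length_bp)
  pi <- params$stationary
  stay <- params$stay_prob_base * w + pi * (1 - w)
  M <- matrix(0, 5, 5)
  for (s in 1:5) {
    off <- pi[-s] / sum(pi[-s])
    M[s, -s] <- (1 - stay[s]) * off
    M[s, s] <- stay[s]
  }
  M / rowSums(M)
}

# Emission matrix (n x 5, natural log) for a whole signal
emission_matrix <- function(signal, params) {
  vapply(0:4, function(s) emission_loglik(signal$lrr, signal$baf, s, params),
         numeric(length(signal$lrr)))
}

#' Viterbi decoding of the copy-number state path
#'
#' Maximum a posteriori state path in log space, per chromosome (the chain
#' restarts at each chromosome with the stationary distribution). Ties are
#' broken toward the diploid state 2 for reproducible boundaries.
#'
#' @param signal sample signal aligned to `map`.
#' @param map probe map.
#' @param params [hmm_params()].
#' @return integer vector of states (0..4), one per probe.
#' @export
viterbi_path <- function(signal, map, params) {
  stopifnot(length(signal$lrr) == nrow(map))
  E <- emission_matrix(signal, params)
  out <- integer(nrow(map))
  log_pi <- log(params$stationary)
  pick <- function(v) {                      # argmax, ties toward state 2
    m <- max(v)
    cand <- which(v == m)
    if (3L %in% cand) 3L else cand[1]
  }
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    n <- length(idx)
    delta <- matrix(-Inf, n, 5)
    psi <- matrix(1L, n, 5)
    delta[1, ] <- log_pi + E[idx[1], ]
    if (n > 1) {
      d <- diff(map$pos_bp[idx])
      for (i in 2:n) {
        logT <- log(transition_matrix(max(d[i - 1], 1), params))
        for (s in 1:5) {
          v <- delta[i - 1, ] + logT[, s]
          j <- pick(v)
          psi[i, s] <- j
          delta[i, s] <- v[j] + E[idx[i], s]
        }
      }
    }
    path <- integer(n)
    path[n] <- pick(delta[n, ])
    if (n > 1) for (i in (n - 1):1) path[i] <- psi[i + 1, path[i + 1]]
    out[idx] <- path - 1L
  }
  out
}

#' Convert a state path to CNV calls
#'
#' Maximal runs of a constant non-diploid state become calls with
#' boundaries at the run's first and last probe; runs shorter than
#' `min_probes` are dropped. A single diploid probe separates runs (no gap
#' bridging).
#'
#' @param path integer state vector.
#' @param map probe map aligned to `path`.
#' @param sample_id sample identifier for the emitted calls.
#' @param min_probes minimum probes per call.
#' @param source track label for the calls.
#' @return `cnv_calls` data.frame (without Bayes factors; see
#'   [bayes_factor()]).
#' @export
path_to_calls <- function(path, map, sample_id, min_probes = 3L,
                          source = "A") {
  stopifnot(length(path) == nrow(map))
  out <- list()
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    r <- rle(path[idx])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values != 2L & r$lengths >= min_probes
    if (!any(keep)) next
    out[[length(out) + 1]] <- data.frame(
      sample_id = sample_id, chrom = ch,
      start_bp = map$pos_bp[idx][starts[keep]],
      end_bp = map$pos_bp[idx][ends[keep]],
      cn = r$values[keep], n_probes = r$lengths[keep], bf = NA_real_,
      source = source, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(cnv_calls())
  validate_cnv_calls(do.call(rbind, out))
}

#' Bayes factor of a call
#'
#' Log10 likelihood ratio, over the call's probes only, of the constant
#' called-state path against the constant diploid path, clipped below at
#' zero. Data outside the call's interval never enter the score, and for a
#' clean event the score grows linearly with the number of supporting
#' probes.
#'
#' @param call one-row call (or list with `chrom`, `start_bp`, `end_bp`,
#'   `cn`).
#' @param signal the sample signal the call was made from.
#' @param map probe map.
#' @param params [hmm_params()].
#' @return non-negative Bayes factor (log10 scale).
#' @export
bayes_factor <- function(call, signal, map, params) {
  idx <- which(map$chrom == call$chrom & map$pos_bp >= call$start_bp &
                 map$pos_bp <= call$end_bp)
  if (!length(idx)) stop("call covers zero probes")
  lrr <- signal$lrr[idx]; baf <- signal$baf[idx]
  ll_alt <- sum(emission_loglik(lrr, baf, call$cn, params))
  ll_null <- sum(emission_loglik(lrr, baf, 2L, params))
  max(0, (ll_alt - ll_null) / log(10))
}

#' Call CNVs in one sample
#'
#' Composition Viterbi decoding -> run extraction -> per-call Bayes
#' factor.
#'
#' @param signal sample signal.
#' @param map probe map.
#' @param params [hmm_params()].
#' @param min_probes minimum probes per call.
#' @return `cnv_calls` with `bf` filled and `source` set to the preset.
#' @export
call_sample <- function(signal, map, params, min_probes = 3L) {
  path <- viterbi_path(signal, map, params)
  calls <- path_to_calls(path, map, signal$sample_id, min_probes,
                         source = params$preset)
  if (nrow(calls))
    calls$bf <- vapply(seq_len(nrow(calls)), function(i)
      bayes_factor(calls[i, ], signal, map, params), 0)
  calls
}

#' Call CNVs across a cohort
#'
#' @param signals list of sample signals.
#' @param map probe map.
#' @param params [hmm_params()].
#' @param min_probes minimum probes per call.
#' @return `cnv_calls` for all samples.
#' @export
call_cohort <- function(signals, map, params, min_probes = 3L) {
  out <- lapply(signals, call_sample, map = map, params = params,
                min_probes = min_probes)
  res <- do.call(rbind, out)
  if (is.null(res)) cnv_calls() else res
}
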