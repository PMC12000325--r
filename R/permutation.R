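#' Label-permutation p-values for a trial-label statistic map
#'
#' Shuffles the high/low labels (condition sizes preserved; excluded trials
#' untouched) and recomputes the statistic map for each permutation. The
#' one-sided, add-one-smoothed p-value at each (frequency, time) point is
#' `(1 + #\{perm : stat_perm >= stat_obs\}) / (1 + n_perm)`; the attainable
#' minimum is `1/(n_perm + 1)` and degenerate (all-tied) statistics give
#' p = 1. Null maps are retained for cluster correction.
#'
#' @param analytic an `analytic_map`.
#' @param labels a [label_set()] or label vector.
#' @param stat_fn statistic: `function(analytic, label_vector)` returning a
#'   frequencies x times matrix. Default: the POP map ([pop()]).
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @param channel channel index passed to the default statistic.
#' @return list of class `permutation_result`: `observed` and `p`
#'   (frequencies x times), `null` (n_perm x cells), `freqs`, `times`,
#'   `n_perm`, `seed`.
#' @export
permutation_pvalues <- function(analytic, labels, stat_fn = NULL,
                                n_perm = 1000L, seed = 1L, channel = 1L) {
  stopifnot(inherits(analytic, "analytic_map"))
  n_perm <- as.integer(n_perm)
  if (n_perm < 100L) stop_cfg("`n_perm` must be at least 100")
  d <- dim(analytic$values)
  lab <- as_label_vector(labels, d[1])
  used <- which(lab %in% c("high", "low"))
  if (!length(used)) stop_cfg("no high/low trials")
  if (is.null(stat_fn)) {
    u <- unit_phasors(analytic, channel)
    stat_fn <- function(analytic, lab) {
      ia <- which(lab == "high"); ib <- which(lab == "low")
      sa <- colSums(u[ia, , drop = FALSE]); sb <- colSums(u[ib, , drop = FALSE])
      m <- (Mod(sa) / length(ia)) * (Mod(sb) / length(ib)) -
        (Mod(sa + sb) / (length(ia) + length(ib)))^2
      matrix(m, d[3], d[4])
    }
  }
  obs <- run_stat(stat_fn, analytic, lab, "observed data")
  set.seed(seed)
  null <- matrix(0, n_perm, length(obs))
  for (j in seq_len(n_perm)) {
    lp <- lab
    lp[used] <- lab[sample(used)]
    null[j, ] <- as.numeric(run_stat(stat_fn, analytic, lp,
                                     sprintf("permutation %d", j)))
  }
  pv <- (1 + colSums(null >= matrix(as.numeric(obs), n_perm, length(obs),
                                    byrow = TRUE))) / (1 + n_perm)
  structure(
    list(
      observed = obs, null = null,
      p = matrix(pv, nrow(obs), ncol(obs)),
      freqs = analytic$freqs, times = analytic$times,
      n_perm = n_perm, seed = seed
    ),
    class = "permutation_result"
  )
}

run_stat <- function(stat_fn, analytic, lab, what) {
  out <- tryCatch(stat_fn(analytic, lab), error = function(e) {
    stop("statistic function failed on ", what, ": ", conditionMessage(e),
         call. = FALSE)
  })
  if (is.null(dim(out))) out <- matrix(out, nrow = 1L)
  out
}

# 4-neighbourhood connected components of a logical matrix; 0 = background.
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    while (length(stack)) {
      s <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (lab[s] != 0L) next
      lab[s] <- cur
      r <- ((s - 1L) %% nr) + 1L
      cc <- ((s - 1L) %/% nr) + 1L
      nb <- integer(0)
      if (r > 1L && mask[s - 1L] && lab[s - 1L] == 0L) nb <- c(nb, s - 1L)
      if (r < nr && mask[s + 1L] && lab[s + 1L] == 0L) nb <- c(nb, s + 1L)
      if (cc > 1L && mask[s - nr] && lab[s - nr] == 0L) nb <- c(nb, s - nr)
      if (cc < nc && mask[s + nr] && lab[s + nr] == 0L) nb <- c(nb, s + nr)
      stack <- c(stack, nb)
    }
  }
  lab
}

# p -> T transform: one-sided standard-normal quantile of 1 - p.
p_to_t <- function(p) qnorm(1 - p)

# Cluster scores (sum of T over supra-threshold 4-connected components)
# restricted to `mask`; returns list(labels, scores).
cluster_scores <- function(tmap, threshold, mask) {
  supra <- tmap >= threshold & mask
  lab <- label_components(supra)
  k <- max(lab)
  scores <- if (k > 0L) {
    vapply(seq_len(k), function(i) sum(tmap[lab == i]), numeric(1))
  } else numeric(0)
  list(labels = lab, scores = scores)
}

#' Cluster-based family-wise error correction of a permutation result
#'
#' Point-wise p-values are mapped to T-values through the one-sided
#' standard-normal quantile of 1 - p; supra-threshold (T >= `threshold_T`,
#' default 2, about p ~ 0.05) 4-connected components within the time window
#' of interest are scored by their T-sum. The corrected p of each observed
#' cluster is the add-one-smoothed fraction of permutations whose maximal
#' cluster score reaches it. Permutation p-maps are obtained by ranking each
#' permutation statistic within the same null ensemble.
#'
#' @param perm_result a [permutation_pvalues()] result.
#' @param threshold_T cluster-forming threshold on T.
#' @param window `c(t_min, t_max)` seconds; cells with `t_min <= t < t_max`
#'   enter cluster formation (default the pre-movement half second).
#' @param freq_window optional `c(f_lo, f_hi)` restriction.
#' @return list of class `cluster_result`: `clusters` data.frame (score,
#'   corrected p, extent), `labels` matrix, `null_max` scores, `threshold`.
#' @export
cluster_correct <- function(perm_result, threshold_T = 2,
                            window = c(-0.5, 0), freq_window = NULL) {
  stopifnot(inherits(perm_result, "permutation_result"))
  times <- perm_result$times
  freqs <- perm_result$freqs
  tmask <- times >= window[1] & times < window[2]
  if (!any(tmask)) {
    stop_cfg("cluster window outside the analysed epoch")
  }
  fmask <- if (is.null(freq_window)) rep(TRUE, length(freqs)) else {
    freqs >= freq_window[1] & freqs <= freq_window[2]
  }
  mask <- outer(fmask, tmask, `&`)
  n_perm <- perm_result$n_perm
  t_obs <- p_to_t(perm_result$p)
  obs <- cluster_scores(t_obs, threshold_T, mask)
  # null distribution of the maximal cluster score; each permutation map is
  # ranked within the same pooled ensemble (observed + permutations) that
  # produced the observed p-values, keeping the two exchangeable
  null <- perm_result$null
  obs_vec <- matrix(as.numeric(perm_result$observed), n_perm,
                    ncol(null), byrow = TRUE)
  counts_ge <- apply(null, 2, function(v) {
    n_perm - rank(v, ties.method = "min") + 1
  }) # n_perm x cells: #\{k : v_k >= v_j\}, including self
  p_perm <- (counts_ge + (obs_vec >= null)) / (1 + n_perm)
  null_max <- numeric(n_perm)
  nr <- nrow(t_obs); nc <- ncol(t_obs)
  for (j in seq_len(n_perm)) {
    tj <- matrix(p_to_t(p_perm[j, ]), nr, nc)
    sc <- cluster_scores(tj, threshold_T, mask)$scores
    null_max[j] <- if (length(sc)) max(sc) else 0
  }
  k <- length(obs$scores)
  clusters <- if (k > 0L) {
    data.frame(
      cluster = seq_len(k),
      score = obs$scores,
      p_corrected = vapply(obs$scores, function(s) {
        (1 + sum(null_max >= s)) / (1 + n_perm)
      }, numeric(1)),
      n_cells = vapply(seq_len(k), function(i) sum(obs$labels == i), integer(1)),
      f_min = vapply(seq_len(k), function(i) {
        min(freqs[row(obs$labels)[obs$labels == i]])
      }, numeric(1)),
      f_max = vapply(seq_len(k), function(i) {
        max(freqs[row(obs$labels)[obs$labels == i]])
      }, numeric(1)),
      t_min = vapply(seq_len(k), function(i) {
        min(times[col(obs$labels)[obs$labels == i]])
      }, numeric(1)),
      t_max = vapply(seq_len(k), function(i) {
        max(times[col(obs$labels)[obs$labels == i]])
      }, numeric(1))
    )
  } else {
    data.frame(
      cluster = integer(), score = numeric(), p_corrected = numeric(),
      n_cells = integer(), f_min = numeric(), f_max = numeric(),
      t_min = numeric(), t_max = numeric()
    )
  }
  structure(
    list(
      clusters = clusters[order(clusters$p_corrected), , drop = FALSE],
      labels = obs$labels, null_max = null_max,
      threshold = threshold_T, window = window
    ),
    class = "cluster_result"
  )
}

#' Group-level phase opposition test across subjects
#'
#' Averages the observed POP over a declared frequency x time window within
#' each subject, then across subjects; the same window average is computed
#' for each within-subject label permutation (permutation j of every subject
#' contributes to group permutation j), and the group p-value counts larger
#' permuted group means (add-one smoothing).
#'
#' @param results list of per-subject [permutation_pvalues()] results (same
#'   `n_perm` everywhere; subjects with missing nulls are dropped with a
#'   warning).
#' @param freq_window,time_window analysis window; defaults 8-13 Hz and the
#'   pre-movement half second.
#' @return list: `p`, `observed` group mean, `null` group means,
#'   `n_subjects`.
#' @export
group_pop_test <- function(results, freq_window = c(8, 13),
                           time_window = c(-0.5, 0)) {
  ok <- vapply(results, function(r) {
    inherits(r, "permutation_result") && !is.null(r$null)
  }, logical(1))
  if (!all(ok)) {
    warning(sum(!ok), " subject(s) without retained null maps excluded")
    results <- results[ok]
  }
  if (!length(results)) stop_cfg("no usable subjects")
  n_perm <- unique(vapply(results, function(r) as.integer(r$n_perm), integer(1)))
  if (length(n_perm) != 1L) stop_cfg("all subjects must share the permutation count")
  win_mean <- function(r, v) {
    m <- matrix(v, length(r$freqs), length(r$times))
    fm <- r$freqs >= freq_window[1] & r$freqs <= freq_window[2]
    tm <- r$times >= time_window[1] & r$times < time_window[2]
    if (!any(fm) || !any(tm)) stop_cfg("empty analysis window for a subject")
    mean(m[fm, tm])
  }
  obs <- mean(vapply(results, function(r) win_mean(r, r$observed), numeric(1)))
  null <- rowMeans(vapply(results, function(r) {
    apply(r$null, 1, function(v) win_mean(r, v))
  }, numeric(n_perm)))
  list(
    p = (1 + sum(null >= obs)) / (1 + n_perm),
    observed = obs, null = null, n_subjects = length(results)
  )
}

#' Two-sample power contrast with cluster correction
#'
#' Two-sample t statistic (pooled variance) on instantaneous power
#' (squared analytic amplitude) at every (frequency, time) point, high vs
#' low trials, with label-permutation cluster correction on |t| >=
#' `threshold_T`. Zero-variance cells yield t = 0 and are flagged.
#'
#' @param analytic an `analytic_map`.
#' @param labels a [label_set()] or label vector.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param threshold_T cluster-forming threshold on |t|.
#' @param window time window for cluster formation (default whole epoch).
#' @param channel channel index.
#' @return list of class `power_contrast`: `t_map`, `clusters`
#'   (data.frame with corrected p), `null_max`, `degenerate` mask.
#' @export
power_contrast <- function(analytic, labels, n_perm = 1000L, seed = 1L,
                           threshold_T = 2, window = NULL, channel = 1L) {
  stopifnot(inherits(analytic, "analytic_map"))
  d <- dim(analytic$values)
  lab <- as_label_vector(labels, d[1])
  ia <- which(lab == "high"); ib <- which(lab == "low")
  if (length(ia) < 2L || length(ib) < 2L) stop_cfg("need >= 2 trials per condition")
  v <- analytic$values[, channel, , , drop = FALSE]
  dim(v) <- c(d[1], d[3] * d[4])
  pw <- Mod(v)^2
  tstat <- function(ia, ib) {
    xa <- pw[ia, , drop = FALSE]; xb <- pw[ib, , drop = FALSE]
    na <- nrow(xa); nb <- nrow(xb)
    ma <- colMeans(xa); mb <- colMeans(xb)
    va <- colSums(sweep(xa, 2, ma)^2); vb <- colSums(sweep(xb, 2, mb)^2)
    sp2 <- (va + vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    t <- (ma - mb) / se
    t[se == 0] <- 0
    t
  }
  t_obs <- tstat(ia, ib)
  degenerate <- {
    xa <- pw[ia, , drop = FALSE]; xb <- pw[ib, , drop = FALSE]
    apply(xa, 2, var) + apply(xb, 2, var) == 0
  }
  used <- c(ia, ib)
  set.seed(seed)
  times <- analytic$times
  window <- window %||% c(min(times), max(times) + 1 / analytic$fs)
  tmask <- times >= window[1] & times < window[2]
  mask <- matrix(rep(tmask, each = d[3]), d[3], d[4])
  obs <- cluster_scores(matrix(abs(t_obs), d[3], d[4]), threshold_T, mask)
  null_max <- numeric(n_perm)
  for (j in seq_len(n_perm)) {
    sh <- sample(used)
    tj <- abs(tstat(sh[seq_along(ia)], sh[-seq_along(ia)]))
    sc <- cluster_scores(matrix(tj, d[3], d[4]), threshold_T, mask)$scores
    null_max[j] <- if (length(sc)) max(sc) else 0
  }
  k <- length(obs$scores)
  clusters <- data.frame(
    cluster = seq_len(k),
    score = obs$scores,
    p_corrected = vapply(obs$scores, function(s) {
      (1 + sum(null_max >= s)) / (1 + n_perm)
    }, numeric(1))
  )
  structure(
    list(
      t_map = matrix(t_obs, d[3], d[4]),
      clusters = clusters[order(clusters$p_corrected), , drop = FALSE],
      labels = obs$labels, null_max = null_max,
      degenerate = matrix(degenerate, d[3], d[4]),
      freqs = analytic$freqs, times = times
    ),
    class = "power_contrast"
  )
}
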