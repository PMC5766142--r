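# Independent brute-force oracles used to check the package's
# implementations. Deliberately written as plain loops with no shared code.

# long count tibble from site positions and meth/depth matrices
# (sites in rows, samples in columns)
make_counts <- function(pos, meth, depth, samples = NULL, chrom = "c1") {
  samples <- samples %||% sprintf("s%02d", seq_len(ncol(meth)))
  pos_col <- rep(as.integer(pos), times = length(samples))
  sample_col <- rep(samples, each = length(pos))
  tibble::tibble(
    chrom = chrom,
    pos = pos_col,
    sample = sample_col,
    meth = as.integer(meth),
    depth = as.integer(depth)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_design <- function(samples, genotype, treatment) {
  tibble::tibble(sample = samples, genotype = genotype,
                 treatment = treatment)
}

# literal restatement of the greedy merge rule: singletons, left-to-right
# sweep, complete-linkage Spearman with a depth filter, repeat to fixed point
oracle_cluster <- function(pos, meth, depth, max_gap = 1000, thr = 0.5,
                           min_sites = 3, min_depth = 5) {
  prop <- meth / ifelse(depth == 0, NA, depth)
  pair_cor <- function(i, j) {
    s <- which(depth[i, ] >= min_depth & depth[j, ] >= min_depth &
                 !is.na(prop[i, ]) & !is.na(prop[j, ]))
    if (length(s) < 3) return(-Inf)
    r <- suppressWarnings(stats::cor(prop[i, s], prop[j, s],
                                     method = "spearman"))
    if (is.na(r)) -Inf else r
  }
  cl <- as.list(seq_along(pos))
  repeat {
    changed <- FALSE
    i <- 1
    while (i < length(cl)) {
      a <- cl[[i]]; b <- cl[[i + 1]]
      ok <- (pos[b[1]] - pos[a[length(a)]]) <= max_gap
      if (ok) {
        m <- Inf
        for (x in a) for (y in b) m <- min(m, pair_cor(x, y))
        ok <- m >= thr
      }
      if (ok) {
        cl[[i]] <- c(a, b)
        cl[[i + 1]] <- NULL
        changed <- TRUE
      } else {
        i <- i + 1
      }
    }
    if (!changed) break
  }
  cl[lengths(cl) >= min_sites]
}

# BH step-up by direct application of the formula
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) if (n > 1) {
    q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  }
  q_sorted <- pmin(q_sorted, 1)
  out <- numeric(n)
  out[o] <- q_sorted
  out
}

# exact binomial tail by full outcome enumeration (binom.test's definition:
# the two-sided p sums all outcomes no more likely than the observed one)
oracle_binom <- function(k, n, p0, alternative) {
  probs <- dbinom(0:n, n, p0)
  if (alternative == "greater") {
    sum(probs[(k:n) + 1])
  } else if (alternative == "less") {
    sum(probs[0:k + 1])
  } else {
    sum(probs[probs <= probs[k + 1] * (1 + 1e-7)])
  }
}

# weighted beta log-likelihood evaluated directly (shared shrinkage and
# weight-normalization conventions, independent arithmetic)
oracle_loglik <- function(y, w, x, beta0, beta1, phi) {
  n <- length(y)
  w <- n * w / sum(w)
  yp <- (y * (n - 1) + 0.5) / n
  mu <- plogis(beta0 + beta1 * x)
  sum(w * dbeta(yp, mu * phi, (1 - mu) * phi, log = TRUE))
}

# O(n*m) interval overlap check
oracle_overlaps <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    any(b$chrom == a$chrom[i] & b$start < a$end[i] & b$end > a$start[i])
  }, logical(1))
}

# group sample labels for the simulated design
sim_groups <- function(design) paste(design$genotype, design$treatment, sep = "_")

# summarize the generator's planted clusters directly from ground truth,
# bypassing the clustering stage
truth_clusters_summarized <- function(dataset) {
  tc <- dataset$truth$clusters
  cl <- tibble::tibble(cluster_id = tc$cluster_id, chrom = tc$chrom,
                       start = tc$start, end = tc$end, n_sites = tc$n_sites,
                       positions = tc$positions)
  summarize_clusters(cl, dataset$counts)
}
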