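# Independent brute-force oracles and small fixture builders.
# These deliberately avoid the package's cumulative-sum correlation kernel
# and vectorised scans: correlations go through stats::cor, scans through
# plain nested loops.

make_track <- function(values, chrom_sizes, read_length = 36L) {
  binned_track(values, chrom_sizes, window_bp = 100L, step_bp = 50L,
               read_length = read_length)
}

# group of 3 tracks on one chromosome from a list of value vectors
make_group <- function(v1, v2, v3, chrom_len = NULL, condition = "cond") {
  if (is.null(chrom_len)) chrom_len <- (length(v1) - 1) * 50 + 100
  cs <- c(chr1 = chrom_len)
  replicate_group(list(make_track(list(chr1 = v1), cs),
                       make_track(list(chr1 = v2), cs),
                       make_track(list(chr1 = v3), cs)), condition)
}

# brute-force meanCE: log/zero gating + stats::cor, zero-variance pairs -> 0
oracle_meance <- function(vectors, T) {
  vs <- lapply(vectors, function(x) ifelse(x >= T, log(x), 0))
  k <- length(vs)
  vals <- c()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (stats::sd(vs[[i]]) == 0 || stats::sd(vs[[j]]) == 0) {
      vals <- c(vals, 0)
    } else {
      vals <- c(vals, stats::cor(vs[[i]], vs[[j]]))
    }
  }
  mean(vals)
}

# brute-force region caller for a single chromosome: nested-loop density
# scan over the composite mask, oracle meanCE filter, then sweep-merge
oracle_call_regions <- function(values_list, T, f = 2 / 3,
                                density_bins = 40L, density_span_bp = 4000L,
                                window_bp = 100L, step_bp = 50L) {
  n <- length(values_list[[1]])
  n_rep <- length(values_list)
  mask <- logical(n)
  for (w in seq_len(n)) {
    cnt <- sum(vapply(values_list, function(v) v[w] >= T, logical(1)))
    mask[w] <- cnt / n_rep >= f - 1e-12
  }
  idx <- which(mask)
  cands <- list()
  if (length(idx) >= density_bins) {
    for (i in 1:(length(idx) - density_bins + 1)) {
      first <- idx[i]; last <- idx[i + density_bins - 1]
      if ((last - first) * step_bp <= density_span_bp) {
        start <- (first - 1) * step_bp
        end <- (last - 1) * step_bp + window_bp
        vecs <- lapply(values_list, function(v) v[first:last])
        mce <- oracle_meance(vecs, T)
        if (mce > 0)
          cands[[length(cands) + 1]] <- c(start = start, end = end,
                                          mce = mce)
      }
    }
  }
  if (!length(cands))
    return(data.frame(start = integer(0), end = integer(0),
                      mean_ce = numeric(0), n_ceds = integer(0)))
  cd <- as.data.frame(do.call(rbind, cands))
  names(cd) <- c("start", "end", "mce")
  cd <- unique(cd)
  cd <- cd[order(cd$start, cd$end), , drop = FALSE]
  regions <- list()
  cur <- cd[1, ]
  members <- c(cd$mce[1])
  if (nrow(cd) > 1) for (i in 2:nrow(cd)) {
    if (cd$start[i] < cur$end) {
      cur$end <- max(cur$end, cd$end[i])
      members <- c(members, cd$mce[i])
    } else {
      regions[[length(regions) + 1]] <-
        data.frame(start = cur$start, end = cur$end,
                   mean_ce = mean(members), n_ceds = length(members))
      cur <- cd[i, ]; members <- c(cd$mce[i])
    }
  }
  regions[[length(regions) + 1]] <-
    data.frame(start = cur$start, end = cur$end,
               mean_ce = mean(members), n_ceds = length(members))
  out <- do.call(rbind, regions)
  rownames(out) <- NULL
  out
}

# random patchy replicate tracks on a short chromosome: Poisson background
# with a few rectangular enriched stretches
random_patchy_tracks <- function(n_windows = 399L, background = 18,
                                 enriched = 80, n_patches = 3L) {
  rate <- rep(background, n_windows)
  for (p in seq_len(n_patches)) {
    w <- sample(30:120, 1)
    s <- sample(1:(n_windows - w), 1)
    rate[s:(s + w - 1)] <- enriched * stats::runif(1, 0.5, 1.5)
  }
  lapply(1:3, function(r) as.numeric(stats::rpois(n_windows, rate)))
}
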