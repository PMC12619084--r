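# Independent brute-force oracles used across the suite. These stay
# deliberately naive (per-sample / per-row loops) so that they cannot
# share a defect with the vectorised implementations they check.

# Naive per-sample scan of an amplitude envelope: walk the trace, collect
# supra-threshold samples, close a run when the gap since the last supra
# sample exceeds gap_n, keep runs strictly longer than min_dur_s.
brute_scan_events <- function(env, fs, threshold, gap_s, min_dur_s) {
  gap_n <- round(gap_s * fs)
  runs <- list()
  first <- NA_integer_; last <- NA_integer_
  for (i in seq_along(env)) {
    if (env[i] > threshold) {
      if (is.na(first)) first <- i
      else if (i - last - 1L > gap_n) {
        runs[[length(runs) + 1L]] <- c(first, last)
        first <- i
      }
      last <- i
    }
  }
  if (!is.na(first)) runs[[length(runs) + 1L]] <- c(first, last)
  out <- data.frame(onset_s = numeric(0), offset_s = numeric(0))
  for (r in runs) {
    onset <- (r[1] - 1) / fs; offset <- r[2] / fs
    if (offset - onset > min_dur_s)
      out <- rbind(out, data.frame(onset_s = onset, offset_s = offset))
  }
  out
}

# Double-loop KS statistic: max |ECDF_x - ECDF_y| over pooled points.
brute_ks_D <- function(x, y) {
  pts <- c(x, y)
  D <- 0
  for (p in pts) {
    d <- abs(mean(x <= p) - mean(y <= p))
    if (d > D) D <- d
  }
  D
}

# Exact permutation p-value for the two-sample KS D by full enumeration
# of group assignments.
exact_perm_ks_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  Dobs <- brute_ks_D(x, y)
  idx <- utils::combn(length(pooled), n1)
  Ds <- apply(idx, 2, function(i) brute_ks_D(pooled[i], pooled[-i]))
  mean(Ds >= Dobs - 1e-12)
}

# Row-by-row filter-chain scan on an expression experiment.
brute_filter_chain <- function(ip, input, de_stats, fpkm_min = 1,
                               lfc_min = 1, alpha = 0.05,
                               ratio_threshold = 2) {
  ids <- rownames(ip$fpkm)
  expressed <- character(0)
  for (g in ids)
    if (all(ip$fpkm[g, ] > fpkm_min)) expressed <- c(expressed, g)
  degs <- character(0)
  for (g in expressed) {
    row <- de_stats[de_stats$gene_id == g, ]
    if (abs(row$log2fc) >= lfc_min && row$adj_p < alpha)
      degs <- c(degs, g)
  }
  enriched <- character(0)
  for (g in degs) {
    r <- mean(ip$fpkm[g, ]) / mean(input$fpkm[g, ])
    if (r > ratio_threshold) enriched <- c(enriched, g)
  }
  list(expressed = expressed, degs = degs, enriched = enriched)
}

# Match detected against truth intervals: each truth event must pair with
# exactly one detection whose onset and offset are both within tol_s.
match_events <- function(truth, detected, tol_s = 1) {
  if (nrow(truth) != nrow(detected)) return(FALSE)
  if (!nrow(truth)) return(TRUE)
  all(abs(truth$onset_s - detected$onset_s) <= tol_s &
        abs(truth$offset_s - detected$offset_s) <= tol_s)
}

# A deterministic noise-free test signal: sinusoidal bursts with hard
# edges at the stated intervals, zero elsewhere.
burst_signal <- function(duration_s, fs, bursts, amp = 5, freq = 8) {
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  for (i in seq_len(nrow(bursts))) {
    sel <- t >= bursts$onset_s[i] & t < bursts$offset_s[i]
    x[sel] <- amp * sin(2 * pi * freq * t[sel])
  }
  x
}
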