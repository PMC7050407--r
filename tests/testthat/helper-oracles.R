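# Independent brute-force oracles used to cross-check the implementation.

# BH adjusted p-values from the definition: for each p_i, the minimum over
# rejection thresholds t >= p_i (taken over the observed p-values) of
# m * t / #{p_j <= t}, capped at 1.
bh_brute <- function(p) {
  m <- length(p)
  vapply(p, function(pi) {
    ts <- sort(unique(p[p >= pi]))
    min(1, min(vapply(ts, function(t) m * t / sum(p <= t), 0)))
  }, 0)
}

# Distinct-UMI molecule count.
dedup_unique_brute <- function(umis) length(unique(umis))

# Directional UMI collapse, written independently: explicit adjacency
# matrix (Hamming distance 1 and count(parent) >= 2*count(child) - 1),
# then roots found by absorbing reachable nodes from the largest
# unclaimed node.
dedup_directional_brute <- function(umis) {
  tab <- sort(table(umis), decreasing = TRUE)
  u <- names(tab)
  # stable tie-break on the string to mirror a deterministic sort
  o <- order(-as.integer(tab), u)
  u <- u[o]
  cnt <- as.integer(tab)[o]
  k <- length(u)
  ham <- function(a, b) sum(utf8ToInt(a) != utf8ToInt(b))
  adj <- matrix(FALSE, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i != j && ham(u[i], u[j]) == 1 && cnt[i] >= 2 * cnt[j] - 1)
      adj[i, j] <- TRUE
  }
  claimed <- logical(k)
  roots <- 0L
  for (i in seq_len(k)) {
    if (claimed[i]) next
    roots <- roots + 1L
    frontier <- i
    claimed[i] <- TRUE
    while (length(frontier)) {
      nxt <- integer(0)
      for (x in frontier) {
        reach <- which(adj[x, ] & !claimed)
        claimed[reach] <- TRUE
        nxt <- c(nxt, reach)
      }
      frontier <- nxt
    }
  }
  roots
}

# Re-scan of the testability filter straight from the rules.
filter_brute <- function(counts, calls, samples, min_het = 5,
                         min_reads = 10) {
  keep_snps <- character(0)
  for (s in unique(counts$variantID)) {
    d <- counts[counts$variantID == s, ]
    subj <- samples$subject_id[match(d$sample, samples$sample_id)]
    grp <- samples$group[match(d$sample, samples$sample_id)]
    ok <- logical(nrow(d))
    for (i in seq_len(nrow(d))) {
      gcall <- if (subj[i] %in% colnames(calls) && s %in% rownames(calls))
        calls[s, subj[i]] else "missing"
      ok[i] <- gcall == "het" && (d$refCount[i] + d$altCount[i]) > min_reads
    }
    if (sum(ok & grp == "AUD") >= min_het &&
        sum(ok & grp != "AUD") >= min_het)
      keep_snps <- c(keep_snps, s)
  }
  sort(keep_snps)
}

# Row filter for significance classification.
classify_brute <- function(results, fdr = 0.05, min_abs = 1) {
  keep <- logical(nrow(results))
  for (i in seq_len(nrow(results))) {
    keep[i] <- !is.na(results$q_value[i]) && results$q_value[i] < fdr &&
      !is.na(results$adj_log2_fc[i]) && abs(results$adj_log2_fc[i]) > min_abs
  }
  results[keep, , drop = FALSE]
}
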