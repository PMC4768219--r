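# Independent brute-force oracles used to validate the fast implementations.

# Score one window of `pwm` starting at 0-based `offset` of `seq` (forward
# strand), position by position; NA if the window contains a non-ACGT base.
oracle_window_score <- function(seq, pwm, offset) {
  bases <- strsplit(toupper(seq), "")[[1]]
  win <- bases[(offset + 1):(offset + pwm$width)]
  if (any(!win %in% c("A", "C", "G", "T"))) return(NA_real_)
  sum(vapply(seq_len(pwm$width), function(j)
    pwm$logodds[win[j], j], numeric(1)))
}

# Exhaustive both-strand enumeration of PWM hits.
oracle_scan <- function(seq, pwm, rel_threshold) {
  L <- nchar(seq)
  w <- pwm$width
  if (L < w) return(data.frame(offset = integer(), strand = character(),
                               score = numeric(), stringsAsFactors = FALSE))
  cutoff <- rel_threshold * pwm_max_score(pwm)
  rows <- list()
  for (o in 0:(L - w)) {
    fs <- oracle_window_score(seq, pwm, o)
    if (!is.na(fs) && fs >= cutoff)
      rows[[length(rows) + 1]] <- data.frame(offset = o, strand = "+",
                                             score = fs)
    win <- substr(seq, o + 1, o + w)
    if (!grepl("[^ACGTacgt]", win)) {
      rs <- oracle_window_score(revcomp(win), pwm, 0)
      if (!is.na(rs) && rs >= cutoff)
        rows[[length(rows) + 1]] <- data.frame(offset = o, strand = "-",
                                               score = rs)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(offset = integer(), strand = character(),
                         score = numeric())
  out <- out[order(out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Quadratic all-pairs half-open interval overlap.
oracle_assign <- function(peaks, windows) {
  rows <- list()
  for (i in seq_len(nrow(peaks))) {
    for (j in seq_len(nrow(windows))) {
      if (peaks$chrom[i] != windows$chrom[j]) next
      ov <- min(peaks$end[i], windows$end[j]) -
        max(peaks$start[i], windows$start[j])
      if (ov >= 1)
        rows[[length(rows) + 1]] <- data.frame(
          gene_id = windows$gene_id[j], peak_name = peaks$name[i],
          stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(data.frame(gene_id = character(),
                                       peak_name = character()))
  out <- do.call(rbind, rows)
  out[order(out$gene_id, out$peak_name), , drop = FALSE]
}

# Canonical (gene, peak) key set for comparing assignment outputs that may
# use different within-gene orderings.
assignment_keys <- function(df) {
  sort(paste(df$gene_id, df$peak_name, sep = "|"))
}

# Hypergeometric upper tail by direct PMF summation (N small).
oracle_hyper_tail <- function(k, n, K, N) {
  if (k == 0) return(1)
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Textbook pooled-variance two-sample t test.
oracle_pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = n1 + n2 - 2, p = 2 * pt(-abs(t), n1 + n2 - 2))
}

random_dna <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# Expected downstream classification label for a planted regulation mode,
# where genes not modulated by TNF carry no mode.
expected_label <- function(true_mode) {
  map <- c(co_activated = "enhanced_activation",
           co_repressed = "enhanced_repression",
           suppressed_activation = "suppressed_activation",
           relieved_repression = "relieved_repression",
           tnf_only_up = "unaffected", tnf_only_down = "unaffected",
           hs_only_up = "not_tnf_modulated",
           hs_only_down = "not_tnf_modulated",
           null = "not_tnf_modulated")
  unname(map[true_mode])
}

# Predicted label in the same vocabulary from a cross-talk record table.
predicted_label <- function(records) {
  ifelse(records$call_tnf == "none", "not_tnf_modulated", records$mode)
}
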