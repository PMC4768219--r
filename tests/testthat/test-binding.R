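test_that("regulatory windows are strand-aware, clipped and mirror-symmetric", {
  ann <- data.frame(gene_id = c("a", "b", "c"), chrom = "chr1",
                    tss = c(10000, 10000, 3000),
                    strand = c("+", "-", "+"), stringsAsFactors = FALSE)
  w <- make_windows(ann)
  expect_equal(w$start, c(2500, 7500, 0))
  expect_equal(w$end, c(12500, 17500, 5500))
  expect_equal(w$end - w$start, c(10000, 10000, 5500))

  # mirror symmetry: reflect coordinates around L and flip strand
  L <- 100000
  ann_m <- data.frame(gene_id = "a", chrom = "chr1", tss = L - 10000,
                      strand = "-", stringsAsFactors = FALSE)
  wm <- make_windows(ann_m)
  expect_equal(wm$start, L - w$end[1])
  expect_equal(wm$end, L - w$start[1])
})

test_that("peak assignment uses half-open 1-bp overlap and matches the oracle", {
  win <- data.frame(gene_id = "g", chrom = "chr1", start = 2500,
                    end = 12500, strand = "+", stringsAsFactors = FALSE)
  pk <- function(s, e) data.frame(chrom = "chr1", start = s, end = e,
                                  name = "p", score = 1,
                                  stringsAsFactors = FALSE)
  expect_equal(nrow(assign_peaks(pk(12499, 12600), win)), 1)
  expect_equal(nrow(assign_peaks(pk(12500, 12600), win)), 0)
  expect_equal(nrow(assign_peaks(pk(2400, 2501), win)), 1)
  expect_equal(nrow(assign_peaks(pk(2400, 2500), win)), 0)

  set.seed(51)
  for (rep_i in 1:10) {
    np <- sample(1:25, 1); nw <- sample(1:10, 1)
    peaks <- data.frame(
      chrom = sample(c("chr1", "chr2"), np, replace = TRUE),
      start = sample(0:5000, np), stringsAsFactors = FALSE)
    peaks$end <- peaks$start + sample(1:800, np, replace = TRUE)
    peaks$name <- sprintf("p%02d", seq_len(np))
    peaks$score <- runif(np)
    wins <- data.frame(
      gene_id = sprintf("g%02d", seq_len(nw)),
      chrom = sample(c("chr1", "chr2"), nw, replace = TRUE),
      start = sample(0:5000, nw), stringsAsFactors = FALSE)
    wins$end <- wins$start + sample(500:3000, nw, replace = TRUE)
    got <- suppressWarnings(assign_peaks(peaks, wins))
    want <- oracle_assign(peaks, wins)
    expect_equal(nrow(got), nrow(want))
    expect_equal(assignment_keys(got), assignment_keys(want))
    # output ordering contract: by gene, then peak start
    if (nrow(got) > 0)
      expect_equal(got$peak_start,
                   unlist(tapply(got$peak_start, got$gene_id, sort,
                                 simplify = FALSE)), ignore_attr = TRUE)
  }

  # assignment is invariant to input order and to peak duplication removal
  peaks2 <- peaks[sample(nrow(peaks)), ]
  got2 <- suppressWarnings(assign_peaks(peaks2, wins))
  expect_equal(got2, suppressWarnings(assign_peaks(peaks, wins)))

  expect_warning(
    assign_peaks(data.frame(chrom = "chrX", start = 0, end = 100,
                            name = "p", score = 1),
                 win), "absent")
})

test_that("Poisson peak caller: tail p-values, null identity, planted signal", {
  # identical track and reference: nothing can be significant
  tr <- data.frame(chrom = "chr1", start = seq(0, 990, 10),
                   end = seq(10, 1000, 10), count = rpois(100, 10))
  expect_equal(nrow(call_peaks_simple(tr, tr, fdr = 0.05)), 0)

  # a clearly enriched run of bins is recovered as one merged peak
  set.seed(53)
  tt <- simulate_tag_tracks(500, bin_width = 100, lambda = 10,
                            enriched_bins = 201:205, fold = 8)
  peaks <- call_peaks_simple(tt$track, tt$reference, fdr = 0.05)
  expect_gte(nrow(peaks), 1)
  top <- peaks[which.max(peaks$score), ]
  expect_lte(top$start, 200 * 100)
  expect_gte(top$end, 205 * 100)

  # the per-bin p-value is the Poisson upper tail at the scaled rate
  ref <- data.frame(chrom = "c", start = (0:99) * 10, end = (1:100) * 10,
                    count = rep(5L, 100))
  trk <- ref; trk$count <- rep(4L, 100); trk$count[7] <- 15L
  scale <- sum(trk$count) / sum(ref$count)
  p_expected <- ppois(14, scale * 5, lower.tail = FALSE)
  pk <- call_peaks_simple(trk, ref, fdr = 0.5)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$score, -log10(min(p.adjust(
    ppois(trk$count - 1, pmax(scale * ref$count, scale * mean(ref$count)),
          lower.tail = FALSE), "BH"))), tolerance = 1e-10)
  expect_equal(10 ^ (-pk$score),
               p_expected * 100 / 1, tolerance = 1e-8)  # BH with rank 1

  expect_error(call_peaks_simple(trk, transform(ref, count = 0)), "depth")
})

test_that("induced-binding calls honour both evidence routes", {
  cfg <- sim_config(n_genes = 150, rng_seed = 55)
  truth <- simulate_truth(cfg)
  ann <- simulate_annotation(cfg)
  windows <- make_windows(ann)
  b <- simulate_binding(cfg, truth, ann)
  calls <- call_induced_binding(b$peaks, windows)
  expect_true(all(calls$induced_any ==
                    (calls$induced_hs10 | calls$induced_hs20)))
  expect_true(all(calls$induced_any[truth$binding_induced]))
  expect_lt(mean(calls$induced_any[!truth$binding_induced]), 0.05)

  # identical peak sets across conditions: no induction anywhere
  same <- list(Ctr = b$peaks$HS_10, HS_10 = b$peaks$HS_10,
               HS_20 = b$peaks$HS_10)
  none <- call_induced_binding(same, windows)
  expect_false(any(none$induced_any))

  # tag-count route: windows with heat-shock-only tags are induced
  set.seed(56)
  nb <- 2000
  bins <- data.frame(chrom = "chrS1", start = (seq_len(nb) - 1) * 100,
                     end = seq_len(nb) * 100)
  hot <- unlist(lapply(which(truth$binding_induced[1:10]), function(i)
    which(bins$start >= windows$start[i] & bins$end <= windows$end[i])))
  rate <- rep(5, nb); rate[hot] <- 50
  tracks <- list(
    Ctr = transform(bins, count = rpois(nb, 5)),
    HS_10 = transform(bins, count = rpois(nb, rate)),
    HS_20 = transform(bins, count = rpois(nb, rate)))
  calls_t <- call_induced_binding(b$peaks, windows[1:10, ],
                                  method = "tags", tracks = tracks)
  expect_true(all(calls_t$induced_any[truth$binding_induced[1:10]]))

  expect_error(call_induced_binding(b$peaks[c("Ctr", "HS_10")], windows),
               "conditions")
})
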