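test_that("config validation rejects inconsistent settings", {
  expect_error(sim_config(n_replicates = 1), "n_replicates")
  expect_error(sim_config(noise_sd = -1), "deviations")
  expect_error(sim_config(promoter_length = 500), "promoter_length")
  bad_frac <- c(co_activated = 0.5, co_repressed = 0.3,
                suppressed_activation = 0.3, relieved_repression = 0,
                tnf_only_up = 0, tnf_only_down = 0, hs_only_up = 0,
                hs_only_down = 0, null = 0)
  expect_error(sim_config(mode_fractions = bad_frac), "sum to 1")
})

test_that("annotation generation handles empty, seeded and spaced cases", {
  cfg0 <- sim_config(n_genes = 0)
  expect_equal(nrow(simulate_annotation(cfg0)), 0)

  cfg <- sim_config(n_genes = 100, rng_seed = 1)
  a1 <- simulate_annotation(cfg)
  a2 <- simulate_annotation(cfg)
  expect_identical(a1, a2)

  # all pairwise TSS distances at least the configured spacing (brute force)
  d <- abs(outer(a1$tss, a1$tss, "-"))
  expect_true(all(d[upper.tri(d)] >= 20000))

  expect_error(simulate_annotation(sim_config(n_genes = 100,
                                              chrom_length = 50000)),
               "cannot hold")
})

test_that("expression encodes planted modes with correct noise scaling", {
  # zero noise: null genes identical across conditions, co-activated genes
  # exceed the combined-vs-cytokine margin by construction
  cfg <- sim_config(n_genes = 200, noise_sd = 0, effect_log2fc = 1,
                    rng_seed = 3)
  truth <- simulate_truth(cfg)
  ex <- simulate_expression(cfg, truth)
  cond_mean <- function(cond) {
    s <- ex$sample_map$sample_id[ex$sample_map$condition == cond]
    rowMeans(ex$matrix[, s, drop = FALSE])
  }
  nulls <- truth$true_mode == "null"
  spread <- apply(ex$matrix[nulls, , drop = FALSE], 1, function(x)
    diff(range(x)))
  expect_true(all(spread == 0))
  coact <- truth$true_mode == "co_activated"
  expect_true(any(coact))
  expect_true(all((cond_mean("HS_TNF") - cond_mean("TNF"))[coact] >
                    log2(1.2)))

  # sampling variance of the contrast of replicate means matches the
  # closed form noise_sd * sqrt(2 / R)
  cfg2 <- sim_config(n_genes = 1000, noise_sd = 0.25, rng_seed = 5,
                     baseline_sd = 0,
                     mode_fractions = c(co_activated = 0, co_repressed = 0,
                                        suppressed_activation = 0,
                                        relieved_repression = 0,
                                        tnf_only_up = 0, tnf_only_down = 0,
                                        hs_only_up = 0, hs_only_down = 0,
                                        null = 1))
  truth2 <- simulate_truth(cfg2)
  ex2 <- simulate_expression(cfg2, truth2)
  s <- function(cond) ex2$sample_map$sample_id[
    ex2$sample_map$condition == cond]
  diffs <- rowMeans(ex2$matrix[, s("TNF")]) - rowMeans(ex2$matrix[, s("Ctr")])
  expected_sd <- 0.25 * sqrt(2 / cfg2$n_replicates)
  expect_lt(abs(sd(diffs) - expected_sd) / expected_sd, 0.1)
})

test_that("mode frequencies follow the configured fractions", {
  cfg <- sim_config(n_genes = 5000, rng_seed = 11)
  truth <- simulate_truth(cfg)
  freq <- table(factor(truth$true_mode, levels = names(cfg$mode_fractions)))
  freq <- as.numeric(freq) / cfg$n_genes
  expected <- as.numeric(cfg$mode_fractions)
  # multinomial tolerance: 4 sd of each proportion
  tol <- 4 * sqrt(expected * (1 - expected) / cfg$n_genes)
  expect_true(all(abs(freq - expected) <= pmax(tol, 1e-3)))
})

test_that("promoters carry planted consensus instances and are reproducible", {
  cfg <- sim_config(n_genes = 40, rng_seed = 9)
  truth <- simulate_truth(cfg)
  p1 <- simulate_promoters(cfg, truth)
  p2 <- simulate_promoters(cfg, truth)
  expect_identical(p1, p2)
  expect_true(all(nchar(p1$sequences) == cfg$promoter_length))

  # a recorded plant puts the consensus (or its reverse complement) at the
  # recorded offset
  kb <- kb_pwm()
  pl <- p1$plants[p1$plants$motif == "kb", ]
  expect_true(nrow(pl) > 0)
  for (i in seq_len(nrow(pl))) {
    seq <- p1$sequences[[pl$gene_id[i]]]
    ins <- substr(seq, pl$offset[i] + 1, pl$offset[i] + kb$width)
    expected <- if (pl$strand[i] == "+") consensus_seq(kb)
                else revcomp(consensus_seq(kb))
    expect_identical(ins, expected)
  }

  expect_error(simulate_promoters(sim_config(n_genes = 5,
                                             promoter_length = 1000),
                                  truth[1:5, ],
                                  pwms = list(kb = build_hse_pwm(300))),
               "shorter")
})

test_that("binding simulation plants induced peaks inside regulatory windows", {
  cfg <- sim_config(n_genes = 120, rng_seed = 13)
  truth <- simulate_truth(cfg)
  ann <- simulate_annotation(cfg)
  b <- simulate_binding(cfg, truth, ann)
  widths <- unlist(lapply(b$peaks, function(p) p$end - p$start))
  expect_true(all(widths >= 200 & widths <= 800))

  windows <- make_windows(ann)
  for (g in b$planted$gene_id) {
    w <- windows[windows$gene_id == g, ]
    p <- b$planted[b$planted$gene_id == g, ]
    expect_true(min(p$end, w$end) - max(p$start, w$start) >= 1)
  }
  # every induced gene has at least one HS peak overlapping its window
  asg <- assign_peaks(b$peaks$HS_10, windows)
  expect_true(all(truth$gene_id[truth$binding_induced] %in% asg$gene_id))
})

test_that("term simulation enriches marker terms in their target classes", {
  cfg <- sim_config(n_genes = 2000, rng_seed = 17)
  truth <- simulate_truth(cfg)
  tm <- simulate_terms(cfg, truth)
  in_class <- truth$gene_id[truth$true_mode == "suppressed_activation"]
  members <- tm$annotations$gene_id[tm$annotations$term_id == "TERM_SUPP"]
  expect_gt(mean(in_class %in% members), 0.4)
  out_class <- setdiff(truth$gene_id, in_class)
  expect_lt(mean(out_class %in% members), 0.12)
})

test_that("written dataset artifacts are byte-identical across runs", {
  cfg <- sim_config(n_genes = 25, rng_seed = 21)
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  on.exit(unlink(c(d1, d2), recursive = TRUE))
  write_dataset(simulate_dataset(cfg), d1)
  write_dataset(simulate_dataset(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6), info = f)
  }
})
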