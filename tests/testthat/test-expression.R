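make_matrix <- function(values, conditions) {
  # values: list of per-condition replicate vectors for a single gene set
  mat <- do.call(cbind, values)
  colnames(mat) <- unlist(lapply(seq_along(conditions), function(i)
    paste(conditions[i], seq_len(ncol(values[[i]])), sep = "_")))
  mat
}

two_group <- function(treated, reference) {
  mat <- rbind(c(treated, reference))
  rownames(mat) <- "g1"
  colnames(mat) <- c(paste0("T_", seq_along(treated)),
                     paste0("C_", seq_along(reference)))
  map <- data.frame(sample_id = colnames(mat),
                    condition = rep(c("TNF", "Ctr"),
                                    c(length(treated), length(reference))))
  list(mat = mat, map = map)
}

test_that("linear ratio is 2^(mean difference of log2 signals)", {
  d <- two_group(c(4.0, 4.2), c(3.0, 3.0))
  expect_equal(unname(linear_ratio(d$mat, d$map, c("TNF", "Ctr"))),
               2 ^ (4.1 - 3.0))
  d2 <- two_group(c(5, 5), c(5, 5))
  expect_equal(unname(linear_ratio(d2$mat, d2$map, c("TNF", "Ctr"))), 1.0)
  # a ratio of exactly 1.2 sits on the strict boundary and is not a call
  d3 <- two_group(c(3 + log2(1.2), 3 + log2(1.2)), c(3, 3))
  r <- unname(linear_ratio(d3$mat, d3$map, c("TNF", "Ctr")))
  expect_equal(r, 1.2)
  expect_equal(call_de(r, 0.001), "none")
  expect_error(linear_ratio(d$mat, d$map, c("HS", "Ctr")), "condition")
})

test_that("moderated test reduces to the textbook pooled t at d0 = 0", {
  set.seed(42)
  n <- 50
  mat <- matrix(rnorm(n * 6, mean = 7), nrow = n,
                dimnames = list(sprintf("g%02d", 1:n), NULL))
  colnames(mat) <- c(paste0("TNF_", 1:3), paste0("Ctr_", 1:3))
  map <- data.frame(sample_id = colnames(mat),
                    condition = rep(c("TNF", "Ctr"), each = 3))
  res <- moderated_test(mat, map, c("TNF", "Ctr"), moderation_params(0, 1))
  for (i in seq_len(n)) {
    o <- oracle_pooled_t(mat[i, 1:3], mat[i, 4:6])
    expect_equal(res$t[i], o$t, tolerance = 1e-10)
    expect_equal(res$p[i], o$p, tolerance = 1e-10)
  }
  expect_equal(unique(res$df), 4)

  # null identity: zero mean difference gives t = 0, p = 1
  matz <- mat; matz[1, ] <- 5
  resz <- moderated_test(matz, map, c("TNF", "Ctr"), moderation_params(0, 1))
  expect_equal(resz$t[1], 0)
  expect_equal(resz$p[1], 1)
})

test_that("moderated t matches limma given the same prior", {
  skip_if_not_installed("limma")
  set.seed(7)
  n <- 200
  mat <- matrix(rnorm(n * 6, sd = rep(sqrt(rchisq(n, 4) / 4), 6)), nrow = n)
  rownames(mat) <- sprintf("g%03d", 1:n)
  colnames(mat) <- c(paste0("TNF_", 1:3), paste0("Ctr_", 1:3))
  mat[, 1:3] <- mat[, 1:3] + rep(rnorm(n, 0, 1), 3)
  map <- data.frame(sample_id = colnames(mat),
                    condition = rep(c("TNF", "Ctr"), each = 3))
  design <- cbind(1, rep(c(1, 0), each = 3))
  fit <- limma::lmFit(mat, design)
  eb <- limma::eBayes(fit)
  params <- moderation_params(eb$df.prior, eb$s2.prior)
  res <- moderated_test(mat, map, c("TNF", "Ctr"), params)
  expect_equal(res$t, unname(eb$t[, 2]), tolerance = 1e-8)
  expect_equal(res$p, unname(eb$p.value[, 2]), tolerance = 1e-8)
})

test_that("moderation prior is recovered from scaled inverse-chi-square data", {
  set.seed(11)
  n <- 5000
  d0 <- 4; s02 <- 1
  sigma2 <- d0 * s02 / rchisq(n, d0)
  mat <- matrix(rnorm(n * 6, sd = rep(sqrt(sigma2), 6)), nrow = n)
  rownames(mat) <- sprintf("g%04d", 1:n)
  colnames(mat) <- c(paste0("TNF_", 1:3), paste0("Ctr_", 1:3))
  map <- data.frame(sample_id = colnames(mat),
                    condition = rep(c("TNF", "Ctr"), each = 3))
  fit <- fit_moderation(mat, map, c("TNF", "Ctr"))
  expect_lt(abs(fit$d0 - d0) / d0, 0.25)
  expect_lt(abs(fit$s02 - s02), 0.2)

  # equal variances: no dispersion to attribute to the prior -> d0 = Inf
  mate <- matrix(rep(c(1, -1, 0), each = 2), nrow = 20, ncol = 6,
                 byrow = TRUE)
  rownames(mate) <- sprintf("e%02d", 1:20)
  colnames(mate) <- colnames(mat)
  fite <- fit_moderation(mate, map, c("TNF", "Ctr"))
  expect_true(is.infinite(fite$d0))

  matz <- mate; matz[] <- 3
  expect_error(fit_moderation(matz, map, c("TNF", "Ctr")), "zero")
})

test_that("q-value estimation matches the hand-computed step-up and is monotone", {
  expect_equal(as.numeric(estimate_qvalues(c(0.01, 0.04, 0.03),
                                           method = "bh")),
               c(0.03, 0.04, 0.04))
  expect_equal(as.numeric(estimate_qvalues(rep(1, 5), method = "bh")),
               rep(1, 5))
  expect_identical(estimate_qvalues(numeric(0)), numeric(0))
  expect_error(estimate_qvalues(c(0.5, 1.2)), "0, 1")

  set.seed(3)
  p <- c(rbeta(400, 0.3, 4), runif(600))
  qs <- estimate_qvalues(p, method = "storey")
  qb <- estimate_qvalues(p, method = "bh")
  pi0 <- attr(qs, "pi0")
  expect_lte(pi0, 1)
  # storey q-values never exceed BH when pi0 <= 1
  expect_true(all(as.numeric(qs) <= as.numeric(qb) + 1e-12))
  # monotone in p after sorting
  o <- order(p)
  expect_true(all(diff(as.numeric(qs)[o]) >= -1e-12))
  expect_true(all(qs >= 0 & qs <= 1))
})

test_that("the ratio + FDR call rule partitions genes", {
  expect_equal(call_de(1.66, 0.01), "up")
  expect_equal(call_de(0.03, 0.001), "down")
  expect_equal(call_de(1.2, 0.001), "none")
  expect_equal(call_de(0.8, 0.001), "none")
  expect_equal(call_de(2.5, 0.2), "none")
  set.seed(5)
  ratio <- exp(rnorm(200)); q <- runif(200)
  calls <- call_de(ratio, q)
  expect_true(all(calls %in% c("up", "down", "none")))
  expect_equal(length(calls), 200)
})

test_that("de_analysis recovers planted effects on clean data", {
  cfg <- sim_config(n_genes = 500, rng_seed = 23)
  truth <- simulate_truth(cfg)
  ex <- simulate_expression(cfg, truth)
  de <- de_analysis(ex$matrix, ex$sample_map, c("TNF", "Ctr"))
  up <- truth$delta_tnf > 0
  down <- truth$delta_tnf < 0
  expect_gt(mean(de$call[up] == "up"), 0.95)
  expect_gt(mean(de$call[down] == "down"), 0.95)
  expect_gt(mean(de$call[truth$delta_tnf == 0] == "none"), 0.9)
})
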