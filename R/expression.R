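# Differential-expression statistics for the factorial design
# {Ctr, TNF, HS, HS_TNF}: per-gene linear ratios, an empirical-Bayes
# moderated t statistic with explicit prior parameters, Storey/BH q-values,
# and the ratio + FDR call rule (> 1.2 or < 0.8, q < 0.05).

#' Standard contrasts of the factorial design
#'
#' "TNF-modulated" is TNF vs Ctr; "HS-modulated" is HS vs Ctr; the effect of
#' heat-shock pre-treatment on the cytokine response is HS_TNF vs TNF; the
#' reverse analysis (effect of the cytokine on the heat-shock response) is
#' HS_TNF vs HS.
#'
#' @return named list of `c(treated, reference)` pairs.
#' @export
standard_contrasts <- function() {
  list(tnf = c("TNF", "Ctr"),
       hs = c("HS", "Ctr"),
       hstnf_vs_tnf = c("HS_TNF", "TNF"),
       hstnf_vs_hs = c("HS_TNF", "HS"))
}

contrast_columns <- function(mat, sample_map, contrast) {
  stopifnot(length(contrast) == 2, contrast[1] != contrast[2])
  cols <- function(cond) {
    s <- sample_map$sample_id[sample_map$condition == cond]
    s <- intersect(s, colnames(mat))
    if (length(s) < 2)
      stop("condition '", cond, "' needs >= 2 samples in the matrix")
    s
  }
  list(treated = cols(contrast[1]), reference = cols(contrast[2]))
}

#' Linear-scale fold change per gene
#'
#' `2 ^ (mean log2 treated - mean log2 reference)`, the "signal ratio" that
#' the call rule thresholds at > 1.2 (up) and < 0.8 (down).
#'
#' @param mat genes x samples log2 expression matrix with dimnames.
#' @param sample_map data.frame `sample_id`, `condition`.
#' @param contrast `c(treated, reference)` condition pair.
#' @param genes optional gene subset (default: all rows).
#' @return named numeric vector of positive ratios.
#' @export
linear_ratio <- function(mat, sample_map, contrast, genes = NULL) {
  cc <- contrast_columns(mat, sample_map, contrast)
  if (!is.null(genes)) mat <- mat[genes, , drop = FALSE]
  2 ^ (rowMeans(mat[, cc$treated, drop = FALSE]) -
         rowMeans(mat[, cc$reference, drop = FALSE]))
}

#' Moderation prior parameters
#'
#' @param d0 prior degrees of freedom (0 = ordinary pooled t, Inf = all
#'   genes share `s02`).
#' @param s02 prior variance (> 0 unless `d0 == 0`).
#' @return object of class `"moderation_params"`.
#' @export
moderation_params <- function(d0, s02) {
  if (d0 < 0) stop("d0 must be >= 0")
  if (d0 > 0 && s02 <= 0) stop("s02 must be > 0")
  structure(list(d0 = d0, s02 = s02), class = "moderation_params")
}

# Inverse of the trigamma function by Newton iteration on 1/trigamma,
# as used in empirical-Bayes variance moderation.
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < 1e-8) break
  }
  x
}

#' Fit the variance-moderation prior by moment matching
#'
#' Pooled per-gene sample variances for the contrast are modelled as draws
#' from a scaled inverse-chi-square prior with parameters `(d0, s02)`. The
#' prior is fitted by matching the mean and variance of `log(s_g^2)` to their
#' theoretical values under the hierarchical model (digamma/trigamma
#' moments). When the observed dispersion of log variances does not exceed
#' the sampling component, moment matching has no finite solution and the
#' fit falls back to `d0 = Inf` (all genes share `s02`).
#'
#' @inheritParams linear_ratio
#' @return a [moderation_params()] with attribute `df_residual`.
#' @export
fit_moderation <- function(mat, sample_map, contrast) {
  if (nrow(mat) < 10)
    stop("need >= 10 genes for a stable moderation fit")
  cc <- contrast_columns(mat, sample_map, contrast)
  n1 <- length(cc$treated); n2 <- length(cc$reference)
  dg <- n1 + n2 - 2
  s2 <- pooled_variances(mat, cc)
  pos <- s2 > 0
  if (!any(pos))
    stop("all per-gene variances are zero; moderation prior is undefined")
  z <- log(s2[pos])
  evar <- stats::var(z) - trigamma(dg / 2)
  if (!is.finite(evar) || evar <= 0) {
    d0 <- Inf
    s02 <- exp(mean(z) - digamma(dg / 2) + log(dg / 2))
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(mean(z) - digamma(dg / 2) + log(dg / 2) +
                 digamma(d0 / 2) - log(d0 / 2))
  }
  out <- moderation_params(d0, s02)
  attr(out, "df_residual") <- dg
  out
}

pooled_variances <- function(mat, cc) {
  n1 <- length(cc$treated); n2 <- length(cc$reference)
  v1 <- apply(mat[, cc$treated, drop = FALSE], 1, stats::var)
  v2 <- apply(mat[, cc$reference, drop = FALSE], 1, stats::var)
  ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
}

#' Moderated two-sample t test per gene
#'
#' Posterior variance `s~^2 = (d0 s02 + dg s_g^2) / (d0 + dg)`;
#' `t = dmean / (s~ sqrt(1/n1 + 1/n2))` on `d0 + dg` degrees of freedom,
#' two-sided. `d0 = 0` reduces to the ordinary pooled-variance t; `d0 = Inf`
#' scores every gene against the shared prior variance. A zero posterior
#' variance yields `t = +/-Inf` (p = 0) for a non-zero mean difference and
#' `t = 0` (p = 1) otherwise.
#'
#' @inheritParams linear_ratio
#' @param params a [moderation_params()], e.g. from [fit_moderation()].
#' @return data.frame `gene_id`, `delta` (log2 mean difference), `t`, `df`,
#'   `p`.
#' @export
moderated_test <- function(mat, sample_map, contrast, params) {
  cc <- contrast_columns(mat, sample_map, contrast)
  n1 <- length(cc$treated); n2 <- length(cc$reference)
  if (n1 + n2 < 3) stop("insufficient replication: n1 + n2 < 3")
  dg <- n1 + n2 - 2
  delta <- rowMeans(mat[, cc$treated, drop = FALSE]) -
    rowMeans(mat[, cc$reference, drop = FALSE])
  s2 <- pooled_variances(mat, cc)
  d0 <- params$d0
  post <- if (is.infinite(d0)) rep(params$s02, length(s2))
          else (d0 * params$s02 + dg * s2) / (d0 + dg)
  se <- sqrt(post * (1 / n1 + 1 / n2))
  t <- ifelse(se > 0, delta / se, ifelse(delta == 0, 0, sign(delta) * Inf))
  df <- d0 + dg
  p <- 2 * stats::pt(-abs(t), df = df)
  p[is.infinite(t)] <- 0
  data.frame(gene_id = rownames(mat), delta = delta, t = t, df = df, p = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' q-values from p-values (Storey or Benjamini-Hochberg)
#'
#' Storey's method estimates the null proportion pi0 on the lambda grid
#' `0.05, 0.10, ..., 0.95` and smooths pi0(lambda) with a df = 3 spline,
#' taking the fitted value at the largest lambda (clipped to (0, 1]);
#' q-values are then the step-up minima of `pi0 * m * p / rank`. `method =
#' "bh"` is the same computation with pi0 fixed at 1. When the pi0 smoother
#' cannot be fitted (few or degenerate p-values), the estimate falls back to
#' pi0 = 1.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param method `"storey"` or `"bh"`.
#' @param lambda grid for pi0 estimation.
#' @return numeric vector of q-values, same order as `p`; attribute `pi0`
#'   carries the null-proportion estimate.
#' @export
estimate_qvalues <- function(p, method = c("storey", "bh"),
                             lambda = seq(0.05, 0.95, by = 0.05)) {
  method <- match.arg(method)
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1 | is.na(p))) stop("p-values must lie in [0, 1]")
  pi0 <- 1
  if (method == "storey") {
    pi0l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
    fit <- tryCatch(
      stats::smooth.spline(lambda, pi0l, df = 3),
      error = function(e) NULL)
    if (!is.null(fit)) {
      pi0 <- stats::predict(fit, x = max(lambda))$y
    }
    if (!is.finite(pi0) || pi0 <= 0) pi0 <- 1  # unstable estimate: BH fallback
    pi0 <- min(pi0, 1)
  }
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  q <- numeric(m)
  run <- pi0 * m * p[o] / rank(p, ties.method = "max")[o]
  q[o] <- pmin(1, cummin(run))
  attr(q, "pi0") <- pi0
  q
}

#' Differential-expression call from ratio and q-value
#'
#' `up` iff ratio > `thresholds["up"]` and q < `thresholds["fdr"]`;
#' `down` iff ratio < `thresholds["down"]` and q < `thresholds["fdr"]`;
#' otherwise `none`. The ratio comparisons are strict, so a ratio of exactly
#' 1.2 is not a call.
#'
#' @param ratio positive linear fold changes.
#' @param q q-values in [0, 1].
#' @param thresholds named vector with `up`, `down`, `fdr`.
#' @return character vector over `{"up", "down", "none"}`.
#' @export
call_de <- function(ratio, q, thresholds = c(up = 1.2, down = 0.8, fdr = 0.05)) {
  stopifnot(all(ratio > 0), all(q >= 0 & q <= 1))
  ifelse(ratio > thresholds[["up"]] & q < thresholds[["fdr"]], "up",
         ifelse(ratio < thresholds[["down"]] & q < thresholds[["fdr"]],
                "down", "none"))
}

#' Full differential-expression analysis for one contrast
#'
#' Computes linear ratios, fits (or takes) the moderation prior, runs the
#' moderated t test, estimates q-values, and applies the call rule.
#'
#' @inheritParams linear_ratio
#' @param params optional [moderation_params()]; fitted when `NULL`.
#' @param fdr_method passed to [estimate_qvalues()].
#' @param thresholds passed to [call_de()].
#' @return data.frame `gene_id`, `ratio`, `t`, `p`, `q`, `call`.
#' @export
de_analysis <- function(mat, sample_map, contrast, params = NULL,
                        fdr_method = "storey",
                        thresholds = c(up = 1.2, down = 0.8, fdr = 0.05)) {
  if (is.null(params)) {
    params <- tryCatch(fit_moderation(mat, sample_map, contrast),
                       error = function(e) moderation_params(0, 1))
  }
  tt <- moderated_test(mat, sample_map, contrast, params)
  ratio <- 2 ^ tt$delta
  q <- estimate_qvalues(tt$p, method = fdr_method)
  data.frame(gene_id = tt$gene_id, ratio = ratio, t = tt$t, p = tt$p,
             q = as.numeric(q), call = call_de(ratio, q, thresholds),
             stringsAsFactors = FALSE)
}
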