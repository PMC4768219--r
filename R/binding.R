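# HSF1 binding layer: strand-aware regulatory windows around the TSS,
# peak-to-window assignment, a simple Poisson tag-count peak caller, and the
# per-gene heat-shock-induced-binding call from the 10- and 20-min
# timepoints. All coordinates are 0-based half-open (BED convention);
# conversion to the 1-based IRanges convention happens internally.

granges_from_halfopen <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end))
}

#' Strand-aware regulatory windows around each TSS
#'
#' For a plus-strand gene the window is `[tss - upstream, tss + downstream)`;
#' for a minus-strand gene `[tss - downstream, tss + upstream)`. Windows are
#' clipped at position 0. The defaults (7500 bp upstream, 2500 bp
#' downstream) span distal promoters and proximal regulatory elements.
#'
#' @param annotation data.frame `gene_id`, `chrom`, `tss` (0-based),
#'   `strand` (`+`/`-`).
#' @param upstream,downstream extents in bp.
#' @return data.frame `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`.
#' @export
make_windows <- function(annotation, upstream = 7500, downstream = 2500) {
  stopifnot(all(annotation$strand %in% c("+", "-")))
  plus <- annotation$strand == "+"
  start <- ifelse(plus, annotation$tss - upstream, annotation$tss - downstream)
  end <- ifelse(plus, annotation$tss + downstream, annotation$tss + upstream)
  data.frame(gene_id = annotation$gene_id, chrom = annotation$chrom,
             start = as.integer(pmax(start, 0)), end = as.integer(end),
             strand = annotation$strand, stringsAsFactors = FALSE)
}

#' Assign peaks to regulatory windows
#'
#' A peak is assigned to a gene iff it overlaps the gene's window by at least
#' 1 bp (half-open semantics: a peak starting exactly at the window end does
#' not overlap). A peak may be assigned to several genes. Chromosome names
#' absent from the windows produce zero assignments with a warning.
#'
#' @param peaks BED-style data.frame `chrom`, `start`, `end` plus optional
#'   `name`, `score`.
#' @param windows output of [make_windows()].
#' @return data.frame `gene_id`, `peak_name`, `chrom`, `peak_start`,
#'   `peak_end`, `score`, sorted by gene then peak start.
#' @export
assign_peaks <- function(peaks, windows) {
  empty <- data.frame(gene_id = character(), peak_name = character(),
                      chrom = character(), peak_start = integer(),
                      peak_end = integer(), score = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(peaks) == 0 || nrow(windows) == 0) return(empty)
  missing_chrom <- setdiff(unique(peaks$chrom), unique(windows$chrom))
  if (length(missing_chrom))
    warning("peak chromosomes absent from windows (zero overlap): ",
            paste(missing_chrom, collapse = ", "))
  gp <- granges_from_halfopen(peaks)
  gw <- granges_from_halfopen(windows)
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(gp, gw, minoverlap = 1L))
  if (length(ov) == 0) return(empty)
  pi <- S4Vectors::queryHits(ov)
  wi <- S4Vectors::subjectHits(ov)
  out <- data.frame(
    gene_id = windows$gene_id[wi],
    peak_name = if (!is.null(peaks$name)) peaks$name[pi]
                else sprintf("peak_%05d", pi),
    chrom = peaks$chrom[pi],
    peak_start = peaks$start[pi],
    peak_end = peaks$end[pi],
    score = if (!is.null(peaks$score)) peaks$score[pi] else NA_real_,
    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id, out$peak_start, out$peak_end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simple Poisson peak caller on binned tag tracks
#'
#' Per bin, the upper-tail Poisson p-value of the treatment count is computed
#' against a depth-scaled reference rate floored at the global (depth-scaled)
#' mean reference rate; p-values are BH-adjusted across bins and adjacent
#' significant bins are merged into peaks scored by `-log10` of the best
#' adjusted p-value in the peak. This is a deliberately simple caller: one
#' background floor, no fragment-shift model.
#'
#' @param track,reference data.frames `chrom`, `start`, `end`, `count` on the
#'   same bin grid.
#' @param fdr BH-adjusted significance level.
#' @return BED-style data.frame `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @export
call_peaks_simple <- function(track, reference, fdr = 0.05) {
  stopifnot(nrow(track) == nrow(reference))
  if (!all(track$chrom == reference$chrom & track$start == reference$start))
    stop("track and reference must share one bin grid")
  widths <- unique(track$end - track$start)
  if (length(widths) != 1) stop("bins must have uniform width")
  depth_ref <- sum(reference$count)
  if (depth_ref <= 0) stop("reference track has zero depth")
  scale <- sum(track$count) / depth_ref
  floor_rate <- scale * mean(reference$count)
  lambda <- pmax(scale * reference$count, floor_rate)
  p <- stats::ppois(track$count - 1, lambda, lower.tail = FALSE)
  padj <- stats::p.adjust(p, method = "BH")
  sig <- padj < fdr
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(), score = numeric(),
                      strand = character(), stringsAsFactors = FALSE)
  if (!any(sig)) return(empty)
  # merge runs of adjacent significant bins per chromosome
  o <- order(track$chrom, track$start)
  tr <- track[o, ]; sg <- sig[o]; pa <- padj[o]
  new_run <- c(TRUE, tr$chrom[-1] != tr$chrom[-nrow(tr)] |
                 tr$start[-1] != tr$end[-nrow(tr)] | !sg[-nrow(tr)])
  run_id <- cumsum(new_run & sg)
  run_id[!sg] <- NA
  keep <- !is.na(run_id)
  runs <- split(which(keep), run_id[keep])
  out <- do.call(rbind, lapply(seq_along(runs), function(k) {
    i <- runs[[k]]
    data.frame(chrom = tr$chrom[i[1]], start = tr$start[i[1]],
               end = tr$end[i[length(i)]],
               name = sprintf("peak_%05d", k),
               score = -log10(max(min(pa[i]), 1e-300)),
               strand = ".", stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

window_tag_counts <- function(track, windows) {
  gt <- granges_from_halfopen(track)
  gw <- granges_from_halfopen(windows)
  ov <- GenomicRanges::findOverlaps(gt, gw, minoverlap = 1L)
  counts <- rep(0, nrow(windows))
  if (length(ov)) {
    agg <- tapply(track$count[S4Vectors::queryHits(ov)],
                  S4Vectors::subjectHits(ov), sum)
    counts[as.integer(names(agg))] <- agg
  }
  counts
}

#' Call heat-shock-induced HSF1 binding per gene
#'
#' A gene is induced at a timepoint when its regulatory window carries
#' heat-shock binding significantly exceeding the control signal; a gene is
#' induced overall when induced after either 10 or 20 min of heat shock.
#' Two evidence routes are supported:
#' \describe{
#'   \item{`method = "score"`}{(peak sets only) induced iff the best
#'     heat-shock peak score in the window is at least `min_score` and at
#'     least `score_ratio` times the best overlapping control peak score.}
#'   \item{`method = "tags"`}{(binned tag tracks supplied via `tracks`, a
#'     named list with elements `Ctr`, `HS_10`, `HS_20`) Poisson upper-tail
#'     test of the window's heat-shock tag count against the depth-scaled
#'     control count, BH-adjusted across genes at `fdr`.}
#' }
#'
#' @param peaks named list of BED-style data.frames `Ctr`, `HS_10`, `HS_20`.
#' @param windows output of [make_windows()].
#' @param method `"score"` or `"tags"`.
#' @param tracks named list of tag tracks (required for `method = "tags"`).
#' @param fdr BH level for the tag-count test.
#' @param score_ratio minimum HS/control score ratio (score route).
#' @param min_score minimum HS peak score (score route).
#' @return data.frame `gene_id`, `bound_ctr`, `induced_hs10`,
#'   `induced_hs20`, `induced_any`, `hs10_peaks`, `hs20_peaks`
#'   (comma-separated supporting peak names).
#' @export
call_induced_binding <- function(peaks, windows,
                                 method = c("score", "tags"),
                                 tracks = NULL, fdr = 0.05,
                                 score_ratio = 1.5, min_score = 5) {
  method <- match.arg(method)
  need <- c("Ctr", "HS_10", "HS_20")
  if (!all(need %in% names(peaks)))
    stop("peaks must contain conditions: ", paste(need, collapse = ", "))
  asg <- lapply(peaks[need], assign_peaks, windows = windows)
  best <- function(a) {
    sc <- tapply(a$score, a$gene_id, max)
    out <- stats::setNames(rep(0, nrow(windows)), windows$gene_id)
    out[names(sc)] <- sc
    out
  }
  supporting <- function(a) {
    nm <- tapply(a$peak_name, a$gene_id, paste, collapse = ",")
    out <- stats::setNames(rep("", nrow(windows)), windows$gene_id)
    out[names(nm)] <- nm
    out
  }
  ctr <- best(asg$Ctr)
  if (method == "score") {
    induced <- function(cond) {
      hs <- best(asg[[cond]])
      hs >= min_score & hs >= score_ratio * ctr
    }
    i10 <- induced("HS_10"); i20 <- induced("HS_20")
  } else {
    if (is.null(tracks) || !all(need %in% names(tracks)))
      stop("method = 'tags' needs tracks for ", paste(need, collapse = ", "))
    x_ctr <- window_tag_counts(tracks$Ctr, windows)
    depth_ctr <- sum(tracks$Ctr$count)
    bg <- mean(x_ctr)
    induced <- function(cond) {
      x <- window_tag_counts(tracks[[cond]], windows)
      scale <- sum(tracks[[cond]]$count) / depth_ctr
      lambda <- pmax(scale * x_ctr, scale * bg)
      p <- stats::ppois(x - 1, lambda, lower.tail = FALSE)
      stats::p.adjust(p, method = "BH") < fdr
    }
    i10 <- induced("HS_10"); i20 <- induced("HS_20")
  }
  data.frame(gene_id = windows$gene_id,
             bound_ctr = unname(ctr > 0),
             induced_hs10 = unname(i10),
             induced_hs20 = unname(i20),
             induced_any = unname(i10 | i20),
             hs10_peaks = unname(supporting(asg$HS_10)),
             hs20_peaks = unname(supporting(asg$HS_20)),
             stringsAsFactors = FALSE)
}
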