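# Position-weight-matrix models of the kB (NF-kB) and HSE (HSF1) binding
# motifs, and a log-odds scanner over proximal promoter sequences.

DNA_BASES <- c("A", "C", "G", "T")

#' Construct a PWM from a base-probability (or count) matrix
#'
#' Columns are normalised to probabilities after adding `pseudocount` to
#' every cell, so zero entries cannot produce infinite log odds.
#'
#' @param mat 4 x width numeric matrix with rownames A, C, G, T.
#' @param name motif name.
#' @param bg named background composition over A, C, G, T.
#' @param pseudocount value added to each cell before normalisation.
#' @return object of class `"pwm"`: list with `name`, `mat` (probabilities),
#'   `width`, `bg`, `logodds` (log2(p/bg)).
#' @export
new_pwm <- function(mat, name, bg = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                    pseudocount = 0.01) {
  stopifnot(is.matrix(mat), nrow(mat) == 4)
  if (ncol(mat) < 4) stop("PWM width must be >= 4")
  if (is.null(rownames(mat))) rownames(mat) <- DNA_BASES
  mat <- mat[DNA_BASES, , drop = FALSE]
  mat <- mat + pseudocount
  mat <- sweep(mat, 2, colSums(mat), "/")
  bg <- bg[DNA_BASES]
  structure(list(name = name, mat = mat, width = ncol(mat), bg = bg,
                 logodds = log2(mat / bg)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM", x$name, "- width", x$width,
      "- consensus", consensus_seq(x), "\n")
  invisible(x)
}

# Probability matrix from an IUPAC-style consensus: listed bases share
# `major` probability mass, the rest get the remainder.
consensus_to_mat <- function(consensus_bases, major = 0.97) {
  w <- length(consensus_bases)
  mat <- matrix(0, 4, w, dimnames = list(DNA_BASES, NULL))
  for (j in seq_len(w)) {
    b <- consensus_bases[[j]]
    if (length(b) == 4) {
      mat[, j] <- 0.25
    } else {
      mat[b, j] <- major / length(b)
      mat[setdiff(DNA_BASES, b), j] <- (1 - major) / (4 - length(b))
    }
  }
  mat
}

#' Default kB (NF-kB RelA/p50) motif model
#'
#' Encodes the canonical 10-bp decamer consensus GGGRNNYYCC
#' (R = A/G, Y = C/T, N = any).
#'
#' @inheritParams new_pwm
#' @return a [new_pwm()] named `"kb"`.
#' @export
kb_pwm <- function(bg = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                   pseudocount = 0.01) {
  cons <- list("G", "G", "G", c("A", "G"), DNA_BASES, DNA_BASES,
               c("C", "T"), c("C", "T"), "C", "C")
  new_pwm(consensus_to_mat(cons), "kb", bg = bg, pseudocount = pseudocount)
}

#' Heat-shock-element motif model
#'
#' An HSE is composed of `n_units` alternating-orientation nGAAn pentamer
#' units; for three units the consensus reads nGAAnnTTCnnGAAn. Invariant
#' positions are near-deterministic, "n" positions sit at background.
#'
#' @param n_units number of pentamer units (>= 3).
#' @inheritParams new_pwm
#' @return a [new_pwm()] named `"hse"`, width `5 * n_units`.
#' @export
build_hse_pwm <- function(n_units = 3,
                          bg = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                          pseudocount = 0.01) {
  if (n_units < 3) stop("an HSE needs >= 3 nGAAn units")
  cons <- list()
  for (u in seq_len(n_units) - 1L) {
    core <- if (u %% 2 == 0) c("G", "A", "A") else c("T", "T", "C")
    cons <- c(cons, list(DNA_BASES), as.list(core), list(DNA_BASES))
  }
  new_pwm(consensus_to_mat(cons), "hse", bg = bg, pseudocount = pseudocount)
}

#' Consensus sequence of a PWM (highest-probability base per column)
#' @param pwm a [new_pwm()].
#' @return character scalar.
#' @export
consensus_seq <- function(pwm) {
  paste(DNA_BASES[apply(pwm$mat, 2, which.max)], collapse = "")
}

#' Maximum attainable log-odds score of a PWM
#' @param pwm a [new_pwm()].
#' @return numeric scalar (bits).
#' @export
pwm_max_score <- function(pwm) sum(apply(pwm$logodds, 2, max))

#' Reverse complement of a DNA string
#' @param x character scalar over A/C/G/T/N.
#' @return character scalar.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Scores of every window of `pwm` along integer-encoded sequence `idx`
# (NA for unknown bases); windows touching an NA score NA.
window_scores <- function(idx, pwm) {
  L <- length(idx)
  w <- pwm$width
  n_win <- L - w + 1L
  if (n_win < 1) return(numeric(0))
  sc <- numeric(n_win)
  na <- logical(n_win)
  lo <- pwm$logodds
  for (j in seq_len(w)) {
    b <- idx[j:(j + n_win - 1L)]
    miss <- is.na(b)
    na <- na | miss
    b[miss] <- 1L
    sc <- sc + lo[cbind(b, j)]
  }
  sc[na] <- NA_real_
  sc
}

#' Scan a sequence with a PWM on both strands
#'
#' Every window on the forward and reverse strand is scored as the sum of
#' `log2(p_base / bg_base)` over motif positions; windows containing N are
#' skipped. Hits are windows scoring at least `rel_threshold` times the
#' maximum attainable score. Offsets are 0-based positions of the window
#' start on the forward sequence for both strands.
#'
#' @param sequence character scalar over A/C/G/T/N.
#' @param pwm a [new_pwm()].
#' @param rel_threshold fraction of the maximal score in (0, 1].
#' @return data.frame `offset`, `strand`, `score`, sorted by offset; empty
#'   when the sequence is shorter than the motif.
#' @export
scan_pwm <- function(sequence, pwm, rel_threshold = 0.8) {
  stopifnot(rel_threshold > 0, rel_threshold <= 1)
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  empty <- data.frame(offset = integer(), strand = character(),
                      score = numeric(), stringsAsFactors = FALSE)
  if (L < pwm$width) return(empty)
  idx <- match(strsplit(sequence, "", fixed = TRUE)[[1]], DNA_BASES)
  cutoff <- rel_threshold * pwm_max_score(pwm)
  fwd <- window_scores(idx, pwm)
  # reverse strand: score the reverse-complemented sequence, then map the
  # window start back to forward coordinates
  rc_idx <- rev(5L - idx)
  rev_ <- window_scores(rc_idx, pwm)
  hits <- list(empty)
  keep_f <- which(!is.na(fwd) & fwd >= cutoff)
  if (length(keep_f))
    hits[[length(hits) + 1]] <- data.frame(
      offset = keep_f - 1L, strand = "+", score = fwd[keep_f],
      stringsAsFactors = FALSE)
  keep_r <- which(!is.na(rev_) & rev_ >= cutoff)
  if (length(keep_r))
    hits[[length(hits) + 1]] <- data.frame(
      offset = L - pwm$width - (keep_r - 1L), strand = "-",
      score = rev_[keep_r], stringsAsFactors = FALSE)
  out <- do.call(rbind, hits)
  out <- out[order(out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-gene motif presence flags
#'
#' Scans each promoter with each PWM and flags a gene for a motif when at
#' least one hit reaches the relative score threshold.
#'
#' @param promoters named character vector (or `Biostrings::DNAStringSet`) of
#'   promoter sequences keyed by gene id.
#' @param pwms named list of PWMs.
#' @param rel_threshold passed to [scan_pwm()].
#' @return data.frame with `gene_id` and one logical column per motif (named
#'   `<motif>_motif`); attribute `hits` holds the full hit table
#'   (`gene_id`, `motif`, `offset`, `strand`, `score`).
#' @export
motif_presence <- function(promoters, pwms, rel_threshold = 0.8) {
  if (methods::is(promoters, "DNAStringSet"))
    promoters <- stats::setNames(as.character(promoters), names(promoters))
  ids <- names(promoters)
  if (is.null(ids) || anyNA(ids))
    stop("promoters must be named by gene id")
  if (anyDuplicated(ids))
    stop("duplicate promoter ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  flags <- data.frame(gene_id = ids, stringsAsFactors = FALSE)
  all_hits <- list()
  for (m in names(pwms)) {
    hit_any <- logical(length(ids))
    for (i in seq_along(ids)) {
      h <- scan_pwm(promoters[[i]], pwms[[m]], rel_threshold)
      hit_any[i] <- nrow(h) > 0
      if (nrow(h) > 0)
        all_hits[[length(all_hits) + 1]] <-
          cbind(data.frame(gene_id = ids[i], motif = m,
                           stringsAsFactors = FALSE), h)
    }
    flags[[paste0(m, "_motif")]] <- hit_any
  }
  attr(flags, "hits") <- if (length(all_hits)) do.call(rbind, all_hits)
    else data.frame(gene_id = character(), motif = character(),
                    offset = integer(), strand = character(),
                    score = numeric(), stringsAsFactors = FALSE)
  flags
}

#' Read PWMs from a JASPAR-style text file
#'
#' Expects records of the form `>name` followed by four lines
#' `A [ 1 2 3 ... ]` (brackets optional), giving per-base counts or
#' probabilities by column.
#'
#' @param path file path.
#' @inheritParams new_pwm
#' @return named list of [new_pwm()] objects.
#' @export
read_jaspar <- function(path, bg = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                        pseudocount = 0.01) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no JASPAR records ('>' headers) in ", path)
  pwms <- list()
  for (s in seq_along(starts)) {
    hdr <- sub("^>\\s*", "", lines[starts[s]])
    name <- strsplit(hdr, "\\s+")[[1]][1]
    end <- if (s < length(starts)) starts[s + 1] - 1 else length(lines)
    body <- lines[(starts[s] + 1):end]
    if (length(body) < 4) stop("record ", name, " lacks 4 base rows")
    rows <- lapply(body[1:4], function(ln) {
      base <- sub("^\\s*([ACGTacgt]).*", "\\1", ln)
      nums <- gsub("[][]", " ", sub("^\\s*[ACGTacgt]", "", ln))
      list(base = toupper(base),
           vals = as.numeric(strsplit(trimws(nums), "\\s+")[[1]]))
    })
    mat <- do.call(rbind, lapply(rows, `[[`, "vals"))
    rownames(mat) <- vapply(rows, `[[`, character(1), "base")
    pwms[[name]] <- new_pwm(mat, name, bg = bg, pseudocount = pseudocount)
  }
  pwms
}

#' Write PWMs to a JASPAR-style text file
#'
#' @param pwms named list of [new_pwm()] objects.
#' @param path file path.
#' @export
write_jaspar <- function(pwms, path) {
  out <- character()
  for (p in pwms) {
    out <- c(out, paste0(">", p$name))
    for (b in DNA_BASES)
      out <- c(out, sprintf("%s [ %s ]", b,
                            paste(formatC(p$mat[b, ], format = "f",
                                          digits = 6), collapse = " ")))
  }
  writeLines(out, path)
  invisible(path)
}
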