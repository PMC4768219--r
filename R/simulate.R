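# Condition labels used throughout: control, cytokine alone, heat shock alone,
# heat shock followed by cytokine.
CONDITIONS <- c("Ctr", "TNF", "HS", "HS_TNF")

# Regulation modes that can be planted per gene. The four "co-affected" modes
# describe how heat-shock pre-treatment changes the cytokine response; the
# *_only modes respond to a single stimulus; "null" genes are unregulated.
MODES <- c("co_activated", "co_repressed", "suppressed_activation",
           "relieved_repression", "tnf_only_up", "tnf_only_down",
           "hs_only_up", "hs_only_down", "null")

#' Simulation configuration
#'
#' Builds and validates the configuration object consumed by every
#' `simulate_*()` generator. Defaults describe a factorial stimulus-response
#' experiment over the four conditions Ctr/TNF/HS/HS_TNF with three replicates
#' per condition, log2-scale microarray-like intensities, and a planted mix of
#' regulation modes in which antagonism (suppressed activation) is the most
#' common co-affected class.
#'
#' @param n_genes number of genes to simulate.
#' @param n_replicates replicates per condition (>= 2).
#' @param baseline_mean,baseline_sd mean and sd of per-gene baseline log2
#'   intensity.
#' @param noise_sd replicate noise sd on the log2 scale.
#' @param effect_log2fc positive log2 fold change used for planted effects.
#' @param mode_fractions named proportions over the nine regulation modes;
#'   must sum to 1.
#' @param motif_plant_prob named list with elements `kb` and `hse`, each a
#'   named vector of per-mode probabilities that the corresponding motif
#'   consensus is planted in the gene's promoter.
#' @param binding_plant_prob named vector of per-mode probabilities that the
#'   gene carries heat-shock-induced HSF1 binding in its regulatory window.
#' @param promoter_length promoter length in bp (>= 1000).
#' @param peak_width_range length-2 integer vector; ChIP peak widths are drawn
#'   uniformly from this interval (default 200-800 bp, matching typical
#'   sonicated chromatin fragment sizes).
#' @param tag_depth mean background tag count per track bin.
#' @param tss_spacing distance between adjacent TSSs on the synthetic
#'   chromosome; the default 20 kb keeps 10-kb regulatory windows of
#'   neighbouring genes disjoint.
#' @param chrom_length optional explicit chromosome length; an error is raised
#'   if it cannot hold `n_genes` at `tss_spacing`.
#' @param background_comp named base composition (A, C, G, T) of promoter
#'   background sequence.
#' @param rng_seed integer seed; all generators derive their streams from it.
#'
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 1000,
                       n_replicates = 3,
                       baseline_mean = 8,
                       baseline_sd = 1.5,
                       noise_sd = 0.25,
                       effect_log2fc = 2,
                       mode_fractions = c(
                         co_activated = 0.04, co_repressed = 0.03,
                         suppressed_activation = 0.08,
                         relieved_repression = 0.03,
                         tnf_only_up = 0.05, tnf_only_down = 0.05,
                         hs_only_up = 0.06, hs_only_down = 0.06,
                         null = 0.60),
                       motif_plant_prob = list(
                         kb = c(co_activated = 0.8, co_repressed = 0.8,
                                suppressed_activation = 0.8,
                                relieved_repression = 0.8,
                                tnf_only_up = 0.8, tnf_only_down = 0.8,
                                hs_only_up = 0.1, hs_only_down = 0.1,
                                null = 0.1),
                         hse = c(co_activated = 0.6, co_repressed = 0.6,
                                 suppressed_activation = 0.2,
                                 relieved_repression = 0.2,
                                 tnf_only_up = 0.05, tnf_only_down = 0.05,
                                 hs_only_up = 0.6, hs_only_down = 0.6,
                                 null = 0.05)),
                       binding_plant_prob = c(
                         co_activated = 0.8, co_repressed = 0.8,
                         suppressed_activation = 0.3,
                         relieved_repression = 0.3,
                         tnf_only_up = 0.1, tnf_only_down = 0.1,
                         hs_only_up = 0.7, hs_only_down = 0.5,
                         null = 0.05),
                       promoter_length = 1000,
                       peak_width_range = c(200L, 800L),
                       tag_depth = 10,
                       tss_spacing = 20000,
                       chrom_length = NULL,
                       background_comp = c(A = 0.25, C = 0.25,
                                           G = 0.25, T = 0.25),
                       rng_seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_replicates = as.integer(n_replicates),
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              noise_sd = noise_sd, effect_log2fc = effect_log2fc,
              mode_fractions = mode_fractions,
              motif_plant_prob = motif_plant_prob,
              binding_plant_prob = binding_plant_prob,
              promoter_length = as.integer(promoter_length),
              peak_width_range = as.integer(peak_width_range),
              tag_depth = tag_depth,
              tss_spacing = as.integer(tss_spacing),
              chrom_length = chrom_length,
              background_comp = background_comp,
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_genes >= 0)
  if (cfg$n_replicates < 2)
    stop("n_replicates must be >= 2")
  if (cfg$baseline_sd < 0 || cfg$noise_sd < 0)
    stop("standard deviations must be >= 0")
  if (cfg$effect_log2fc <= 0)
    stop("effect_log2fc must be positive")
  if (!setequal(names(cfg$mode_fractions), MODES))
    stop("mode_fractions must be named by the nine regulation modes")
  if (abs(sum(cfg$mode_fractions) - 1) > 1e-9)
    stop("mode_fractions must sum to 1")
  if (any(cfg$mode_fractions < 0))
    stop("mode_fractions must be non-negative")
  if (cfg$promoter_length < 1000)
    stop("promoter_length must be >= 1000 (proximal promoter span)")
  if (length(cfg$peak_width_range) != 2 || diff(cfg$peak_width_range) < 0 ||
      cfg$peak_width_range[1] <= 0)
    stop("peak_width_range must be an increasing positive interval")
  if (abs(sum(cfg$background_comp) - 1) > 1e-9 ||
      !setequal(names(cfg$background_comp), c("A", "C", "G", "T")))
    stop("background_comp must be a composition over A, C, G, T")
  invisible(cfg)
}

# Run `expr` under a derived seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Sub-stream seeds: each generator draws from its own derived seed so that
# artifacts are reproducible independently of call order.
sim_seed <- function(cfg, stage) {
  offs <- c(truth = 11L, annotation = 23L, expression = 37L,
            promoters = 53L, binding = 71L, terms = 89L, tracks = 97L)
  (cfg$rng_seed * 101L + offs[[stage]]) %% .Machine$integer.max
}

#' Assign planted regulation modes and effect sizes
#'
#' Draws a regulation mode per gene from `mode_fractions` and encodes it as
#' additive log2 effects per condition. Suppressed-activation genes are
#' TNF-activated but return to their HS level under the combined treatment
#' (half of them are themselves HS-downregulated, half HS-neutral);
#' relieved-repression genes mirror this for TNF-downregulated genes.
#' Co-activated (co-repressed) genes respond to both stimuli separately and
#' more strongly to the combination. Motif and induced-binding flags are
#' drawn per mode from the configured plant probabilities.
#'
#' @param cfg a [sim_config()].
#' @return data.frame with one row per gene: `gene_id`, `true_mode`,
#'   `delta_tnf`, `delta_hs`, `delta_hstnf` (log2 offsets from baseline),
#'   `kb_planted`, `hse_planted`, `binding_induced`.
#' @export
simulate_truth <- function(cfg) {
  n <- cfg$n_genes
  gene_id <- sprintf("G%05d", seq_len(max(n, 0)))[seq_len(n)]
  if (n == 0) {
    return(data.frame(gene_id = character(), true_mode = character(),
                      delta_tnf = numeric(), delta_hs = numeric(),
                      delta_hstnf = numeric(), kb_planted = logical(),
                      hse_planted = logical(), binding_induced = logical(),
                      stringsAsFactors = FALSE))
  }
  with_local_seed(sim_seed(cfg, "truth"), {
    mode <- sample(names(cfg$mode_fractions), n, replace = TRUE,
                   prob = cfg$mode_fractions)
    e <- cfg$effect_log2fc
    d_tnf <- d_hs <- d_hstnf <- numeric(n)
    # random secondary HS effect for the antagonistic modes
    hs_side <- sample(c(0, 1), n, replace = TRUE)
    for (i in seq_len(n)) {
      switch(mode[i],
        null = NULL,
        tnf_only_up = { d_tnf[i] <- e; d_hstnf[i] <- e },
        tnf_only_down = { d_tnf[i] <- -e; d_hstnf[i] <- -e },
        hs_only_up = { d_hs[i] <- e; d_hstnf[i] <- e },
        hs_only_down = { d_hs[i] <- -e; d_hstnf[i] <- -e },
        co_activated = { d_tnf[i] <- e; d_hs[i] <- e; d_hstnf[i] <- 2 * e },
        co_repressed = { d_tnf[i] <- -e; d_hs[i] <- -e; d_hstnf[i] <- -2 * e },
        suppressed_activation = {
          d_tnf[i] <- e
          d_hs[i] <- if (hs_side[i] == 1) -e else 0
          d_hstnf[i] <- d_hs[i]
        },
        relieved_repression = {
          d_tnf[i] <- -e
          d_hs[i] <- if (hs_side[i] == 1) e else 0
          d_hstnf[i] <- d_hs[i]
        },
        stop("unknown regulation mode: ", mode[i]))
    }
    plant <- function(p) stats::runif(n) < p[mode]
    data.frame(gene_id = gene_id, true_mode = mode,
               delta_tnf = d_tnf, delta_hs = d_hs, delta_hstnf = d_hstnf,
               kb_planted = plant(cfg$motif_plant_prob$kb),
               hse_planted = plant(cfg$motif_plant_prob$hse),
               binding_induced = plant(cfg$binding_plant_prob),
               stringsAsFactors = FALSE)
  })
}

#' Simulate a gene annotation table
#'
#' Places genes on a single synthetic chromosome at a fixed TSS spacing (so
#' that regulatory windows of adjacent genes do not overlap at the default
#' spacing) with random strands.
#'
#' @param cfg a [sim_config()].
#' @return data.frame with columns `gene_id`, `chrom`, `tss` (0-based),
#'   `strand`.
#' @export
simulate_annotation <- function(cfg) {
  n <- cfg$n_genes
  margin <- 10000L
  needed <- margin * 2L + max(n - 1L, 0L) * cfg$tss_spacing
  chrom_len <- if (is.null(cfg$chrom_length)) needed else as.integer(cfg$chrom_length)
  if (chrom_len < needed)
    stop("chromosome of length ", chrom_len, " cannot hold ", n,
         " genes at spacing ", cfg$tss_spacing)
  if (n == 0) {
    return(structure(data.frame(gene_id = character(), chrom = character(),
                                tss = integer(), strand = character(),
                                stringsAsFactors = FALSE),
                     chrom_length = chrom_len))
  }
  with_local_seed(sim_seed(cfg, "annotation"), {
    ann <- data.frame(
      gene_id = sprintf("G%05d", seq_len(n)),
      chrom = "chrS1",
      tss = margin + (seq_len(n) - 1L) * cfg$tss_spacing,
      strand = sample(c("+", "-"), n, replace = TRUE),
      stringsAsFactors = FALSE)
    attr(ann, "chrom_length") <- chrom_len
    ann
  })
}

#' Simulate a four-condition replicate expression matrix
#'
#' log2 intensity of gene g in condition c, replicate r is
#' `baseline_g + delta_{g,c} + N(0, noise_sd)`, with the per-condition deltas
#' taken from the planted truth.
#'
#' @param cfg a [sim_config()].
#' @param truth output of [simulate_truth()].
#' @return list with `matrix` (genes x samples log2 intensities) and
#'   `sample_map` (data.frame `sample_id`, `condition`).
#' @export
simulate_expression <- function(cfg, truth) {
  n <- nrow(truth)
  R <- cfg$n_replicates
  samples <- paste(rep(CONDITIONS, each = R), seq_len(R), sep = "_")
  sample_map <- data.frame(sample_id = samples,
                           condition = rep(CONDITIONS, each = R),
                           stringsAsFactors = FALSE)
  with_local_seed(sim_seed(cfg, "expression"), {
    baseline <- stats::rnorm(n, cfg$baseline_mean, cfg$baseline_sd)
    delta <- cbind(Ctr = 0, TNF = truth$delta_tnf, HS = truth$delta_hs,
                   HS_TNF = truth$delta_hstnf)
    mu <- baseline + delta[, rep(CONDITIONS, each = R), drop = FALSE]
    mat <- mu + matrix(stats::rnorm(n * length(samples), 0, cfg$noise_sd),
                       nrow = n)
    dimnames(mat) <- list(truth$gene_id, samples)
    list(matrix = mat, sample_map = sample_map)
  })
}

#' Simulate promoter sequences with planted motif instances
#'
#' Background sequence is i.i.d. over the configured base composition. For
#' genes whose truth record flags a motif, the motif's consensus is inserted
#' at a random offset on a random strand; when both motifs are planted the kB
#' instance goes in the first half of the promoter and the HSE in the second
#' half so the inserts cannot overlap.
#'
#' @param cfg a [sim_config()].
#' @param truth output of [simulate_truth()].
#' @param pwms named list of PWMs; defaults to `list(kb = kb_pwm(),
#'   hse = build_hse_pwm(3))`. Names must include `kb` and `hse`.
#' @return list with `sequences` (named character vector, one promoter per
#'   gene, 5'->3' on the gene's strand ending at the TSS) and `plants`
#'   (data.frame `gene_id`, `motif`, `offset`, `strand`).
#' @export
simulate_promoters <- function(cfg, truth,
                               pwms = list(kb = kb_pwm(),
                                           hse = build_hse_pwm(3))) {
  L <- cfg$promoter_length
  for (p in pwms) {
    if (p$width > L)
      stop("promoter_length ", L, " is shorter than motif ", p$name)
  }
  n <- nrow(truth)
  with_local_seed(sim_seed(cfg, "promoters"), {
    bases <- names(cfg$background_comp)
    seqs <- vapply(seq_len(n), function(i) {
      paste(sample(bases, L, replace = TRUE, prob = cfg$background_comp),
            collapse = "")
    }, character(1))
    names(seqs) <- truth$gene_id
    plants <- list()
    insert <- function(seq, ins, offset) {
      paste0(substr(seq, 1, offset), ins,
             substr(seq, offset + nchar(ins) + 1, nchar(seq)))
    }
    half <- L %/% 2
    for (i in seq_len(n)) {
      for (m in c("kb", "hse")) {
        flagged <- if (m == "kb") truth$kb_planted[i] else truth$hse_planted[i]
        if (!flagged) next
        pwm <- pwms[[m]]
        cons <- consensus_seq(pwm)
        both <- truth$kb_planted[i] && truth$hse_planted[i]
        rng <- if (!both) c(0L, L - pwm$width)
               else if (m == "kb") c(0L, half - pwm$width)
               else c(half, L - pwm$width)
        offset <- sample(rng[1]:rng[2], 1)
        strand <- sample(c("+", "-"), 1)
        ins <- if (strand == "+") cons else revcomp(cons)
        seqs[i] <- insert(seqs[i], ins, offset)
        plants[[length(plants) + 1]] <-
          data.frame(gene_id = truth$gene_id[i], motif = m,
                     offset = offset, strand = strand,
                     stringsAsFactors = FALSE)
      }
    }
    plants <- if (length(plants)) do.call(rbind, plants)
              else data.frame(gene_id = character(), motif = character(),
                              offset = integer(), strand = character(),
                              stringsAsFactors = FALSE)
    list(sequences = seqs, plants = plants)
  })
}

#' Simulate HSF1 peak sets for control and heat-shocked conditions
#'
#' A shared set of basal peaks (placed uniformly over the chromosome,
#' independent of the planted truth) appears in all three conditions with
#' jittered scores. Every gene flagged `binding_induced` additionally gets a
#' strong peak inside its regulatory window in both heat-shock timepoints
#' (HS_10 and HS_20); the control either lacks that peak or, with probability
#' `ctr_leak`, carries a much weaker one at the same position.
#'
#' @param cfg a [sim_config()].
#' @param truth output of [simulate_truth()].
#' @param annotation output of [simulate_annotation()].
#' @param n_basal number of basal peaks (default: half the gene count).
#' @param ctr_leak probability that an induced site shows weak basal binding
#'   in the control.
#' @param upstream,downstream regulatory-window extents used for placement.
#' @return list with `peaks` (named list of BED-style data.frames for
#'   `Ctr`, `HS_10`, `HS_20`: `chrom`, `start`, `end` 0-based half-open,
#'   `name`, `score`, `strand`) and `planted` (data.frame of induced peak
#'   coordinates per gene).
#' @export
simulate_binding <- function(cfg, truth, annotation,
                             n_basal = max(1L, cfg$n_genes %/% 2L),
                             ctr_leak = 0.3,
                             upstream = 7500, downstream = 2500) {
  chrom_len <- attr(annotation, "chrom_length")
  if (is.null(chrom_len)) chrom_len <- max(annotation$tss) + 10000L
  windows <- make_windows(annotation, upstream, downstream)
  with_local_seed(sim_seed(cfg, "binding"), {
    wrange <- cfg$peak_width_range
    draw_width <- function(k) sample(wrange[1]:wrange[2], k, replace = TRUE)
    basal_w <- draw_width(n_basal)
    basal_start <- vapply(basal_w, function(w)
      sample.int(chrom_len - w, 1) - 1L, integer(1))
    basal_score <- stats::runif(n_basal, 2, 6)
    idx <- which(truth$binding_induced)
    ind_w <- draw_width(length(idx))
    win <- windows[match(truth$gene_id[idx], windows$gene_id), , drop = FALSE]
    ind_start <- integer(length(idx))
    for (j in seq_along(idx)) {
      lo <- win$start[j]
      hi <- max(lo, win$end[j] - ind_w[j])
      ind_start[j] <- if (hi > lo) sample(lo:hi, 1) else lo
    }
    ind_score <- stats::runif(length(idx), 10, 30)
    leak <- stats::runif(length(idx)) < ctr_leak
    jitter <- function(s) s * stats::runif(length(s), 0.8, 1.25)
    mk <- function(chrom, start, width, score, prefix) {
      k <- length(start)
      data.frame(chrom = rep("chrS1", k), start = as.integer(start),
                 end = as.integer(pmin(start + width, chrom_len)),
                 name = sprintf("%s_%04d", prefix, seq_len(k)),
                 score = round(score, 3), strand = rep(".", k),
                 stringsAsFactors = FALSE)
    }
    peaks <- list()
    for (cond in c("Ctr", "HS_10", "HS_20")) {
      b <- mk("chrS1", basal_start, basal_w, jitter(basal_score),
              paste0("basal_", cond))
      if (cond == "Ctr") {
        keep <- leak
        p <- mk("chrS1", ind_start[keep], ind_w[keep],
                stats::runif(sum(keep), 1, 4), "weak_Ctr")
      } else {
        p <- mk("chrS1", ind_start, ind_w, jitter(ind_score),
                paste0("induced_", cond))
      }
      df <- rbind(b, p)
      peaks[[cond]] <- df[order(df$start, df$end), , drop = FALSE]
      rownames(peaks[[cond]]) <- NULL
    }
    planted <- data.frame(gene_id = truth$gene_id[idx], chrom = "chrS1",
                          start = ind_start,
                          end = as.integer(pmin(ind_start + ind_w, chrom_len)),
                          stringsAsFactors = FALSE)
    list(peaks = peaks, planted = planted)
  })
}

#' Simulate a gene-to-term annotation table
#'
#' Background terms are assigned to genes independently at `bg_prob`; four
#' marker terms are additionally enriched (at `enriched_prob`) in the four
#' co-affected regulation-mode classes, giving downstream overrepresentation
#' tests a planted positive.
#'
#' @param cfg a [sim_config()].
#' @param truth output of [simulate_truth()].
#' @param n_terms number of background terms.
#' @param bg_prob background membership probability.
#' @param enriched_prob membership probability of a marker term within its
#'   target class.
#' @return list with `annotations` (data.frame `gene_id`, `term_id`) and
#'   `labels` (data.frame `term_id`, `label`).
#' @export
simulate_terms <- function(cfg, truth, n_terms = 40, bg_prob = 0.05,
                           enriched_prob = 0.6) {
  marker_class <- c(TERM_COACT = "co_activated", TERM_COREP = "co_repressed",
                    TERM_SUPP = "suppressed_activation",
                    TERM_RELIEF = "relieved_repression")
  with_local_seed(sim_seed(cfg, "terms"), {
    n <- nrow(truth)
    rows <- list()
    for (t in seq_len(n_terms)) {
      member <- stats::runif(n) < bg_prob
      if (any(member))
        rows[[length(rows) + 1]] <- data.frame(
          gene_id = truth$gene_id[member],
          term_id = sprintf("TERM_BG%03d", t), stringsAsFactors = FALSE)
    }
    for (tid in names(marker_class)) {
      in_class <- truth$true_mode == marker_class[[tid]]
      p <- ifelse(in_class, enriched_prob, bg_prob)
      member <- stats::runif(n) < p
      if (any(member))
        rows[[length(rows) + 1]] <- data.frame(
          gene_id = truth$gene_id[member], term_id = tid,
          stringsAsFactors = FALSE)
    }
    ann <- do.call(rbind, rows)
    ann <- ann[order(ann$term_id, ann$gene_id), , drop = FALSE]
    rownames(ann) <- NULL
    labels <- data.frame(
      term_id = c(sprintf("TERM_BG%03d", seq_len(n_terms)),
                  names(marker_class)),
      label = c(sprintf("background term %d", seq_len(n_terms)),
                paste("marker term for", unname(marker_class))),
      stringsAsFactors = FALSE)
    list(annotations = ann, labels = labels)
  })
}

#' Simulate a complete planted dataset
#'
#' Convenience wrapper running every generator in order under the seeds
#' derived from `cfg$rng_seed`.
#'
#' @param cfg a [sim_config()].
#' @param pwms PWMs passed to [simulate_promoters()].
#' @return list with elements `cfg`, `truth`, `annotation`, `expression`,
#'   `promoters`, `binding`, `terms`.
#' @export
simulate_dataset <- function(cfg, pwms = list(kb = kb_pwm(),
                                              hse = build_hse_pwm(3))) {
  truth <- simulate_truth(cfg)
  annotation <- simulate_annotation(cfg)
  list(cfg = cfg, truth = truth, annotation = annotation,
       expression = simulate_expression(cfg, truth),
       promoters = simulate_promoters(cfg, truth, pwms),
       binding = simulate_binding(cfg, truth, annotation),
       terms = simulate_terms(cfg, truth),
       pwms = pwms)
}

#' Simulate a pair of tag-count tracks with optional enriched bins
#'
#' Produces fixed-width binned tag tracks for exercising the simple Poisson
#' peak caller: both treatment and reference are Poisson(`lambda`) i.i.d.,
#' and bins listed in `enriched_bins` have their treatment rate multiplied by
#' `fold`.
#'
#' @param n_bins number of bins.
#' @param bin_width bin width in bp.
#' @param lambda background Poisson rate per bin.
#' @param enriched_bins integer indices of enriched bins (may be empty).
#' @param fold rate multiplier in enriched bins.
#' @param chrom chromosome name.
#' @return list with `track` and `reference`, each a data.frame `chrom`,
#'   `start`, `end`, `count`.
#' @export
simulate_tag_tracks <- function(n_bins, bin_width = 100, lambda = 10,
                                enriched_bins = integer(), fold = 5,
                                chrom = "chrS1") {
  start <- (seq_len(n_bins) - 1L) * bin_width
  rate <- rep(lambda, n_bins)
  rate[enriched_bins] <- lambda * fold
  mk <- function(counts) data.frame(chrom = chrom, start = start,
                                    end = start + bin_width,
                                    count = counts, stringsAsFactors = FALSE)
  list(track = mk(stats::rpois(n_bins, rate)),
       reference = mk(stats::rpois(n_bins, lambda)))
}
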