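# End-to-end orchestration: one validated configuration drives
# simulate -> de -> scan -> bind -> classify -> enrich, writing TSV/JSON
# outputs plus a manifest that fully reconstructs the run.

#' Pipeline configuration
#'
#' Builds and validates the configuration for [run_pipeline()]. With
#' `simulate = TRUE` (the default) the input paths are ignored and a planted
#' dataset is generated from `sim`; otherwise `inputs` must point to the
#' annotation, expression, sample-map, promoter FASTA, per-condition BED and
#' term files.
#'
#' @param out_dir output directory.
#' @param simulate generate inputs with [simulate_dataset()]?
#' @param sim a [sim_config()] used when `simulate = TRUE`.
#' @param inputs named list of paths (`annotation`, `expression`,
#'   `sample_map`, `promoters`, `peaks_ctr`, `peaks_hs10`, `peaks_hs20`,
#'   `terms`, optional `pwms`) used when `simulate = FALSE`.
#' @param ratio_up,ratio_down,fdr DE call thresholds.
#' @param fdr_method q-value method (`"storey"` or `"bh"`).
#' @param motif_rel_threshold relative PWM score threshold.
#' @param window_upstream,window_downstream regulatory-window extents (bp).
#' @param peak_fdr FDR for the peak caller / induced-binding test.
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "de", "scan", "bind", "classify", "enrich")`.
#' @param seed integer seed for the run.
#' @return validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir,
                            simulate = TRUE,
                            sim = sim_config(),
                            inputs = list(),
                            ratio_up = 1.2, ratio_down = 0.8, fdr = 0.05,
                            fdr_method = "storey",
                            motif_rel_threshold = 0.8,
                            window_upstream = 7500,
                            window_downstream = 2500,
                            peak_fdr = 0.05,
                            stages = c("simulate", "de", "scan", "bind",
                                       "classify", "enrich"),
                            seed = 1L) {
  cfg <- list(out_dir = out_dir, simulate = simulate, sim = sim,
              inputs = inputs, ratio_up = ratio_up, ratio_down = ratio_down,
              fdr = fdr, fdr_method = fdr_method,
              motif_rel_threshold = motif_rel_threshold,
              window_upstream = window_upstream,
              window_downstream = window_downstream,
              peak_fdr = peak_fdr, stages = stages, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  in_unit <- function(x) is.numeric(x) && length(x) == 1 && x > 0 && x < 1
  if (!in_unit(cfg$fdr) || !in_unit(cfg$peak_fdr))
    stop("fdr and peak_fdr must lie in (0, 1)")
  if (!(cfg$ratio_up > 1)) stop("ratio_up must exceed 1")
  if (!(cfg$ratio_down > 0 && cfg$ratio_down < 1))
    stop("ratio_down must lie in (0, 1)")
  if (!in_unit(cfg$motif_rel_threshold) && cfg$motif_rel_threshold != 1)
    stop("motif_rel_threshold must lie in (0, 1]")
  if (!cfg$fdr_method %in% c("storey", "bh"))
    stop("fdr_method must be 'storey' or 'bh'")
  bad <- setdiff(cfg$stages, c("simulate", "de", "scan", "bind",
                               "classify", "enrich"))
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  if (cfg$window_upstream < 0 || cfg$window_downstream < 0)
    stop("window extents must be >= 0")
  if (!cfg$simulate) {
    need <- c("annotation", "expression", "sample_map", "promoters",
              "peaks_ctr", "peaks_hs10", "peaks_hs20", "terms")
    missing <- setdiff(need, names(cfg$inputs))
    if (length(missing))
      stop("inputs missing: ", paste(missing, collapse = ", "))
    absent <- unlist(cfg$inputs[need])[!file.exists(unlist(cfg$inputs[need]))]
    if (length(absent))
      stop("input files not found: ", paste(absent, collapse = ", "))
  }
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the `sim` key
#' holds [sim_config()] arguments.
#'
#' @param path YAML file.
#' @param ... overrides applied after reading.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) {
    if (!is.null(y$sim$mode_fractions))
      y$sim$mode_fractions <- unlist(y$sim$mode_fractions)
    if (!is.null(y$sim$motif_plant_prob))
      y$sim$motif_plant_prob <- lapply(y$sim$motif_plant_prob, unlist)
    if (!is.null(y$sim$binding_plant_prob))
      y$sim$binding_plant_prob <- unlist(y$sim$binding_plant_prob)
    y$sim <- do.call(sim_config, y$sim)
  }
  args <- utils::modifyList(y, list(...))
  do.call(pipeline_config, args)
}

#' Run the full cross-talk pipeline
#'
#' Executes the enabled stages in order (simulate, differential expression
#' over the standard contrasts, promoter motif scan, HSF1
#' binding-window analysis, combined-effect classification, term
#' overrepresentation of the suppressed-activation subset), writes all
#' result tables under `config$out_dir`, and finishes with a
#' `manifest.json` recording inputs, thresholds, seed, package version and
#' completed stages. Re-running with an identical configuration and seed
#' reproduces the output bundle byte for byte.
#'
#' @param config a [pipeline_config()].
#' @return invisible list with the in-memory results (`de`, `motifs`,
#'   `binding`, `records`, `tally`, `report`, `enrichment`, and `sim` when
#'   simulated).
#' @export
run_pipeline <- function(config) {
  validate_pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(config$out_dir, x)
  done <- character()
  res <- list()
  thresholds <- c(up = config$ratio_up, down = config$ratio_down,
                  fdr = config$fdr)
  pwms <- list(kb = kb_pwm(), hse = build_hse_pwm(3))

  if ("simulate" %in% config$stages && config$simulate) {
    sim <- config$sim
    sim$rng_seed <- config$seed
    res$sim <- simulate_dataset(sim, pwms = pwms)
    write_dataset(res$sim, fp("simulated"))
    annotation <- res$sim$annotation
    expr <- res$sim$expression
    promoters <- res$sim$promoters$sequences
    peaks <- res$sim$binding$peaks
    terms <- res$sim$terms$annotations
    term_labels <- res$sim$terms$labels
    done <- c(done, "simulate")
  } else {
    annotation <- read_annotation(config$inputs$annotation)
    expr <- read_expression(config$inputs$expression,
                            config$inputs$sample_map)
    promoters <- read_promoters(config$inputs$promoters)
    peaks <- list(Ctr = read_peaks_bed(config$inputs$peaks_ctr),
                  HS_10 = read_peaks_bed(config$inputs$peaks_hs10),
                  HS_20 = read_peaks_bed(config$inputs$peaks_hs20))
    terms <- utils::read.delim(config$inputs$terms,
                               stringsAsFactors = FALSE)
    term_labels <- NULL
    if (!is.null(config$inputs$pwms))
      pwms <- read_jaspar(config$inputs$pwms)
  }

  de <- NULL
  if ("de" %in% config$stages) {
    de <- lapply(standard_contrasts(), function(ct)
      de_analysis(expr$matrix, expr$sample_map, ct,
                  fdr_method = config$fdr_method, thresholds = thresholds))
    for (nm in names(de)) {
      out <- de[[nm]]
      out[c("ratio", "t", "p", "q")] <-
        lapply(out[c("ratio", "t", "p", "q")], signif, digits = 8)
      write_tsv(out, fp(sprintf("de_%s.tsv", nm)))
    }
    res$de <- de
    done <- c(done, "de")
  }

  motifs <- NULL
  if ("scan" %in% config$stages) {
    motifs <- motif_presence(promoters, pwms,
                             rel_threshold = config$motif_rel_threshold)
    hits <- attr(motifs, "hits")
    hits$score <- signif(hits$score, 8)
    write_tsv(hits, fp("motif_hits.tsv"))
    write_tsv(motifs, fp("motif_flags.tsv"))
    res$motifs <- motifs
    done <- c(done, "scan")
  }

  binding <- NULL
  if ("bind" %in% config$stages) {
    windows <- make_windows(annotation, config$window_upstream,
                            config$window_downstream)
    write_peaks_bed(
      data.frame(chrom = windows$chrom, start = windows$start,
                 end = windows$end, name = windows$gene_id, score = 0,
                 strand = windows$strand, stringsAsFactors = FALSE),
      fp("windows.bed"))
    assignments <- do.call(rbind, lapply(names(peaks), function(cond)
      cbind(condition = cond, assign_peaks(peaks[[cond]], windows))))
    write_tsv(assignments, fp("peak_assignment.tsv"))
    binding <- call_induced_binding(peaks, windows, method = "score",
                                    fdr = config$peak_fdr)
    write_tsv(binding, fp("binding_calls.tsv"))
    res$binding <- binding
    done <- c(done, "bind")
  }

  records <- NULL
  if ("classify" %in% config$stages) {
    if (is.null(de)) stop("classify stage requires the de stage")
    records <- classify_crosstalk(de$tnf, de$hs, de$hstnf_vs_tnf,
                                  motif_flags = motifs, binding = binding,
                                  thresholds = thresholds)
    out <- records
    out[c("ratio_hstnf_vs_tnf", "q_hstnf_vs_tnf")] <-
      lapply(out[c("ratio_hstnf_vs_tnf", "q_hstnf_vs_tnf")], signif,
             digits = 8)
    write_tsv(out, fp("crosstalk_records.tsv"))
    tally <- tally_subsets(records)
    jsonlite::write_json(tally, fp("tally.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    report <- table1_report(records)
    write_tsv(report, fp("tnf_up_kb_hsf1_report.tsv"))
    res$records <- records
    res$tally <- tally
    res$report <- report
    done <- c(done, "classify")
  }

  if ("enrich" %in% config$stages) {
    if (is.null(records)) stop("enrich stage requires the classify stage")
    background <- records$gene_id
    sub <- records$gene_id[!is.na(records$mode) &
                             records$mode == "suppressed_activation"]
    enr <- if (length(sub))
      enrich(sub, background, terms, alpha = 0.05, labels = term_labels)
    else data.frame()
    if (nrow(enr)) {
      enr[c("p", "p_adj")] <- lapply(enr[c("p", "p_adj")], signif, 8)
    }
    write_tsv(enr, fp("enrichment_suppressed.tsv"))
    res$enrichment <- enr
    done <- c(done, "enrich")
  }

  manifest <- list(
    package = "stressxtalk",
    version = as.character(utils::packageVersion("stressxtalk")),
    seed = config$seed,
    simulate = config$simulate,
    inputs = if (config$simulate) "simulated" else config$inputs,
    thresholds = list(ratio_up = config$ratio_up,
                      ratio_down = config$ratio_down, fdr = config$fdr,
                      fdr_method = config$fdr_method,
                      motif_rel_threshold = config$motif_rel_threshold,
                      window_upstream = config$window_upstream,
                      window_downstream = config$window_downstream,
                      peak_fdr = config$peak_fdr),
    stages = done)
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(res)
}
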