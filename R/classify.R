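# Integration layer: combine the three contrast calls with motif and binding
# flags, assign each TNF-modulated gene a combined-effect mode, and emit the
# subset tallies and the report of TNF-upregulated genes carrying both a kB
# motif and induced HSF1 binding.

CROSSTALK_MODES <- c("enhanced_activation", "enhanced_repression",
                     "suppressed_activation", "relieved_repression",
                     "unaffected")

#' Combined-effect mode of a TNF-modulated gene
#'
#' Classifies how heat-shock pre-treatment changed the cytokine response,
#' using the same ratio/FDR machinery as primary DE calling applied to the
#' HS_TNF-vs-TNF contrast: a significant increase (ratio > up threshold, q <
#' fdr) on a TNF-upregulated gene is `enhanced_activation` (co-activation); a
#' significant decrease on a TNF-upregulated gene is `suppressed_activation`
#' (antagonism); a significant decrease on a TNF-downregulated gene is
#' `enhanced_repression` (co-repression); a significant increase on a
#' TNF-downregulated gene is `relieved_repression`; anything else is
#' `unaffected`.
#'
#' @param call_tnf character vector over `{"up", "down"}` (the TNF-vs-Ctr
#'   call; `"none"` is a contract violation).
#' @param ratio_hstnf_vs_tnf positive linear HS_TNF/TNF signal ratios.
#' @param q_hstnf_vs_tnf q-values of the HS_TNF-vs-TNF contrast.
#' @param thresholds named vector `up`, `down`, `fdr`.
#' @return character vector over the five modes.
#' @export
classify_mode <- function(call_tnf, ratio_hstnf_vs_tnf, q_hstnf_vs_tnf,
                          thresholds = c(up = 1.2, down = 0.8, fdr = 0.05)) {
  if (any(!call_tnf %in% c("up", "down")))
    stop("classify_mode is defined only for TNF-modulated genes (call_tnf up/down)")
  int_call <- call_de(ratio_hstnf_vs_tnf, q_hstnf_vs_tnf, thresholds)
  mode <- rep("unaffected", length(call_tnf))
  mode[call_tnf == "up" & int_call == "up"] <- "enhanced_activation"
  mode[call_tnf == "up" & int_call == "down"] <- "suppressed_activation"
  mode[call_tnf == "down" & int_call == "down"] <- "enhanced_repression"
  mode[call_tnf == "down" & int_call == "up"] <- "relieved_repression"
  mode
}

#' Co-activation / co-repression flags
#'
#' A gene is co-activated when the combined treatment enhanced its activation
#' and the gene is also upregulated by heat shock alone; co-repressed when
#' combined repression is enhanced and the gene is also HS-downregulated.
#'
#' @param mode output of [classify_mode()].
#' @param call_hs HS-vs-Ctr call (`up`/`down`/`none`).
#' @return data.frame `coactivated`, `corepressed` (logical).
#' @export
flag_cofunctions <- function(mode, call_hs) {
  data.frame(coactivated = mode == "enhanced_activation" & call_hs == "up",
             corepressed = mode == "enhanced_repression" & call_hs == "down")
}

table_labels <- function(mode, call_hs, call_tnf) {
  ifelse(mode %in% c("suppressed_activation", "relieved_repression"), "O",
         ifelse(mode == "enhanced_activation" & call_hs == "up" &
                  call_tnf == "up", "A", ""))
}

#' Build per-gene cross-talk records
#'
#' Joins the three contrast call tables on gene id, classifies
#' TNF-modulated genes into combined-effect modes, flags
#' co-activation/co-repression, and attaches motif and binding flags.
#'
#' @param de_tnf,de_hs,de_int [de_analysis()] tables for TNF-vs-Ctr,
#'   HS-vs-Ctr and HS_TNF-vs-TNF.
#' @param motif_flags optional [motif_presence()] table (`gene_id`,
#'   `kb_motif`, `hse_motif`).
#' @param binding optional [call_induced_binding()] table (`gene_id`,
#'   `induced_any`).
#' @param thresholds passed to [classify_mode()].
#' @return data.frame, one row per gene of `de_tnf`: `gene_id`, `call_tnf`,
#'   `call_hs`, `call_hstnf_vs_tnf`, `ratio_hstnf_vs_tnf`,
#'   `q_hstnf_vs_tnf`, `kb_motif`, `hse_motif`, `hsf1_induced`, `mode`
#'   (NA for genes not TNF-modulated), `coactivated`, `corepressed`,
#'   `table_label`.
#' @export
classify_crosstalk <- function(de_tnf, de_hs, de_int, motif_flags = NULL,
                               binding = NULL,
                               thresholds = c(up = 1.2, down = 0.8,
                                              fdr = 0.05)) {
  ids <- de_tnf$gene_id
  pick <- function(df, col, default = NA) {
    if (is.null(df)) return(rep(default, length(ids)))
    v <- df[[col]][match(ids, df$gene_id)]
    v[is.na(v)] <- default
    v
  }
  rec <- data.frame(
    gene_id = ids,
    call_tnf = de_tnf$call,
    call_hs = pick(de_hs, "call", "none"),
    call_hstnf_vs_tnf = pick(de_int, "call", "none"),
    ratio_hstnf_vs_tnf = pick(de_int, "ratio", NA_real_),
    q_hstnf_vs_tnf = pick(de_int, "q", NA_real_),
    kb_motif = pick(motif_flags, "kb_motif", FALSE),
    hse_motif = pick(motif_flags, "hse_motif", FALSE),
    hsf1_induced = pick(binding, "induced_any", FALSE),
    stringsAsFactors = FALSE)
  rec$mode <- rep(NA_character_, nrow(rec))
  mod <- rec$call_tnf != "none"
  if (any(mod))
    rec$mode[mod] <- classify_mode(rec$call_tnf[mod],
                                   rec$ratio_hstnf_vs_tnf[mod],
                                   rec$q_hstnf_vs_tnf[mod], thresholds)
  cf <- flag_cofunctions(ifelse(is.na(rec$mode), "unaffected", rec$mode),
                         rec$call_hs)
  rec$coactivated <- cf$coactivated
  rec$corepressed <- cf$corepressed
  rec$table_label <- ifelse(mod,
                            table_labels(rec$mode, rec$call_hs, rec$call_tnf),
                            "")
  rec
}

#' Subset tallies over cross-talk records
#'
#' Emits the standard count summary: genes modulated by each stimulus, the
#' overlap and its direction-concordant subsets, per-mode counts among
#' TNF-modulated genes, co-activation/co-repression counts, and
#' intersections with the motif and binding flags.
#'
#' @param records output of [classify_crosstalk()].
#' @return named list of integer counts.
#' @export
tally_subsets <- function(records) {
  r <- records
  tnf_mod <- r$call_tnf != "none"
  hs_mod <- r$call_hs != "none"
  mode_counts <- vapply(CROSSTALK_MODES, function(m)
    sum(tnf_mod & !is.na(r$mode) & r$mode == m), integer(1))
  list(
    n_genes = nrow(r),
    tnf_modulated = sum(tnf_mod),
    tnf_up = sum(r$call_tnf == "up"),
    tnf_down = sum(r$call_tnf == "down"),
    hs_modulated = sum(hs_mod),
    hs_up = sum(r$call_hs == "up"),
    hs_down = sum(r$call_hs == "down"),
    overlap = sum(tnf_mod & hs_mod),
    up_both = sum(r$call_tnf == "up" & r$call_hs == "up"),
    down_both = sum(r$call_tnf == "down" & r$call_hs == "down"),
    modes = as.list(mode_counts),
    coactivated = sum(r$coactivated),
    corepressed = sum(r$corepressed),
    kb_in_all = sum(r$kb_motif),
    kb_in_tnf_modulated = sum(r$kb_motif & tnf_mod),
    kb_in_hs_modulated = sum(r$kb_motif & hs_mod),
    kb_in_overlap = sum(r$kb_motif & tnf_mod & hs_mod),
    hse_in_all = sum(r$hse_motif),
    hse_in_tnf_modulated = sum(r$hse_motif & tnf_mod),
    hse_in_hs_modulated = sum(r$hse_motif & hs_mod),
    hse_in_overlap = sum(r$hse_motif & tnf_mod & hs_mod),
    hsf1_induced_all = sum(r$hsf1_induced),
    hsf1_in_tnf_modulated = sum(r$hsf1_induced & tnf_mod),
    hsf1_in_hs_modulated = sum(r$hsf1_induced & hs_mod),
    kb_hsf1_tnf_up = sum(r$kb_motif & r$hsf1_induced & r$call_tnf == "up"))
}

#' Report of TNF-upregulated genes with a kB motif and induced HSF1 binding
#'
#' Filters records to `call_tnf == "up" & kb_motif & hsf1_induced` and
#' formats them as a three-column report: heat-shock direction glyph
#' (up/down/blank for the HS-vs-Ctr call), the HS_TNF/TNF signal ratio, and
#' the combined-effect label (O = antagonistic, A = co-activation, blank =
#' unaffected). Rows are ordered O block, then A block, then unlabelled,
#' with HS-downregulated before HS-upregulated before HS-neutral genes
#' inside each block, alphabetically within ties.
#'
#' @param records output of [classify_crosstalk()].
#' @return data.frame `gene_id`, `hs_direction` (`down`/`up`/`none`),
#'   `ratio_hstnf_vs_tnf`, `label`.
#' @export
table1_report <- function(records) {
  keep <- records$call_tnf == "up" & records$kb_motif & records$hsf1_induced
  r <- records[keep, , drop = FALSE]
  out <- data.frame(gene_id = r$gene_id,
                    hs_direction = ifelse(r$call_hs == "none", "none",
                                          r$call_hs),
                    ratio_hstnf_vs_tnf = r$ratio_hstnf_vs_tnf,
                    label = r$table_label,
                    stringsAsFactors = FALSE)
  block <- match(out$label, c("O", "A", ""))
  glyph <- match(out$hs_direction, c("down", "up", "none"))
  out <- out[order(block, glyph, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Percentage with the reporting rounding rule
#'
#' Rounds `100 * k / n` to the nearest integer, except that values below 2%
#' are reported to the nearest half point (so small subsets are not rounded
#' away to 2% or 1%).
#'
#' @param k numerator count.
#' @param n denominator count.
#' @return numeric percentage.
#' @export
format_pct <- function(k, n) {
  r <- 100 * k / n
  ifelse(r < 2, round(r * 2) / 2, round(r))
}
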