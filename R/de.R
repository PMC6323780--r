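#' Classification thresholds for misalignment-versus-aging regulation
#'
#' Genes are first gated on significance in the misalignment (CCM) contrast
#' at `ccm_fdr`. Among those, agreement with the aging contrast is graded:
#' same-direction changes significant at `aging_strict_fdr` are convergent;
#' same-direction changes with adjusted p in
#' \[`aging_strict_fdr`, `aging_trend_upper`) are a trend; opposite-
#' direction changes significant at the relaxed `aging_opposite_fdr` are
#' opposite regulation. All padj intervals are half-open \[lower, upper).
#'
#' @param ccm_fdr BH FDR gate on the CCM contrast (default 0.1).
#' @param aging_strict_fdr Strict aging FDR for convergence (default 0.1).
#' @param aging_trend_upper Upper bound of the same-direction trend band
#'   (default 0.3).
#' @param aging_opposite_fdr Relaxed FDR for opposite regulation
#'   (default 0.3).
#' @return A named list of class `class_thresholds`.
#' @export
class_thresholds <- function(ccm_fdr = 0.1, aging_strict_fdr = 0.1,
                             aging_trend_upper = 0.3, aging_opposite_fdr = 0.3) {
  stopifnot(ccm_fdr > 0, ccm_fdr <= aging_trend_upper, aging_trend_upper <= 1)
  structure(list(ccm_fdr = ccm_fdr, aging_strict_fdr = aging_strict_fdr,
                 aging_trend_upper = aging_trend_upper,
                 aging_opposite_fdr = aging_opposite_fdr),
            class = "class_thresholds")
}

REGULATION_CLASSES <- c("convergent", "trend_same", "opposite",
                        "not_ccm_significant", "unclassified")

#' Read a differential-expression result table
#'
#' @param path TSV with columns `gene`, `log2fc`, `padj` (`NA` allowed for
#'   genes filtered out on low counts).
#' @return Tibble `gene`, `log2fc`, `padj`.
#' @export
read_de_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(gene = "c", log2fc = "d", padj = "d"))
}

#' Cross-classify genes by misalignment versus aging regulation
#'
#' Joins a CCM contrast (misaligned vs control) with an aging contrast
#' (old vs young control) by gene and assigns each gene exactly one class:
#'
#' * `not_ccm_significant` — `ccm_padj >= ccm_fdr`;
#' * `convergent` — same-sign fold changes, `aging_padj < aging_strict_fdr`;
#' * `trend_same` — same sign, `aging_strict_fdr <= aging_padj <
#'   aging_trend_upper`;
#' * `opposite` — opposite-sign fold changes, `aging_padj <
#'   aging_opposite_fdr`;
#' * `unclassified` — missing values, zero fold change (sign undefined;
#'   warned), or aging change too uncertain to grade.
#'
#' @param ccm,aging Data frames with columns `gene`, `log2fc`, `padj`
#'   (see [read_de_table()]). Genes absent from one table get missing
#'   values there.
#' @param thresholds A [class_thresholds()].
#' @return Tibble `gene`, `ccm_log2fc`, `ccm_padj`, `aging_log2fc`,
#'   `aging_padj`, `regulation_class` (factor over the five classes).
#' @export
classify_regulation <- function(ccm, aging, thresholds = class_thresholds()) {
  for (nm in list(list(ccm, "ccm"), list(aging, "aging"))) {
    dup <- unique(nm[[1]]$gene[duplicated(nm[[1]]$gene)])
    if (length(dup) > 0) {
      abort(sprintf("duplicate gene id(s) in %s table: %s (de-duplicate upstream)",
                    nm[[2]], paste(head(dup, 5), collapse = ", ")))
    }
  }
  th <- thresholds
  joined <- dplyr::full_join(
    dplyr::rename(as_tibble(ccm), ccm_log2fc = "log2fc", ccm_padj = "padj"),
    dplyr::rename(as_tibble(aging), aging_log2fc = "log2fc", aging_padj = "padj"),
    by = "gene")
  complete <- !is.na(joined$ccm_log2fc) & !is.na(joined$ccm_padj) &
    !is.na(joined$aging_log2fc) & !is.na(joined$aging_padj)
  zero_fc <- complete & joined$ccm_padj < th$ccm_fdr &
    (joined$ccm_log2fc == 0 | joined$aging_log2fc == 0)
  if (any(zero_fc)) {
    warn(sprintf("%d gene(s) with log2FC exactly 0: direction undefined, left unclassified",
                 sum(zero_fc)))
  }
  same <- sign(joined$ccm_log2fc) == sign(joined$aging_log2fc)
  cls <- dplyr::case_when(
    !complete ~ "unclassified",
    joined$ccm_padj >= th$ccm_fdr ~ "not_ccm_significant",
    zero_fc ~ "unclassified",
    same & joined$aging_padj < th$aging_strict_fdr ~ "convergent",
    same & joined$aging_padj < th$aging_trend_upper ~ "trend_same",
    !same & joined$aging_padj < th$aging_opposite_fdr ~ "opposite",
    .default = "unclassified"
  )
  joined$regulation_class <- factor(cls, levels = REGULATION_CLASSES)
  joined[, c("gene", "ccm_log2fc", "ccm_padj", "aging_log2fc", "aging_padj",
             "regulation_class")]
}

#' Class counts split by CCM direction
#'
#' @param classified Output of [classify_regulation()].
#' @return Tibble `regulation_class`, `ccm_direction` (`up`/`down`), `n`,
#'   covering every class x direction combination (zero-filled).
#' @export
regulation_counts <- function(classified) {
  x <- classified[!is.na(classified$ccm_log2fc) & classified$ccm_log2fc != 0, ]
  x$ccm_direction <- ifelse(x$ccm_log2fc > 0, "up", "down")
  counts <- dplyr::count(x, .data$regulation_class, .data$ccm_direction,
                         .drop = FALSE)
  tidyr::complete(counts, regulation_class = factor(REGULATION_CLASSES,
                                                    levels = REGULATION_CLASSES),
                  ccm_direction = c("down", "up"), fill = list(n = 0L))
}

#' Fold-change correlation between two contrasts
#'
#' Rank (Spearman, default) or Pearson correlation of per-gene log2 fold
#' changes on the genes shared by both tables, with a Fisher-z 95%
#' confidence interval.
#'
#' @param table_a,table_b Data frames with columns `gene`, `log2fc`.
#' @param genes Optional gene subset.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return Tibble `rho`, `conf.low`, `conf.high`, `p.value`, `n`, `method`.
#' @export
fc_correlation <- function(table_a, table_b, genes = NULL,
                           method = c("spearman", "pearson")) {
  method <- match.arg(method)
  j <- dplyr::inner_join(
    dplyr::select(as_tibble(table_a), "gene", a = "log2fc"),
    dplyr::select(as_tibble(table_b), "gene", b = "log2fc"),
    by = "gene")
  if (!is.null(genes)) j <- j[j$gene %in% genes, ]
  j <- j[stats::complete.cases(j$a, j$b), ]
  if (nrow(j) < 4) abort("need at least 4 shared genes")
  if (length(unique(j$a)) < 2 || length(unique(j$b)) < 2) {
    abort("degenerate fold-change vector: correlation undefined")
  }
  ct <- suppressWarnings(cor.test(j$a, j$b, method = method, exact = FALSE))
  r <- unname(ct$estimate)
  z <- atanh(r)
  se <- 1 / sqrt(nrow(j) - 3)
  tibble(rho = r,
         conf.low = tanh(z - qnorm(0.975) * se),
         conf.high = tanh(z + qnorm(0.975) * se),
         p.value = ct$p.value, n = nrow(j), method = method)
}

#' Bundled example gene tables
#'
#' A curated 16-gene example set: genes significantly regulated by chronic
#' circadian misalignment (week-3 contrast) whose aging contrast runs in
#' the opposite direction, shipped as two 3-column TSVs. Useful as a
#' worked example for [classify_regulation()] — all 16 genes classify as
#' `opposite` (12 down-, 4 upregulated by misalignment).
#'
#' @param which `"ccm"` (week-3 misalignment contrast) or `"aging"`
#'   (old-vs-young control contrast).
#' @return Path to the TSV inside the installed package.
#' @export
example_de_table <- function(which = c("ccm", "aging")) {
  which <- match.arg(which)
  system.file("extdata",
              sprintf("opposite_regulation_%s.tsv", which),
              package = "misalignr", mustWork = TRUE)
}
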