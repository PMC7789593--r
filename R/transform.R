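#' Directionalize differential-expression p-values
#'
#' The mixture model explains an enrichment of small p-values but p-values
#' carry no sign, so the analysis is run twice. In the down-analysis every
#' gene with fold change greater than 1 (log2 fold change > 0) has its
#' p-value replaced by `1 - p`, so only downregulated genes can retain small
#' p-values; the up-analysis is the mirror image. Genes with fold change
#' exactly 1 (log2fc == 0) are left unchanged in both modes. Genes with a
#' missing fold change or p-value are dropped with a message stating the
#' count. Resulting zeros are clamped to `floor` so every value lies in
#' (0, 1].
#'
#' @param de_table Tibble with columns `gene`, `log2fc`, `pval` (`pval` in
#'   \[0, 1\]).
#' @param mode `"up"`, `"down"`, or `"raw"` (no directionalization, floor
#'   clamp only).
#' @param floor Lower clamp applied after transformation; default `1e-12`.
#' @return A tibble with `gene` and transformed `pval`, with the mode stored
#'   in attribute `"mode"`.
#' @examples
#' de <- tibble::tibble(gene = c("a", "b"), log2fc = c(1, -1), pval = c(0.01, 0.02))
#' transform_de_pvalues(de, "down")$pval  # 0.99, 0.02
#' @export
transform_de_pvalues <- function(de_table, mode = c("up", "down", "raw"),
                                 floor = 1e-12) {
  mode <- match.arg(mode)
  stopifnot(all(c("gene", "log2fc", "pval") %in% names(de_table)),
            floor > 0, floor < 1)
  keep <- !is.na(de_table$log2fc) & !is.na(de_table$pval)
  if (any(!keep)) {
    message(sum(!keep), " gene(s) dropped for missing fold change or p-value")
    de_table <- de_table[keep, ]
  }
  if (any(de_table$pval < 0 | de_table$pval > 1)) {
    stop("input p-values must lie in [0, 1]")
  }
  p <- de_table$pval
  flip <- switch(mode,
    down = de_table$log2fc > 0,
    up = de_table$log2fc < 0,
    raw = rep(FALSE, length(p))
  )
  p[flip] <- 1 - p[flip]
  p <- pmax(p, floor)
  out <- tibble::tibble(gene = de_table$gene, pval = p)
  attr(out, "mode") <- mode
  out
}
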