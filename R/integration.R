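#' Overlap differential proteins with differential genes
#'
#' Intersects the significant feature sets of a proteomic and a transcriptomic
#' differential-expression analysis (after mapping protein ids to gene
#' symbols) and records, per common target, both log2 fold changes and
#' whether their directions agree. Concordance is reported, not used as a
#' membership filter. Venn-style exclusive counts accompany the table.
#'
#' @param prot_de data.frame with `feature`, `log2fc`, `significant` (protein
#'   arm).
#' @param rna_de data.frame with the same columns (gene arm, gene symbols).
#' @param id_map optional two-column data.frame mapping protein ids to gene
#'   symbols; unmappable significant proteins are excluded and counted.
#' @return an object of class `overlap_report`: list with `common`
#'   (data.frame `gene`, `protein_log2fc`, `gene_log2fc`, `concordant`),
#'   `n_common`, `n_protein_only`, `n_rna_only`, `n_unmapped`.
#' @export
overlap_targets <- function(prot_de, rna_de, id_map = NULL) {
  stopifnot(!is.null(prot_de$significant), !is.null(rna_de$significant))
  ps <- prot_de[prot_de$significant, , drop = FALSE]
  gs <- rna_de[rna_de$significant, , drop = FALSE]
  n_unmapped <- 0L
  if (!is.null(id_map)) {
    idx <- match(ps$feature, id_map[[1]])
    n_unmapped <- sum(is.na(idx))
    ps <- ps[!is.na(idx), , drop = FALSE]
    ps$feature <- id_map[[2]][idx[!is.na(idx)]]
  }
  common <- intersect(ps$feature, gs$feature)
  pfc <- ps$log2fc[match(common, ps$feature)]
  gfc <- gs$log2fc[match(common, gs$feature)]
  tab <- data.frame(gene = common, protein_log2fc = pfc, gene_log2fc = gfc,
                    concordant = sign(pfc) == sign(gfc),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$gene), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(common = tab,
                 n_common = nrow(tab),
                 n_protein_only = length(setdiff(ps$feature, gs$feature)),
                 n_rna_only = length(setdiff(gs$feature, ps$feature)),
                 n_unmapped = n_unmapped),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("overlap_report: %d common, %d protein-only, %d gene-only (%d unmapped)\n",
              x$n_common, x$n_protein_only, x$n_rna_only, x$n_unmapped))
  if (x$n_common) print(x$common)
  invisible(x)
}
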