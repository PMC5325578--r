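#' Relative quantification of qRT-PCR data (2^-ddCt)
#'
#' Expression of a gene is first normalised to a reference gene
#' (beta-actin role) within each condition (dCt = Ct_gene - Ct_ref),
#' then to the control condition (ddCt = dCt_treat - dCt_control); the
#' fold change is 2^-ddCt. Technical then biological replicates are
#' averaged on the Ct scale before the subtraction.
#'
#' @name expression
NULL

#' 2^-ddCt fold change
#'
#' @param ct_t_treat,ct_ref_treat target and reference Ct in the treated
#'   condition.
#' @param ct_t_ctrl,ct_ref_ctrl target and reference Ct in the control
#'   condition.
#' @return `2^-((ct_t_treat - ct_ref_treat) - (ct_t_ctrl - ct_ref_ctrl))`.
#' @export
fold_change <- function(ct_t_treat, ct_ref_treat, ct_t_ctrl, ct_ref_ctrl) {
  2^-((ct_t_treat - ct_ref_treat) - (ct_t_ctrl - ct_ref_ctrl))
}

#' Fold changes for a table of Ct measurements
#'
#' @param ct data frame with columns `gene`, `condition`, `replicate`,
#'   `ct_target`, `ct_reference`.
#' @param control name of the control condition.
#' @return data frame `gene`, `condition`, `fold_change` (the control
#'   condition's own fold change is 1 by construction).
#' @export
ddct_table <- function(ct, control) {
  stopifnot(control %in% ct$condition,
            all(is.finite(ct$ct_target)), all(is.finite(ct$ct_reference)))
  mean_ct <- stats::aggregate(cbind(ct_target, ct_reference) ~ gene + condition,
                              data = ct, FUN = mean)
  out <- lapply(split(mean_ct, mean_ct$gene), function(g) {
    ctrl <- g[g$condition == control, , drop = FALSE]
    if (!nrow(ctrl)) stop("gene ", g$gene[1], " has no control measurements")
    data.frame(gene = g$gene, condition = g$condition,
               fold_change = fold_change(g$ct_target, g$ct_reference,
                                         ctrl$ct_target[1],
                                         ctrl$ct_reference[1]),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
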