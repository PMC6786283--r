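#' Protein-by-sample peptide count table
#'
#' Spectral peptide counts from a co-immunoprecipitation experiment. Samples
#' carry roles: the immunoprecipitate (`"IP"`) and two kinds of negative
#' control (`"blocked_control"`: antibody blocked with its epitope peptide;
#' `"IgG_control"`: non-specific IgG).
#'
#' @param counts non-negative integer matrix, proteins x samples, with
#'   dimnames
#' @param roles character vector, one role per sample column, values in
#'   `c("IP", "blocked_control", "IgG_control")`
#' @return an object of class `peptide_table`
#' @export
peptide_table <- function(counts, roles) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == length(roles),
            all(roles %in% c("IP", "blocked_control", "IgG_control")),
            all(counts >= 0), all(counts == round(counts)))
  if (!any(roles == "IP")) stop("need at least one IP sample")
  if (is.null(rownames(counts)) && nrow(counts) > 0)
    rownames(counts) <- paste0("P", seq_len(nrow(counts)))
  structure(list(counts = counts, roles = roles), class = "peptide_table")
}

#' Filter co-IP interactors by peptide evidence
#'
#' A protein is retained as a putative interactor when it has at least
#' `min_peptides` significantly matching peptides in the immunoprecipitate
#' (per-IP-replicate aggregation by maximum by default) and is absent (zero
#' peptides) from every negative control, both blocked-antibody and IgG.
#' Output is deterministic: sorted by descending IP evidence, then protein
#' id.
#'
#' @param table a `peptide_table` (must contain at least one control column)
#' @param min_peptides minimum IP peptide count (default 2)
#' @param aggregate how to combine multiple IP replicates: `"max"` (default)
#'   or `"sum"`
#' @return character vector of retained protein ids, with an `evidence`
#'   attribute (data.frame of per-protein IP and control counts)
#' @export
filter_interactors <- function(table, min_peptides = 2,
                               aggregate = c("max", "sum")) {
  stopifnot(inherits(table, "peptide_table"), min_peptides >= 0)
  aggregate <- match.arg(aggregate)
  ip_cols <- table$roles == "IP"
  ctrl_cols <- !ip_cols
  if (!any(ctrl_cols))
    stop("filter undefined: table has no negative-control columns")
  counts <- table$counts
  if (nrow(counts) == 0) {
    out <- character(0)
    attr(out, "evidence") <- data.frame(protein = character(0),
                                        ip = numeric(0), control = numeric(0))
    return(out)
  }
  agg_fun <- if (aggregate == "max") function(m) apply(m, 1, max) else rowSums
  ip <- agg_fun(counts[, ip_cols, drop = FALSE])
  ctrl <- apply(counts[, ctrl_cols, drop = FALSE], 1, max)
  keep <- ip >= min_peptides & ctrl == 0
  ids <- rownames(counts)[keep]
  ord <- order(-ip[keep], ids)
  out <- ids[ord]
  attr(out, "evidence") <- data.frame(protein = out,
                                      ip = unname(ip[keep][ord]),
                                      control = unname(ctrl[keep][ord]))
  out
}
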