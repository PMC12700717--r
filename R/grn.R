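# Stage-progression regulatory network: trend-filter expression by group
# means across the ordered stages, join the surviving miRNAs and genes with
# a miRNA -> target interaction table, and rank hub miRNAs by out-degree.

#' Filter features by a monotone group-mean trend
#'
#' Keeps features whose group means across the stage order healthy -> T2c
#' -> T3b are strictly monotone in the requested direction, each step
#' exceeding the margin `delta`.
#'
#' @param norm Normalized expression matrix, features x samples.
#' @param groups Factor with levels `healthy`, `T2c`, `T3b`, one per
#'   sample column.
#' @param direction `"decreasing"` (mRNA convention) or `"increasing"`
#'   (miRNA convention).
#' @param delta Nonnegative per-step margin (default 0: weak monotone).
#' @return Character vector of surviving feature ids.
#' @export
trend_filter <- function(norm, groups,
                         direction = c("decreasing", "increasing"),
                         delta = 0) {
  direction <- match.arg(direction)
  groups <- factor(groups, levels = c("healthy", "T2c", "T3b"))
  if (any(is.na(groups)) || nlevels(droplevels(groups)) != 3)
    stopf("all three groups (healthy, T2c, T3b) must be present")
  mH <- rowMeans(norm[, groups == "healthy", drop = FALSE])
  m2 <- rowMeans(norm[, groups == "T2c", drop = FALSE])
  m3 <- rowMeans(norm[, groups == "T3b", drop = FALSE])
  keep <- if (direction == "decreasing")
    (mH - m2 > delta) & (m2 - m3 > delta)
  else
    (m2 - mH > delta) & (m3 - m2 > delta)
  rownames(norm)[keep]
}

#' Build the bipartite miRNA-target regulatory network
#'
#' Induces the subgraph of the interaction table on the filtered miRNA and
#' gene sets, deduplicates edges, computes miRNA out-degrees and returns
#' hubs (degree >= `hub_min_degree`), sorted by descending degree with
#' lexicographic tie-break.
#'
#' @param mirnas Character vector of retained miRNAs (e.g. from
#'   [trend_filter()] with `direction = "increasing"`).
#' @param genes Character vector of retained target genes.
#' @param interactions Data frame with columns `mirna`, `gene`.
#' @param hub_min_degree Minimum out-degree for hub status (default 2).
#' @return List of class `bipartite_grn`: `edges` (deduplicated data
#'   frame), `degrees` (named, descending), `hubs`, `covered_genes` (genes
#'   reached by hubs), `n_mirna`, `n_gene`.
#' @export
build_grn <- function(mirnas, genes, interactions, hub_min_degree = 2) {
  if (!nrow(interactions)) stopf("empty interaction table")
  if (!all(c("mirna", "gene") %in% names(interactions)))
    stopf("interaction table needs 'mirna' and 'gene' columns")
  sub <- interactions[interactions$mirna %in% mirnas &
                        interactions$gene %in% genes, c("mirna", "gene")]
  sub <- unique(sub)
  if (!nrow(sub)) {
    return(structure(list(edges = sub, degrees = integer(0),
                          hubs = character(0), covered_genes = character(0),
                          n_mirna = 0L, n_gene = 0L),
                     class = "bipartite_grn"))
  }
  deg <- table(sub$mirna)
  deg <- deg[order(-deg, names(deg))]
  degrees <- stats::setNames(as.integer(deg), names(deg))
  hubs <- names(degrees)[degrees >= hub_min_degree]
  covered <- sort(unique(sub$gene[sub$mirna %in% hubs]))
  rownames(sub) <- NULL
  structure(list(edges = sub, degrees = degrees, hubs = hubs,
                 covered_genes = covered,
                 n_mirna = length(unique(sub$mirna)),
                 n_gene = length(unique(sub$gene))),
            class = "bipartite_grn")
}
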