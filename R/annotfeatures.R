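## annotfeatures: binary target-gene and pathway descriptors built from a
## target map and pathway gene sets. "High-potential" targets are those at or
## above the score threshold (default 80, the usual convention for confident
## target predictions).

#' Annotation-descriptor configuration
#'
#' @param score_threshold minimum prediction score (0-100) for a target gene
#'   to count as high-potential. Default 80.
#' @param max_genes_per_mirna optional cap: keep only the top-scoring genes of
#'   each miRNA after thresholding.
#' @param gene_universe optional explicit gene list defining the descriptor
#'   columns; default is the union of passing targets of the supplied miRNAs,
#'   sorted alphabetically for determinism.
#' @return An `annot_descriptor_config` list.
#' @export
annot_descriptor_config <- function(score_threshold = 80,
                                    max_genes_per_mirna = NULL,
                                    gene_universe = NULL) {
  if (score_threshold < 0 || score_threshold > 100) {
    stop_config("score_threshold must lie in [0,100]")
  }
  if (!is.null(max_genes_per_mirna) && max_genes_per_mirna < 1) {
    stop_config("max_genes_per_mirna must be >= 1 when set")
  }
  structure(list(score_threshold = score_threshold,
                 max_genes_per_mirna = max_genes_per_mirna,
                 gene_universe = if (is.null(gene_universe)) NULL
                                 else toupper(gene_universe)),
            class = "annot_descriptor_config")
}

# passing (miRNA, gene) edges after threshold + optional per-miRNA cap
passing_targets <- function(targets, config) {
  keep <- targets[targets$score >= config$score_threshold, , drop = FALSE]
  cap <- config$max_genes_per_mirna
  if (!is.null(cap) && nrow(keep)) {
    keep <- do.call(rbind, lapply(split(keep, keep$mirna), function(d) {
      d[order(-d$score, d$gene), , drop = FALSE][seq_len(min(cap, nrow(d))), ,
                                                 drop = FALSE]
    }))
    rownames(keep) <- NULL
  }
  keep
}

#' Binary target-gene descriptors
#'
#' One binary attribute `gene_<SYMBOL>` per gene in the descriptor universe;
#' a cell is 1 iff that (miRNA, gene) prediction passes the score threshold.
#' miRNAs without any passing target get all-zero rows and are reported via a
#' coverage message.
#'
#' @param targets a `target_gene_map`.
#' @param mirnas character vector of miRNA ids defining the rows (in order).
#' @param config an [annot_descriptor_config()].
#' @param labels optional class labels aligned with `mirnas`.
#' @return A `feature_table` of binary attributes.
#' @export
target_gene_descriptors <- function(targets, mirnas,
                                    config = annot_descriptor_config(),
                                    labels = NULL) {
  if (!length(mirnas)) stop_domain("target_gene_descriptors: no miRNA ids")
  keep <- passing_targets(targets, config)
  universe <- config$gene_universe %||%
    sort(unique(keep$gene[keep$mirna %in% mirnas]))
  if (!length(universe)) {
    stop_config("empty gene universe after score filtering (threshold %s)",
                config$score_threshold)
  }
  values <- matrix(0, nrow = length(mirnas), ncol = length(universe),
                   dimnames = list(mirnas, paste0("gene_", universe)))
  keep <- keep[keep$mirna %in% mirnas & keep$gene %in% universe, , drop = FALSE]
  if (nrow(keep)) values[cbind(keep$mirna, paste0("gene_", keep$gene))] <- 1
  uncovered <- mirnas[rowSums(values) == 0]
  if (length(uncovered)) {
    message(sprintf("target_gene_descriptors: %d/%d miRNA(s) without passing targets: %s",
                    length(uncovered), length(mirnas),
                    paste(utils::head(uncovered, 5), collapse = ", ")))
  }
  feature_table(values, "binary", labels = labels)
}

path_slug <- function(name) {
  gsub("^_+|_+$", "", gsub("[^A-Za-z0-9]+", "_", name))
}

#' Binary pathway descriptors
#'
#' One binary attribute `path_<slug>` per pathway; a cell is 1 iff at least
#' one passing target gene of the miRNA belongs to the pathway's gene set.
#' Pathways disjoint from every passing target produce a warning but their
#' all-zero columns are retained.
#'
#' @param targets a `target_gene_map`.
#' @param pathways a `pathway_gene_sets`.
#' @inheritParams target_gene_descriptors
#' @return A `feature_table` of binary attributes.
#' @export
pathway_descriptors <- function(targets, pathways, mirnas,
                                config = annot_descriptor_config(),
                                labels = NULL) {
  if (!length(mirnas)) stop_domain("pathway_descriptors: no miRNA ids")
  if (!length(pathways)) stop_domain("pathway_descriptors: no pathways")
  keep <- passing_targets(targets, config)
  genes_by_mirna <- split(keep$gene, factor(keep$mirna, levels = mirnas))
  slugs <- paste0("path_", path_slug(names(pathways)))
  if (anyDuplicated(slugs)) {
    stop_domain("pathway names collide after slugging: %s",
                paste(unique(slugs[duplicated(slugs)]), collapse = ", "))
  }
  values <- matrix(0, nrow = length(mirnas), ncol = length(pathways),
                   dimnames = list(mirnas, slugs))
  for (j in seq_along(pathways)) {
    hit <- vapply(genes_by_mirna, function(g) any(g %in% pathways[[j]]),
                  logical(1))
    values[, j] <- as.numeric(hit)
  }
  dead <- colSums(values) == 0
  if (any(dead)) {
    warning(sprintf("pathway_descriptors: %d pathway(s) disjoint from all passing targets (all-zero columns retained)",
                    sum(dead)), call. = FALSE)
  }
  feature_table(values, "binary", labels = labels)
}
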