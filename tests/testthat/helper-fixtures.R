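# Shared fixture builders; everything is generated in code.

random_rna <- function(n, len_range = c(16, 28)) {
  vapply(seq_len(n), function(i) {
    len <- sample(len_range[1]:len_range[2], 1)
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# a small labeled table with one perfectly informative binary attribute,
# one constant, and one numeric noise attribute
toy_table <- function(n_per_class = 10, seed = 42) {
  withr::with_seed(seed, {
    labels <- rep(c("negative", "positive"), each = n_per_class)
    v <- cbind(copy = as.numeric(labels == "positive"),
               const = 0,
               noise = stats::runif(2 * n_per_class))
    rownames(v) <- sprintf("m%02d", seq_len(2 * n_per_class))
    feature_table(v, c("binary", "binary", "numeric"), labels = labels)
  })
}

tiny_targets <- function() {
  target_gene_map(
    mirna = c("hsa-miR-21-3p", "hsa-miR-21-3p", "hsa-miR-32-3p", "hsa-miR-99"),
    gene = c("MAPK1", "TP53", "PTEN", "MAPK1"),
    score = c(92, 85, 90, 60))
}

tiny_pathways <- function() {
  structure(list(`p53 signaling pathway` = c("TP53", "CDKN1A"),
                 `MAPK signaling pathway` = c("MAPK1", "AKT1"),
                 `orphan pathway` = c("ZZZ9")),
            class = "pathway_gene_sets")
}
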