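## seqio: readers/writers for the formats the pipeline touches.
## FASTA parsing itself is delegated to Biostrings; the wrapper adds the
## miRBase-header convention (first token = id, rest = description), RNA
## canonicalization and the uniqueness/alphabet contracts.

#' Read mature miRNA sequences from a miRBase-dialect FASTA file
#'
#' Headers follow the `mature.fa` layout: the first whitespace-separated token
#' is the miRNA id (e.g. `hsa-miR-21-3p`), the remainder is free-text
#' description. With `canonicalize = TRUE` (default) sequences are uppercased
#' and `T` is mapped to `U`, accommodating DNA-alphabet exports; with
#' `canonicalize = FALSE` any `T` is an alphabet violation.
#'
#' @param path FASTA file path.
#' @param canonicalize uppercase and map T to U before validation.
#' @return A `mirna_set`: data frame with columns `id`, `sequence`,
#'   `description`.
#' @export
read_mirna_fasta <- function(path, canonicalize = TRUE) {
  if (!file.exists(path)) stop_io("FASTA file not found: %s", path)
  check_fasta_structure(path)
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- as.character(set)
  if (canonicalize) {
    seqs <- chartr("t", "u", chartr("T", "U", toupper(seqs)))
  }
  bad <- grepl("[^ACGU]", seqs)
  if (any(bad)) {
    stop_format("non-ACGU character in sequence of record '%s'",
                ids[which(bad)[1]])
  }
  if (anyDuplicated(ids)) {
    stop_format("duplicate miRNA id(s) in FASTA: %s",
                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  mirna_set(ids, seqs, desc)
}

# minimal structural pre-scan so malformed FASTA is reported with a line number
check_fasta_structure <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (!length(nonempty)) return(invisible(TRUE))
  if (!startsWith(lines[nonempty[1]], ">")) {
    stop_format("malformed FASTA at line %d: expected '>' header", nonempty[1])
  }
  # every header must be followed by at least one sequence line
  hdr <- nonempty[startsWith(lines[nonempty], ">")]
  for (h in hdr) {
    nxt <- nonempty[nonempty > h]
    if (!length(nxt) || startsWith(lines[nxt[1]], ">")) {
      stop_format("malformed FASTA at line %d: header without sequence", h)
    }
  }
  invisible(TRUE)
}

#' Construct a mature-miRNA record collection
#'
#' @param id unique accession-like ids.
#' @param sequence uppercase RNA strings (A/C/G/U), length >= 1.
#' @param description free-text descriptions (default empty).
#' @return A `mirna_set` data frame.
#' @export
mirna_set <- function(id, sequence, description = "") {
  if (anyDuplicated(id)) {
    stop_domain("duplicate miRNA id(s): %s",
                paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (any(!nzchar(sequence))) stop_domain("empty miRNA sequence for id '%s'",
                                          id[which(!nzchar(sequence))[1]])
  if (any(grepl("[^ACGU]", sequence))) {
    stop_domain("sequence of '%s' contains non-ACGU characters",
                id[which(grepl("[^ACGU]", sequence))[1]])
  }
  out <- data.frame(id = as.character(id), sequence = as.character(sequence),
                    description = rep_len(as.character(description), length(id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("mirna_set", "data.frame")
  out
}

#' Write miRNA records as FASTA
#'
#' @param records a `mirna_set`.
#' @param path output path.
#' @export
write_mirna_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- ifelse(nzchar(records$description),
                       paste(records$id, records$description),
                       records$id)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a miRDB-style miRNA target-gene table
#'
#' Tab-separated with at least three columns: miRNA id, gene symbol,
#' prediction score in \[0,100\]. A header row is auto-detected (score field
#' not numeric). Gene symbols are uppercased; exact duplicate rows are
#' collapsed, conflicting scores for the same (miRNA, gene) pair are an error.
#'
#' @param path TSV file path.
#' @return A `target_gene_map`: data frame with columns `mirna`, `gene`,
#'   `score`.
#' @export
read_target_table <- function(path) {
  if (!file.exists(path)) stop_io("target table not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(target_gene_map(character(), character(), numeric()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3)) {
    stop_format("target table row %d has fewer than 3 tab-separated columns",
                which(lengths(fields) < 3)[1])
  }
  start <- 1L
  if (is.na(suppressWarnings(as.numeric(fields[[1]][3])))) start <- 2L  # header
  if (start > length(fields)) {
    return(target_gene_map(character(), character(), numeric()))
  }
  fields <- fields[start:length(fields)]
  mirna <- vapply(fields, `[`, character(1), 1)
  gene <- vapply(fields, `[`, character(1), 2)
  score_chr <- vapply(fields, `[`, character(1), 3)
  score <- suppressWarnings(as.numeric(score_chr))
  if (anyNA(score)) {
    stop_format("unparseable score '%s' in target table row %d",
                score_chr[which(is.na(score))[1]],
                which(is.na(score))[1] + start - 1L)
  }
  target_gene_map(mirna, gene, score)
}

#' Construct a miRNA -> target-gene map
#'
#' @param mirna miRNA ids.
#' @param gene gene symbols (uppercased on construction).
#' @param score prediction scores in \[0,100\].
#' @return A `target_gene_map` data frame.
#' @export
target_gene_map <- function(mirna, gene, score) {
  gene <- toupper(gene)
  if (length(score) && (any(score < 0) || any(score > 100))) {
    stop_domain("target scores must lie in [0,100]")
  }
  df <- unique(data.frame(mirna = as.character(mirna), gene = gene,
                          score = as.numeric(score), stringsAsFactors = FALSE))
  key <- paste(df$mirna, df$gene, sep = "\r")
  if (anyDuplicated(key)) {
    stop_format("conflicting scores for (miRNA, gene) pair(s): %s",
                paste(unique(sub("\r", "/", key[duplicated(key)])), collapse = ", "))
  }
  class(df) <- c("target_gene_map", "data.frame")
  df
}

#' Read pathway gene sets (TSV or GMT)
#'
#' `.gmt` files use the GMT layout (name, description, then one gene per
#' column); any other extension is read as TSV: pathway name, tab, then gene
#' symbols separated by commas or further tabs. Blank lines are skipped, gene
#' symbols are uppercased, pathway names must be unique and every pathway must
#' have at least one gene.
#'
#' @param path file path (`.gmt` selects the GMT dialect).
#' @return A `pathway_gene_sets`: named list of character vectors.
#' @export
read_pathway_sets <- function(path) {
  if (!file.exists(path)) stop_io("pathway file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  gmt <- grepl("\\.gmt$", path, ignore.case = TRUE)
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (gmt) {
      name <- f[1]
      genes <- f[-(1:2)]
    } else {
      name <- f[1]
      genes <- unlist(strsplit(f[-1], ",", fixed = TRUE))
    }
    genes <- toupper(trimws(genes))
    genes <- genes[nzchar(genes)]
    if (!length(genes)) {
      stop_format("pathway '%s' (line %d) has no genes", name, lineno[i])
    }
    if (name %in% names(sets)) {
      stop_format("duplicate pathway name '%s' (line %d)", name, lineno[i])
    }
    sets[[name]] <- unique(genes)
  }
  structure(sets, class = "pathway_gene_sets")
}

#' Write pathway gene sets as TSV
#' @param pathways a `pathway_gene_sets` (named list of gene vectors).
#' @param path output path.
#' @export
write_pathway_sets <- function(pathways, path) {
  writeLines(vapply(names(pathways), function(n) {
    paste(n, paste(pathways[[n]], collapse = ","), sep = "\t")
  }, character(1)), path)
  invisible(path)
}

#' Write a miRNA target table as TSV
#' @param targets a `target_gene_map`.
#' @param path output path.
#' @export
write_target_table <- function(targets, path) {
  writeLines(c("miRNA\tgene\tscore",
               sprintf("%s\t%s\t%s", targets$mirna, targets$gene,
                       num_chr(targets$score))), path)
  invisible(path)
}

## ---- ARFF ------------------------------------------------------------------

arff_quote <- function(x) {
  needs <- grepl("[^A-Za-z0-9_.-]", x) | !nzchar(x)
  x[needs] <- paste0("'", gsub("'", "\\\\'", x[needs]), "'")
  x
}

#' Write a feature table as ARFF
#'
#' WEKA-compatible dialect: the instance id is stored as a leading `string`
#' attribute, binary attributes are declared as nominal `{0,1}`, numeric
#' attributes as `numeric`, and the class is a nominal `{negative,positive}`
#' attribute placed last (`?` for unlabeled instances). Numeric values are
#' rendered with full round-trip precision and formatting is deterministic, so
#' two writes of the same table are byte-identical.
#'
#' @param table a `feature_table`.
#' @param path output path.
#' @param relation ARFF relation name.
#' @export
write_arff <- function(table, path, relation = "mirna_features") {
  header <- c(
    sprintf("@relation %s", arff_quote(relation)),
    "",
    "@attribute id string",
    sprintf("@attribute %s %s",
            arff_quote(ft_attributes(table)),
            ifelse(table$kinds == "binary", "{0,1}", "numeric")),
    "@attribute class {negative,positive}",
    "",
    "@data"
  )
  n <- nrow(table$values)
  if (n > 0) {
    cells <- apply(table$values, 1, num_chr)  # attributes x instances
    if (is.null(dim(cells))) cells <- matrix(cells, nrow = ncol(table$values))
    lab <- if (is.null(table$labels)) rep("?", n) else as.character(table$labels)
    rows <- sprintf("%s,%s,%s",
                    arff_quote(ft_ids(table)),
                    apply(cells, 2, paste, collapse = ","),
                    lab)
  } else rows <- character()
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, rows), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

arff_unquote <- function(x) {
  q <- startsWith(x, "'") & endsWith(x, "'")
  x[q] <- gsub("\\\\'", "'", substr(x[q], 2, nchar(x[q]) - 1))
  x
}

# split one ARFF data row on commas, honoring single-quoted fields
arff_split_row <- function(line) {
  out <- character()
  buf <- ""
  inq <- FALSE
  chars <- strsplit(line, "", fixed = TRUE)[[1]]
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "\\" && inq && i < length(chars)) {
      buf <- paste0(buf, chars[i + 1]); i <- i + 2L; next
    }
    if (ch == "'") { inq <- !inq; i <- i + 1L; next }
    if (ch == "," && !inq) { out <- c(out, buf); buf <- ""; i <- i + 1L; next }
    buf <- paste0(buf, ch); i <- i + 1L
  }
  c(out, buf)
}

#' Read an ARFF feature table written by [write_arff()]
#'
#' @param path ARFF file path.
#' @return A `feature_table`; the class column becomes labels (all-`?` class
#'   yields an unlabeled table).
#' @export
read_arff <- function(path) {
  if (!file.exists(path)) stop_io("ARFF file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  att_idx <- grep("^\\s*@attribute\\s", lines, ignore.case = TRUE)
  data_idx <- grep("^\\s*@data\\s*$", lines, ignore.case = TRUE)
  if (!length(data_idx)) stop_format("ARFF file has no @data section: %s", path)
  specs <- lapply(lines[att_idx], function(l) {
    m <- regmatches(l, regexec("^\\s*@attribute\\s+('(?:\\\\'|[^'])*'|\\S+)\\s+(.*)$",
                               l, ignore.case = TRUE))[[1]]
    list(name = arff_unquote(m[2]), type = trimws(m[3]))
  })
  names_ <- vapply(specs, `[[`, character(1), "name")
  types <- vapply(specs, `[[`, character(1), "type")
  if (names_[1] != "id" || names_[length(names_)] != "class") {
    stop_format("ARFF dialect requires leading 'id' and trailing 'class' attributes")
  }
  attr_names <- names_[-c(1, length(names_))]
  attr_types <- types[-c(1, length(types))]
  kinds <- ifelse(grepl("^\\{", attr_types), "binary", "numeric")
  body <- if (data_idx[1] < length(lines))
    lines[(data_idx[1] + 1):length(lines)] else character()
  body <- body[nzchar(trimws(body))]
  n <- length(body)
  values <- matrix(NA_real_, nrow = n, ncol = length(attr_names),
                   dimnames = list(NULL, attr_names))
  ids <- character(n)
  labs <- character(n)
  for (i in seq_len(n)) {
    f <- arff_split_row(body[i])
    if (length(f) != length(names_)) {
      stop_format("ARFF data row %d has %d fields, expected %d",
                  i, length(f), length(names_))
    }
    ids[i] <- f[1]
    labs[i] <- f[length(f)]
    values[i, ] <- as.numeric(f[-c(1, length(f))])
  }
  rownames(values) <- ids
  labels <- if (n && all(labs == "?")) NULL else labs
  if (!is.null(labels) && any(labels == "?")) {
    stop_format("ARFF mixes labeled and unlabeled instances")
  }
  feature_table(values, kinds, labels = labels)
}

## ---- CSV mirror ------------------------------------------------------------

#' Write a feature table as CSV
#'
#' Mirror of [write_arff()] for ecosystem interoperability: header row,
#' comma delimiter, UTF-8; columns are `id`, the attributes, then `class`
#' (empty when unlabeled). Deterministic formatting.
#'
#' @inheritParams write_arff
#' @export
write_feature_csv <- function(table, path) {
  header <- paste(c("id", ft_attributes(table), "class"), collapse = ",")
  n <- nrow(table$values)
  if (n > 0) {
    cells <- apply(table$values, 1, num_chr)
    if (is.null(dim(cells))) cells <- matrix(cells, nrow = ncol(table$values))
    lab <- if (is.null(table$labels)) rep("", n) else as.character(table$labels)
    rows <- sprintf("%s,%s,%s", ft_ids(table),
                    apply(cells, 2, paste, collapse = ","), lab)
  } else rows <- character()
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, rows), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a feature-table CSV written by [write_feature_csv()]
#'
#' CSV carries no attribute-kind declarations; columns whose values are all
#' 0/1 are classified as binary unless `kinds` overrides that inference.
#'
#' @param path CSV path.
#' @param kinds optional explicit kind vector (named or positional).
#' @return A `feature_table`.
#' @export
read_feature_csv <- function(path, kinds = NULL) {
  if (!file.exists(path)) stop_io("CSV file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  if (!("id" %in% names(df)) || !("class" %in% names(df))) {
    stop_format("feature CSV must have 'id' and 'class' columns")
  }
  attr_names <- setdiff(names(df), c("id", "class"))
  values <- matrix(NA_real_, nrow = nrow(df), ncol = length(attr_names),
                   dimnames = list(df$id, attr_names))
  for (a in attr_names) values[, a] <- as.numeric(df[[a]])
  if (is.null(kinds)) {
    kinds <- vapply(attr_names, function(a) {
      if (all(values[, a] %in% c(0, 1))) "binary" else "numeric"
    }, character(1))
  }
  labels <- if (nrow(df) && all(!nzchar(df$class))) NULL else df$class
  feature_table(values, kinds, labels = labels)
}
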