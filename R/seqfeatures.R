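## seqfeatures: sequence-based descriptors for mature miRNAs.
## The composition block is fixed at 12 numeric attributes: 4 base counts,
## 4 base frequencies, length, GC fraction, molecular weight and Watson-Crick
## hydrogen-bond capacity. Dinucleotide frequencies (16) and motif-presence
## flags are optional blocks controlled by the descriptor config.

RNA_BASES <- c("A", "C", "G", "U")
DINUCLEOTIDES <- as.vector(outer(RNA_BASES, RNA_BASES,
                                 function(a, b) paste0(a, b)))

# Placeholder heptamer motifs shipped with the package; they mark seed-like
# 7-mers of well-studied human miRNAs and are meant to be replaced by the
# user's own motif hypotheses via the config.
DEFAULT_MOTIFS <- c("AGCUUAU", "AAGUGCU", "UAAGGCA", "ACUGCAU",
                    "UUGGUCC", "AGCAGCA", "UUCAAGU", "AAAGUGC")

# average ssRNA residue masses (Da); terminal constant adds one water for the
# 5'-OH / 3'-OH convention
DEFAULT_MW_CONSTANTS <- c(A = 329.2, C = 305.2, G = 345.2, U = 306.2)
DEFAULT_MW_TERMINAL <- 18.0

check_rna <- function(seq, what = "sequence") {
  if (length(seq) != 1 || is.na(seq) || !nzchar(seq)) {
    stop_domain("empty %s", what)
  }
  if (grepl("[^ACGU]", seq)) {
    stop_domain("%s contains characters outside {A,C,G,U}: %s", what, seq)
  }
  invisible(seq)
}

#' Sequence-descriptor configuration
#'
#' @param motifs character vector of RNA motifs tested for presence (contiguous
#'   substring match); the shipped default is a set of 8 placeholder seed-region
#'   heptamers, expected to be replaced by the user's motif hypotheses.
#' @param include_dinucleotides add the 16 dinucleotide-frequency attributes.
#' @param mw_constants named residue masses in daltons for A, C, G, U.
#' @param mw_terminal terminal mass constant (daltons) added once per molecule.
#' @return A `seq_descriptor_config` list.
#' @export
seq_descriptor_config <- function(motifs = DEFAULT_MOTIFS,
                                  include_dinucleotides = TRUE,
                                  mw_constants = DEFAULT_MW_CONSTANTS,
                                  mw_terminal = DEFAULT_MW_TERMINAL) {
  motifs <- as.character(motifs)
  if (any(!nzchar(motifs)) || any(grepl("[^ACGU]", motifs))) {
    stop_config("motifs must be non-empty strings over {A,C,G,U}")
  }
  if (!all(RNA_BASES %in% names(mw_constants)) || any(mw_constants <= 0)) {
    stop_config("mw_constants must name positive masses for A, C, G, U")
  }
  structure(list(motifs = motifs,
                 include_dinucleotides = isTRUE(include_dinucleotides),
                 mw_constants = mw_constants[RNA_BASES],
                 mw_terminal = mw_terminal),
            class = "seq_descriptor_config")
}

#' Nucleotide composition of an RNA sequence
#'
#' @param seq canonical RNA string (uppercase, A/C/G/U).
#' @return Named numeric vector: counts `n_A..n_U`, frequencies `f_A..f_U`,
#'   `length`, and `gc_fraction`.
#' @export
composition <- function(seq) {
  check_rna(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  counts <- vapply(RNA_BASES, function(b) sum(chars == b), numeric(1))
  len <- length(chars)
  freqs <- counts / len
  c(stats::setNames(counts, paste0("n_", RNA_BASES)),
    stats::setNames(freqs, paste0("f_", RNA_BASES)),
    length = len,
    gc_fraction = (counts[["G"]] + counts[["C"]]) / len)
}

#' Dinucleotide frequencies of an RNA sequence
#'
#' Frequencies over the `length - 1` overlapping windows; a length-1 sequence
#' yields all zeros.
#'
#' @inheritParams composition
#' @return Named numeric vector `f_AA` .. `f_UU` (16 values).
#' @export
dinucleotide_frequencies <- function(seq) {
  check_rna(seq)
  n <- nchar(seq)
  counts <- stats::setNames(numeric(16), DINUCLEOTIDES)
  if (n >= 2) {
    wins <- substring(seq, 1:(n - 1), 2:n)
    tab <- table(wins)
    counts[names(tab)] <- as.numeric(tab)
    counts <- counts / (n - 1)
  }
  stats::setNames(counts, paste0("f_", DINUCLEOTIDES))
}

#' Molecular weight of a single-stranded RNA
#'
#' Sum of per-residue masses plus a single terminal constant; strictly
#' increasing in length and invariant under permutation of the sequence.
#'
#' @inheritParams composition
#' @param mw_constants named residue masses (Da) for A, C, G, U.
#' @param mw_terminal terminal mass constant (Da).
#' @return Molecular weight in daltons.
#' @export
molecular_weight <- function(seq, mw_constants = DEFAULT_MW_CONSTANTS,
                             mw_terminal = DEFAULT_MW_TERMINAL) {
  check_rna(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  sum(mw_constants[chars]) + mw_terminal
}

#' Watson-Crick hydrogen-bond capacity of an RNA sequence
#'
#' Counts the hydrogen bonds each base would form in a canonical pair:
#' 3 per G or C, 2 per A or U.
#'
#' @inheritParams composition
#' @return Integer bond count.
#' @export
hydrogen_bond_count <- function(seq) {
  check_rna(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  gc <- sum(chars %in% c("G", "C"))
  as.integer(3L * gc + 2L * (length(chars) - gc))
}

#' Motif presence flags
#'
#' One binary value per motif: 1 iff the motif occurs as a contiguous
#' substring of the sequence (overlaps allowed).
#'
#' @inheritParams composition
#' @param motifs character vector of RNA motifs.
#' @return Named 0/1 vector, names `motif_<string>`.
#' @export
motif_presence <- function(seq, motifs) {
  check_rna(seq)
  if (any(!nzchar(motifs)) || any(grepl("[^ACGU]", motifs))) {
    stop_config("motifs must be non-empty strings over {A,C,G,U}")
  }
  stats::setNames(as.numeric(vapply(motifs, function(m)
    grepl(m, seq, fixed = TRUE), logical(1))),
    paste0("motif_", motifs))
}

#' Build the sequence-descriptor feature table
#'
#' One row per miRNA record. Attribute order is deterministic: the 12-attribute
#' composition block (counts, frequencies, length, GC fraction, molecular
#' weight, hydrogen-bond count), then the 16 dinucleotide frequencies when
#' enabled, then one binary flag per configured motif. Total attribute count is
#' `12 + 16 * include_dinucleotides + length(motifs)`.
#'
#' @param records a `mirna_set`.
#' @param config a [seq_descriptor_config()].
#' @param labels optional class labels aligned with `records`.
#' @return A `feature_table` with the miRNA ids as instance ids.
#' @export
featurize_sequences <- function(records, config = seq_descriptor_config(),
                                labels = NULL) {
  if (!nrow(records)) stop_domain("featurize_sequences: no records")
  rows <- lapply(records$sequence, function(s) {
    comp <- composition(s)
    base <- c(comp[1:9], comp["gc_fraction"],
              mw = molecular_weight(s, config$mw_constants, config$mw_terminal),
              hbond = hydrogen_bond_count(s))
    if (config$include_dinucleotides) base <- c(base, dinucleotide_frequencies(s))
    if (length(config$motifs)) base <- c(base, motif_presence(s, config$motifs))
    base
  })
  values <- do.call(rbind, rows)
  rownames(values) <- records$id
  kinds <- c(rep("numeric", 12 + 16 * config$include_dinucleotides),
             rep("binary", length(config$motifs)))
  feature_table(values, kinds, labels = labels)
}
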