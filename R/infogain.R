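## infogain: attribute ranking by information gain against the binary class.
## Numeric attributes are discretized first with the Fayyad-Irani MDL
## criterion (recursive entropy-minimizing binary splits accepted only when
## the gain beats the MDL penalty), the same behavior WEKA's
## InfoGainAttributeEval applies through its supervised discretization step.
## Base-2 logarithms throughout; 0 log 0 is taken as 0.

entropy_bits <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

#' Shannon entropy of the class labels (bits)
#'
#' @param labels class labels (`negative`/`positive`), at least one.
#' @return Entropy in bits: 0 for pure labels, 1 for a balanced binary split.
#' @export
class_entropy <- function(labels) {
  if (!length(labels)) stop_domain("class_entropy: no labels")
  labels <- as_class_factor(labels)
  entropy_bits(table(labels))
}

# weighted conditional entropy of labels given a bin assignment
conditional_entropy <- function(bins, labels) {
  n <- length(labels)
  tab <- table(bins, labels)
  sum(apply(tab, 1, function(r) sum(r) / n * entropy_bits(r)))
}

#' Supervised MDL discretization (Fayyad-Irani)
#'
#' Recursively splits a numeric attribute at the boundary midpoint that
#' minimizes class entropy, accepting a split only when its information gain
#' exceeds the minimum-description-length bound
#' `(log2(N-1) + log2(3^k - 2) - k*H(S) + k1*H(S1) + k2*H(S2)) / N`.
#' An empty cut list means the attribute collapses to a single bin.
#'
#' @param values numeric vector.
#' @param labels class labels of the same length.
#' @return Sorted numeric vector of cutpoints (possibly empty).
#' @export
mdl_discretize <- function(values, labels) {
  if (length(values) != length(labels)) {
    stop_domain("mdl_discretize: values and labels differ in length")
  }
  labels <- as_class_factor(labels)
  ord <- order(values)
  sort(mdl_split(values[ord], labels[ord]))
}

# values sorted ascending; returns unsorted cut list
mdl_split <- function(values, labels) {
  n <- length(values)
  if (n < 2) return(numeric())
  distinct <- which(diff(values) > 0)   # split after position i
  if (!length(distinct)) return(numeric())
  base_tab <- table(labels)
  h_s <- entropy_bits(base_tab)
  k <- sum(base_tab > 0)
  best <- NULL
  best_h <- Inf
  lab_int <- as.integer(labels)
  cum_pos <- cumsum(lab_int == 2L)
  cum_neg <- cumsum(lab_int == 1L)
  for (i in distinct) {
    left <- c(cum_neg[i], cum_pos[i])
    right <- c(cum_neg[n] - cum_neg[i], cum_pos[n] - cum_pos[i])
    h <- (i / n) * entropy_bits(left) + ((n - i) / n) * entropy_bits(right)
    if (h < best_h - 1e-12) {
      best_h <- h
      best <- list(i = i, left = left, right = right)
    }
  }
  if (is.null(best)) return(numeric())
  gain <- h_s - best_h
  k1 <- sum(best$left > 0)
  k2 <- sum(best$right > 0)
  h1 <- entropy_bits(best$left)
  h2 <- entropy_bits(best$right)
  delta <- log2(3^k - 2) - (k * h_s - k1 * h1 - k2 * h2)
  if (gain <= (log2(n - 1) + delta) / n) return(numeric())
  cut <- (values[best$i] + values[best$i + 1]) / 2
  i <- best$i
  c(mdl_split(values[1:i], labels[1:i]),
    cut,
    mdl_split(values[(i + 1):n], labels[(i + 1):n]))
}

# equal-frequency fallback discretization
eqfreq_cuts <- function(values, nbins = 10) {
  qs <- unique(stats::quantile(values, probs = seq_len(nbins - 1) / nbins,
                               names = FALSE, type = 7))
  qs[qs > min(values) & qs < max(values)]
}

# bin assignment given cutpoints; out-of-range values land in boundary bins
bin_values <- function(values, cuts) {
  findInterval(values, cuts) + 1L
}

#' Rank attributes by information gain
#'
#' For each attribute, gain = `H(class) - H(class | discretized attribute)`.
#' Binary attributes use their two values as bins directly; numeric attributes
#' are discretized by [mdl_discretize()] (or an equal-frequency 10-bin scheme
#' with `discretize = "eqfreq"`). Entries are sorted by gain descending with
#' ties broken by original attribute order, so reports are deterministic.
#'
#' @param table a labeled `feature_table` with both classes present.
#' @param discretize `"mdl"` (default) or `"eqfreq"`.
#' @return An `attribute_ranking`: list with `entries` (data frame of
#'   attribute, gain), `class_entropy`, and `cutpoints` per numeric attribute.
#' @export
info_gain <- function(table, discretize = c("mdl", "eqfreq")) {
  discretize <- match.arg(discretize)
  if (is.null(table$labels)) stop_domain("info_gain requires a labeled table")
  labels <- table$labels
  if (length(unique(labels)) < 2) {
    stop_domain("info_gain requires both classes present")
  }
  h <- class_entropy(labels)
  attrs <- ft_attributes(table)
  cutpoints <- list()
  gains <- numeric(length(attrs))
  for (j in seq_along(attrs)) {
    v <- table$values[, j]
    if (table$kinds[j] == "binary") {
      bins <- v
    } else {
      cuts <- if (discretize == "mdl") mdl_discretize(v, labels)
              else eqfreq_cuts(v)
      cutpoints[[attrs[j]]] <- cuts
      bins <- bin_values(v, cuts)
    }
    gains[j] <- h - conditional_entropy(bins, labels)
  }
  gains <- pmax(gains, 0)   # clip -0 / rounding noise at the boundary
  ord <- order(-gains)      # base order() is stable: ties keep original order
  structure(list(entries = data.frame(attribute = attrs[ord],
                                      gain = gains[ord],
                                      stringsAsFactors = FALSE),
                 class_entropy = h,
                 cutpoints = cutpoints),
            class = "attribute_ranking")
}

#' @export
print.attribute_ranking <- function(x, n = 10, ...) {
  cat(sprintf("<attribute_ranking> %d attributes, class entropy %.4f bits\n",
              nrow(x$entries), x$class_entropy))
  print(utils::head(x$entries, n), row.names = FALSE)
  invisible(x)
}

#' Select top-ranked attributes
#'
#' Exactly one of `k` (keep the k best) or `min_gain` (keep attributes with
#' gain strictly above the threshold) must be given. Selection is stable:
#' within tied gains the original attribute order decides.
#'
#' @param ranking an `attribute_ranking`.
#' @param k number of attributes to keep.
#' @param min_gain gain threshold; `min_gain = 0` keeps only attributes with
#'   strictly positive gain.
#' @return Character vector of selected attribute names, in ranking order.
#' @export
select_top <- function(ranking, k = NULL, min_gain = NULL) {
  if (is.null(k) == is.null(min_gain)) {
    stop_config("select_top: give exactly one of k or min_gain")
  }
  if (!is.null(k)) {
    if (k < 1) stop_config("select_top: k must be >= 1")
    if (k > nrow(ranking$entries)) {
      warning(sprintf("select_top: k = %d exceeds attribute count %d; returning all",
                      k, nrow(ranking$entries)), call. = FALSE)
      k <- nrow(ranking$entries)
    }
    return(ranking$entries$attribute[seq_len(k)])
  }
  if (min_gain < 0) stop_config("select_top: min_gain must be >= 0")
  ranking$entries$attribute[ranking$entries$gain > min_gain]
}

#' Write an attribute ranking as TSV
#'
#' Columns: attribute, gain, comma-separated discretization cutpoints (empty
#' for binary attributes or attributes collapsing to one bin).
#'
#' @param ranking an `attribute_ranking`.
#' @param path output path.
#' @export
write_ranking_tsv <- function(ranking, path) {
  cuts <- vapply(ranking$entries$attribute, function(a) {
    cp <- ranking$cutpoints[[a]]
    if (is.null(cp) || !length(cp)) "" else paste(num_chr(cp), collapse = ",")
  }, character(1))
  writeLines(c("attribute\tgain\tcutpoints",
               sprintf("%s\t%s\t%s", ranking$entries$attribute,
                       num_chr(ranking$entries$gain), cuts)), path)
  invisible(path)
}
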