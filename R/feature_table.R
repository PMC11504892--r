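#' Feature table: instances x named attributes with optional class labels
#'
#' The pipeline's central exchange object. Rows are miRNA instances (row names
#' are the instance ids), columns are named attributes of kind `"numeric"` or
#' `"binary"`, and an optional class label (`negative`/`positive`) is attached
#' per instance. Binary attributes may only contain 0/1; attribute names and
#' instance ids must be unique.
#'
#' @param values numeric matrix with unique row names (instance ids) and unique
#'   column names (attribute names).
#' @param kinds character vector, one of `"numeric"`/`"binary"` per attribute;
#'   recycled to a single value if length 1.
#' @param labels optional vector of class labels (`"negative"`/`"positive"`),
#'   one per instance.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(values, kinds = "numeric", labels = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_domain("feature_table values must be a numeric matrix")
  }
  if (is.null(rownames(values)) && nrow(values) > 0) {
    stop_domain("feature_table requires instance ids as row names")
  }
  if (is.null(colnames(values)) && ncol(values) > 0) {
    stop_domain("feature_table requires attribute names as column names")
  }
  if (anyDuplicated(rownames(values))) {
    stop_domain("duplicate instance ids: %s",
                paste(unique(rownames(values)[duplicated(rownames(values))]),
                      collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) {
    stop_domain("duplicate attribute names: %s",
                paste(unique(colnames(values)[duplicated(colnames(values))]),
                      collapse = ", "))
  }
  if (length(kinds) == 1) kinds <- rep(kinds, ncol(values))
  if (length(kinds) != ncol(values)) {
    stop_domain("kinds length (%d) != attribute count (%d)",
                length(kinds), ncol(values))
  }
  if (!all(kinds %in% c("numeric", "binary"))) {
    stop_domain("attribute kinds must be 'numeric' or 'binary'")
  }
  names(kinds) <- colnames(values)
  for (j in which(kinds == "binary")) {
    v <- values[, j]
    if (!all(v %in% c(0, 1))) {
      stop_domain("binary attribute '%s' contains values outside {0,1}",
                  colnames(values)[j])
    }
  }
  if (!is.null(labels)) {
    labels <- as_class_factor(labels)
    if (length(labels) != nrow(values)) {
      stop_domain("labels length (%d) != instance count (%d)",
                  length(labels), nrow(values))
    }
    names(labels) <- rownames(values)
  }
  structure(list(values = values, kinds = kinds, labels = labels),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d instances x %d attributes (%d numeric, %d binary)%s\n",
              nrow(x$values), ncol(x$values),
              sum(x$kinds == "numeric"), sum(x$kinds == "binary"),
              if (is.null(x$labels)) ", unlabeled"
              else sprintf("; labels: %d negative / %d positive",
                           sum(x$labels == "negative"),
                           sum(x$labels == "positive"))))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Instance ids of a feature table
#' @param table a `feature_table`.
#' @return Character vector of instance ids.
#' @export
ft_ids <- function(table) rownames(table$values)

#' Attribute names of a feature table
#' @inheritParams ft_ids
#' @return Character vector of attribute names.
#' @export
ft_attributes <- function(table) colnames(table$values)

#' Row-subset a feature table
#'
#' @param table a `feature_table`.
#' @param idx integer or logical row index, or character instance ids.
#' @return A `feature_table` with the selected instances, labels carried along.
#' @export
ft_subset <- function(table, idx) {
  v <- table$values[idx, , drop = FALSE]
  feature_table(v, table$kinds,
                labels = if (is.null(table$labels)) NULL else
                  as.character(table$labels[idx]))
}

#' Column-wise merge of feature tables
#'
#' Concatenates the attribute blocks of several feature tables that describe
#' the same instances in the same order. Attribute names must be disjoint;
#' labels (when present on more than one table) must agree.
#'
#' @param tables list of `feature_table` objects.
#' @return A single merged `feature_table`.
#' @export
merge_tables <- function(tables) {
  if (!length(tables)) stop_domain("merge_tables: empty table list")
  stopifnot(all(vapply(tables, inherits, logical(1), "feature_table")))
  ids <- ft_ids(tables[[1]])
  for (t in tables[-1]) {
    if (!identical(ft_ids(t), ids)) {
      stop_domain("merge_tables: instance ids differ or are reordered between tables")
    }
  }
  all_names <- unlist(lapply(tables, ft_attributes))
  if (anyDuplicated(all_names)) {
    stop_domain("merge_tables: duplicate attribute name(s): %s",
                paste(unique(all_names[duplicated(all_names)]), collapse = ", "))
  }
  labels <- NULL
  for (t in tables) {
    if (!is.null(t$labels)) {
      if (!is.null(labels) && !identical(as.character(labels), as.character(t$labels))) {
        stop_domain("merge_tables: conflicting labels between tables")
      }
      labels <- t$labels
    }
  }
  feature_table(do.call(cbind, lapply(tables, `[[`, "values")),
                unlist(lapply(tables, `[[`, "kinds"), use.names = FALSE),
                labels = if (is.null(labels)) NULL else as.character(labels))
}
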