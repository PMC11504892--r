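## model: the classifiers compared in the study. The headline method is a
## discrete Bayesian-network classifier with the naive structure (class is
## the sole parent of every attribute): numeric attributes are discretized at
## fit time with the supervised MDL criterion, conditional probability tables
## are estimated with a smoothing pseudo-count, and prediction works in log
## space. Baselines: Gaussian naive Bayes (same code path, Gaussian numeric
## likelihoods), random forest / random tree (randomForest package), and a
## natively implemented Hoeffding incremental tree.

MODEL_KINDS <- c("bayesnet", "naivebayes", "hoeffding_tree",
                 "random_forest", "random_tree")

model_schema <- function(table) {
  list(attributes = ft_attributes(table), kinds = unname(table$kinds))
}

check_schema <- function(model, table) {
  if (!identical(model$schema$attributes, ft_attributes(table)) ||
      !identical(model$schema$kinds, unname(table$kinds))) {
    stop_domain("attribute schema of the table differs from the one the model was fitted on")
  }
}

check_trainable <- function(table) {
  if (is.null(table$labels)) stop_domain("training requires a labeled table")
  if (length(unique(table$labels)) < 2) {
    stop_domain("training requires both classes present")
  }
}

new_model <- function(kind, schema, fit, extra = list()) {
  structure(c(list(kind = kind, schema = schema, fit = fit), extra),
            class = c(paste0("mirdiag_", kind), "mirdiag_model"))
}

#' @export
print.mirdiag_model <- function(x, ...) {
  cat(sprintf("<mirdiag_model> kind=%s, %d attributes\n",
              x$kind, length(x$schema$attributes)))
  invisible(x)
}

## ---- bayesnet --------------------------------------------------------------

# per-attribute bin ids for discrete models: binary -> value+1, numeric ->
# findInterval over fit-time cutpoints (out-of-range values fall in the
# boundary bins by construction)
discrete_bins <- function(values, kinds, cuts) {
  bins <- matrix(1L, nrow = nrow(values), ncol = ncol(values),
                 dimnames = dimnames(values))
  for (j in seq_len(ncol(values))) {
    bins[, j] <- if (kinds[j] == "binary") as.integer(values[, j]) + 1L
                 else bin_values(values[, j], cuts[[j]])
  }
  bins
}

#' Fit the discrete Bayesian-network (naive-structure) classifier
#'
#' The class node is the sole parent of every attribute. Numeric attributes
#' are discretized with [mdl_discretize()] and the cutpoints are frozen into
#' the model; binary attributes use their two values as states. The class
#' prior and every conditional probability table are estimated with a
#' pseudo-count `alpha` (simple estimator): `P(state | class) =
#' (count + alpha) / (n_class + alpha * n_states)`.
#'
#' @param table labeled `feature_table` with both classes present.
#' @param alpha smoothing pseudo-count (default 0.5).
#' @return A `mirdiag_model` of kind `"bayesnet"`.
#' @export
fit_bayesnet <- function(table, alpha = 0.5) {
  check_trainable(table)
  if (alpha <= 0) stop_config("alpha must be > 0")
  labels <- table$labels
  kinds <- unname(table$kinds)
  cuts <- vector("list", ncol(table$values))
  for (j in seq_len(ncol(table$values))) {
    if (kinds[j] == "numeric") {
      cuts[[j]] <- mdl_discretize(table$values[, j], labels)
    }
  }
  bins <- discrete_bins(table$values, kinds, cuts)
  nbins <- ifelse(kinds == "binary", 2L,
                  vapply(cuts, length, integer(1)) + 1L)
  n_class <- table(labels)
  cpts <- lapply(seq_len(ncol(bins)), function(j) {
    tab <- table(factor(bins[, j], levels = seq_len(nbins[j])), labels)
    sweep(tab + alpha, 2, n_class + alpha * nbins[j], "/")
  })
  prior <- (as.numeric(n_class) + alpha) / (length(labels) + 2 * alpha)
  names(prior) <- CLASS_LEVELS
  new_model("bayesnet", model_schema(table),
            fit = list(alpha = alpha, cutpoints = cuts, nbins = nbins,
                       cpts = cpts, prior = prior))
}

#' Fit Gaussian naive Bayes
#'
#' Shares the Bayes-net code path but models numeric attributes with
#' class-conditional Gaussians (binary attributes keep smoothed discrete
#' tables). Standard deviations are floored at `sd_floor` to keep likelihoods
#' finite for constant attributes.
#'
#' @inheritParams fit_bayesnet
#' @param sd_floor minimum class-conditional standard deviation.
#' @return A `mirdiag_model` of kind `"naivebayes"`.
#' @export
fit_naivebayes <- function(table, alpha = 0.5, sd_floor = 1e-3) {
  check_trainable(table)
  labels <- table$labels
  kinds <- unname(table$kinds)
  n_class <- table(labels)
  params <- lapply(seq_len(ncol(table$values)), function(j) {
    v <- table$values[, j]
    if (kinds[j] == "binary") {
      tab <- table(factor(v, levels = c(0, 1)), labels)
      list(kind = "discrete",
           cpt = sweep(tab + alpha, 2, n_class + alpha * 2, "/"))
    } else {
      mu <- tapply(v, labels, mean)
      sd_ <- pmax(tapply(v, labels, stats::sd), sd_floor)
      sd_[is.na(sd_)] <- sd_floor
      list(kind = "gaussian", mu = mu, sd = sd_)
    }
  })
  prior <- (as.numeric(n_class) + alpha) / (length(labels) + 2 * alpha)
  names(prior) <- CLASS_LEVELS
  new_model("naivebayes", model_schema(table),
            fit = list(alpha = alpha, params = params, prior = prior))
}

log_sum_exp <- function(a, b) {
  m <- pmax(a, b)
  m + log(exp(a - m) + exp(b - m))
}

posterior_bayesnet <- function(model, table) {
  bins <- discrete_bins(table$values, unname(table$kinds),
                        model$fit$cutpoints)
  n <- nrow(bins)
  logp <- matrix(rep(log(model$fit$prior), each = n), nrow = n)
  for (j in seq_len(ncol(bins))) {
    cpt <- model$fit$cpts[[j]]
    logp <- logp + log(cpt[bins[, j], , drop = FALSE])
  }
  logp
}

posterior_naivebayes <- function(model, table) {
  n <- nrow(table$values)
  logp <- matrix(rep(log(model$fit$prior), each = n), nrow = n)
  for (j in seq_along(model$fit$params)) {
    p <- model$fit$params[[j]]
    v <- table$values[, j]
    if (p$kind == "discrete") {
      logp <- logp + log(p$cpt[as.integer(v) + 1L, , drop = FALSE])
    } else {
      for (ci in 1:2) {
        logp[, ci] <- logp[, ci] +
          stats::dnorm(v, p$mu[ci], p$sd[ci], log = TRUE)
      }
    }
  }
  logp
}

#' Predict with a fitted classifier
#'
#' Returns one positive-class probability per instance plus the hard label at
#' the 0.5 threshold. The table's attribute schema must match the schema the
#' model was fitted on; for discrete models, numeric values outside the
#' training range fall into the nearest boundary bin.
#'
#' @param object a `mirdiag_model`.
#' @param table a `feature_table` (labels, if any, are ignored).
#' @param ... unused.
#' @return A `prediction_result`: data frame with columns `id`,
#'   `prob_positive`, `label`.
#' @export
predict.mirdiag_model <- function(object, table, ...) {
  check_schema(object, table)
  if (!nrow(table$values)) stop_domain("predict: empty table")
  prob <- switch(object$kind,
    bayesnet = {
      lp <- posterior_bayesnet(object, table)
      exp(lp[, 2] - log_sum_exp(lp[, 1], lp[, 2]))
    },
    naivebayes = {
      lp <- posterior_naivebayes(object, table)
      exp(lp[, 2] - log_sum_exp(lp[, 1], lp[, 2]))
    },
    hoeffding_tree = predict_hoeffding(object, table),
    random_forest = ,
    random_tree = {
      df <- as.data.frame(table$values)
      colnames(df) <- object$fit$safe_names
      stats::predict(object$fit$forest, newdata = df,
                     type = "prob")[, "positive"]
    },
    stop_config("unknown model kind '%s'", object$kind))
  prediction_result(ft_ids(table), unname(prob))
}

prediction_result <- function(ids, prob) {
  if (any(!is.finite(prob)) || any(prob < 0) || any(prob > 1)) {
    stop_domain("predicted probabilities outside [0,1]")
  }
  out <- data.frame(id = ids, prob_positive = prob,
                    label = ifelse(prob > 0.5, "positive", "negative"),
                    stringsAsFactors = FALSE)
  class(out) <- c("prediction_result", "data.frame")
  out
}

## ---- baselines -------------------------------------------------------------

#' Fit any of the supported classifiers behind a common contract
#'
#' Kinds: `bayesnet`, `naivebayes`, `hoeffding_tree`, `random_forest`
#' (500 trees), `random_tree` (a single randomized tree). Fits are
#' deterministic given `seed`.
#'
#' @param kind classifier kind.
#' @param table labeled `feature_table`.
#' @param seed integer seed for the stochastic learners.
#' @param ... passed to the kind-specific fitter.
#' @return A `mirdiag_model`.
#' @export
fit_classifier <- function(kind, table, seed = 1, ...) {
  if (!kind %in% MODEL_KINDS) {
    stop_config("unknown classifier kind '%s' (supported: %s)",
                kind, paste(MODEL_KINDS, collapse = ", "))
  }
  switch(kind,
    bayesnet = fit_bayesnet(table, ...),
    naivebayes = fit_naivebayes(table, ...),
    hoeffding_tree = fit_hoeffding_tree(table, ...),
    random_forest = fit_random_forest(table, seed, ntree = 500, ...),
    random_tree = fit_random_forest(table, seed, ntree = 1,
                                    kind = "random_tree", ...))
}

fit_random_forest <- function(table, seed, ntree, kind = "random_forest") {
  check_trainable(table)
  df <- as.data.frame(table$values)
  safe <- make.names(colnames(df), unique = TRUE)
  colnames(df) <- safe
  forest <- withr::with_seed(seed,
    randomForest::randomForest(x = df, y = table$labels, ntree = ntree))
  new_model(kind, model_schema(table),
            fit = list(forest = forest, safe_names = safe, seed = seed))
}

## ---- Hoeffding incremental tree -------------------------------------------

## A minimal very-fast-decision-tree learner: attributes are discretized to
## the same fit-time bins the Bayes net uses, instances are processed in
## table order, leaves accumulate class and attribute-state counts, and a
## leaf splits (multiway on attribute states) once the information-gain lead
## of the best attribute over the runner-up exceeds the Hoeffding bound
## eps = sqrt(ln(1/delta) / (2 n)) or falls under the tie threshold tau.

#' Fit a Hoeffding incremental decision tree
#'
#' @inheritParams fit_bayesnet
#' @param grace re-evaluate split candidates every `grace` instances at a leaf.
#' @param delta Hoeffding bound confidence parameter.
#' @param tau tie-break threshold on the gain lead.
#' @param max_depth maximum tree depth.
#' @return A `mirdiag_model` of kind `"hoeffding_tree"`.
#' @export
fit_hoeffding_tree <- function(table, grace = 20, delta = 1e-7, tau = 0.05,
                               max_depth = 8) {
  check_trainable(table)
  labels <- as.integer(table$labels)   # 1 = negative, 2 = positive
  kinds <- unname(table$kinds)
  cuts <- vector("list", ncol(table$values))
  for (j in seq_len(ncol(table$values))) {
    if (kinds[j] == "numeric") {
      cuts[[j]] <- mdl_discretize(table$values[, j], table$labels)
    }
  }
  bins <- discrete_bins(table$values, kinds, cuts)
  nbins <- ifelse(kinds == "binary", 2L,
                  vapply(cuts, length, integer(1)) + 1L)
  p <- ncol(bins)

  new_leaf <- function(depth) {
    list(leaf = TRUE, depth = depth, n = 0L, class_counts = c(0L, 0L),
         att = lapply(seq_len(p), function(j) matrix(0L, nbins[j], 2)),
         split_attr = NULL, children = list())
  }
  tree <- list(root = new_leaf(1L))

  leaf_gains <- function(node) {
    h <- entropy_bits(node$class_counts)
    vapply(seq_len(p), function(j) {
      tab <- node$att[[j]]
      h - sum(vapply(seq_len(nrow(tab)), function(b) {
        sum(tab[b, ]) / node$n * entropy_bits(tab[b, ])
      }, numeric(1)))
    }, numeric(1))
  }

  insert <- function(node, x, y) {
    if (!node$leaf) {
      b <- x[node$split_attr]
      node$children[[b]] <- insert(node$children[[b]], x, y)
      return(node)
    }
    node$n <- node$n + 1L
    node$class_counts[y] <- node$class_counts[y] + 1L
    for (j in seq_len(p)) node$att[[j]][x[j], y] <- node$att[[j]][x[j], y] + 1L
    if (node$n %% grace == 0 && all(node$class_counts > 0) &&
        node$depth < max_depth) {
      g <- sort(leaf_gains(node), decreasing = TRUE)
      eps <- sqrt(log(1 / delta) / (2 * node$n))
      if (length(g) >= 1 && g[1] > 0 &&
          (length(g) == 1 || g[1] - g[2] > eps || eps < tau)) {
        gains <- leaf_gains(node)
        j <- which.max(gains)   # first max: deterministic tie-break
        node$leaf <- FALSE
        node$split_attr <- j
        # children start empty: their class and attribute statistics must
        # accumulate together so that naive-Bayes leaf scoring stays
        # consistent; until a child has seen data, prediction falls back to
        # the splitting node's frozen statistics
        node$children <- lapply(seq_len(nbins[j]), function(b)
          new_leaf(node$depth + 1L))
      }
    }
    node
  }

  for (i in seq_len(nrow(bins))) {
    tree$root <- insert(tree$root, bins[i, ], labels[i])
  }
  new_model("hoeffding_tree", model_schema(table),
            fit = list(tree = tree, cutpoints = cuts, nbins = nbins,
                       grace = grace, delta = delta, tau = tau))
}

predict_hoeffding <- function(model, table) {
  bins <- discrete_bins(table$values, unname(table$kinds),
                        model$fit$cutpoints)
  nbins <- model$fit$nbins
  # naive-Bayes leaves: score with the leaf's accumulated sufficient
  # statistics instead of a bare majority vote, which keeps the learner
  # informative on sample sizes too small for the Hoeffding bound to split
  leaf_score <- function(node, x) {
    logp <- log(node$class_counts + 1)   # Laplace class prior at the leaf
    for (j in seq_along(x)) {
      cnt <- node$att[[j]][x[j], ]
      logp <- logp + log((cnt + 0.5) / (node$class_counts + 0.5 * nbins[j]))
    }
    exp(logp[2] - log_sum_exp(logp[1], logp[2]))
  }
  route <- function(node, x) {
    while (!node$leaf) {
      nxt <- node$children[[x[node$split_attr]]]
      if (is.null(nxt) || nxt$n == 0) break
      node <- nxt
    }
    if (sum(node$class_counts) == 0) return(0.5)
    leaf_score(node, x)
  }
  vapply(seq_len(nrow(bins)), function(i)
    route(model$fit$tree$root, bins[i, ]), numeric(1))
}

## ---- serialization ---------------------------------------------------------

#' Write a fitted model as a versioned JSON artifact
#'
#' Bayes models serialize their schema and parameters natively; tree models
#' embed their fitted object as a base64 payload inside the same JSON
#' envelope. The artifact records the model kind, format version, and seed
#' where applicable.
#'
#' @param model a `mirdiag_model`.
#' @param path output path.
#' @export
write_model_json <- function(model, path) {
  env <- list(format = "mirdiag-model", version = 1L, kind = model$kind,
              schema = model$schema)
  if (model$kind == "bayesnet") {
    env$fit <- list(alpha = model$fit$alpha,
                    cutpoints = lapply(model$fit$cutpoints, function(x)
                      if (is.null(x)) numeric() else x),
                    nbins = model$fit$nbins,
                    prior = as.list(model$fit$prior),
                    cpts = lapply(model$fit$cpts, function(m) {
                      m <- unclass(m)
                      list(negative = unname(m[, 1]), positive = unname(m[, 2]))
                    }))
  } else if (model$kind == "naivebayes") {
    env$fit <- list(alpha = model$fit$alpha,
                    prior = as.list(model$fit$prior),
                    params = lapply(model$fit$params, function(p) {
                      if (p$kind == "discrete") {
                        m <- unclass(p$cpt)
                        list(kind = "discrete",
                             negative = unname(m[, 1]), positive = unname(m[, 2]))
                      } else {
                        list(kind = "gaussian", mu = as.list(p$mu),
                             sd = as.list(p$sd))
                      }
                    }))
  } else {
    env$payload <- jsonlite::base64_enc(serialize(model, NULL))
  }
  jsonlite::write_json(env, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model artifact written by [write_model_json()]
#'
#' @param path JSON artifact path.
#' @return A `mirdiag_model`.
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) stop_io("model file not found: %s", path)
  env <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  if (!identical(env$format, "mirdiag-model")) {
    stop_format("not a mirdiag model artifact: %s", path)
  }
  if (!is.null(env$payload)) {
    return(unserialize(jsonlite::base64_dec(env$payload)))
  }
  schema <- list(attributes = env$schema$attributes, kinds = env$schema$kinds)
  if (env$kind == "bayesnet") {
    cpts <- lapply(env$fit$cpts, function(e)
      cbind(negative = as.numeric(unlist(e$negative)),
            positive = as.numeric(unlist(e$positive))))
    cuts <- lapply(seq_along(schema$attributes), function(j) {
      if (schema$kinds[j] == "binary") NULL
      else as.numeric(unlist(env$fit$cutpoints[[j]]))
    })
    new_model("bayesnet", schema,
              fit = list(alpha = env$fit$alpha, cutpoints = cuts,
                         nbins = as.integer(env$fit$nbins), cpts = cpts,
                         prior = unlist(env$fit$prior)[CLASS_LEVELS]))
  } else if (env$kind == "naivebayes") {
    params <- lapply(env$fit$params, function(p) {
      if (identical(p$kind, "discrete")) {
        list(kind = "discrete",
             cpt = cbind(negative = as.numeric(unlist(p$negative)),
                         positive = as.numeric(unlist(p$positive))))
      } else {
        list(kind = "gaussian",
             mu = unlist(p$mu)[CLASS_LEVELS], sd = unlist(p$sd)[CLASS_LEVELS])
      }
    })
    new_model("naivebayes", schema,
              fit = list(alpha = env$fit$alpha, params = params,
                         prior = unlist(env$fit$prior)[CLASS_LEVELS]))
  } else {
    stop_format("model kind '%s' requires an embedded payload", env$kind)
  }
}
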