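test_that("bayesnet CPTs match Laplace-smoothing hand arithmetic", {
  tab <- toy_table(n_per_class = 10)   # 'copy' equals the class indicator
  model <- fit_bayesnet(tab, alpha = 0.5)
  j <- which(ft_attributes(tab) == "copy")
  cpt <- model$fit$cpts[[j]]
  # P(copy = 1 | positive) = (10 + 0.5) / (10 + 0.5 * 2) = 10.5 / 11
  expect_equal(unname(cpt[2, "positive"]), 10.5 / 11)
  expect_equal(unname(cpt[1, "positive"]), 0.5 / 11)
  expect_equal(unname(cpt[2, "negative"]), 0.5 / 11)
  # every CPT column (distribution over states given the class) sums to 1
  for (m in model$fit$cpts) expect_equal(unname(colSums(m)), c(1, 1))
  # smoothed prior on balanced 20 instances
  expect_equal(unname(model$fit$prior), rep(10.5 / 21, 2))
})

test_that("posteriors match explicit Bayes-rule evaluation from the CPTs", {
  tab <- toy_table(n_per_class = 10)
  model <- fit_bayesnet(tab, alpha = 0.5)
  pred <- predict(model, tab)
  # hand Bayes rule using only the 'copy' attribute and near-uniform others:
  # the copy=1 instance must be classified positive with high probability
  expect_true(all(pred$prob_positive[tab$labels == "positive"] > 0.9))
  expect_true(all(pred$prob_positive[tab$labels == "negative"] < 0.1))

  # explicit computation for a single-attribute model
  v <- cbind(copy = as.numeric(rep(c(0, 1), each = 10)))
  rownames(v) <- sprintf("i%d", 1:20)
  one <- feature_table(v, "binary",
                       labels = rep(c("negative", "positive"), each = 10))
  m1 <- fit_bayesnet(one, alpha = 0.5)
  p1 <- predict(m1, one)
  lik_pos <- 10.5 / 11; lik_neg <- 0.5 / 11
  want <- (0.5 * lik_pos) / (0.5 * lik_pos + 0.5 * lik_neg)
  expect_equal(p1$prob_positive[11], want, tolerance = 1e-12)
  # probabilities of the two classes sum to 1 by construction
  expect_true(all(p1$prob_positive >= 0 & p1$prob_positive <= 1))
})

test_that("alpha -> Inf drives posteriors to the class prior ratio", {
  tab <- toy_table(n_per_class = 10)
  model <- fit_bayesnet(tab, alpha = 1e9)
  pred <- predict(model, tab)
  expect_true(all(abs(pred$prob_positive - 0.5) < 1e-6))
})

test_that("empty attribute set yields the class prior and fits are deterministic", {
  v <- matrix(numeric(0), nrow = 12, ncol = 0,
              dimnames = list(sprintf("i%d", 1:12), NULL))
  tab <- feature_table(v, character(0),
                       labels = rep(c("negative", "positive"), c(4, 8)))
  model <- fit_bayesnet(tab, alpha = 0.5)
  pred <- predict(model, tab)
  expect_equal(pred$prob_positive, rep(8.5 / 13, 12), tolerance = 1e-12)

  tab2 <- toy_table()
  expect_identical(fit_bayesnet(tab2)$fit, fit_bayesnet(tab2)$fit)
})

test_that("training rejects single-class tables and schema mismatches", {
  v <- cbind(a = rep(c(0, 1), 5)); rownames(v) <- sprintf("i%d", 1:10)
  expect_error(fit_bayesnet(feature_table(v, "binary",
                                          labels = rep("positive", 10))),
               class = "mirdiag_domain_error")
  tab <- toy_table()
  model <- fit_bayesnet(tab)
  other <- feature_table(v, "binary")
  expect_error(predict(model, other), class = "mirdiag_domain_error")
})

test_that("bayesnet is invariant to uniform duplication of the training set", {
  tab <- toy_table(n_per_class = 8, seed = 1)
  dup_values <- rbind(tab$values, tab$values)
  rownames(dup_values) <- c(rownames(tab$values),
                            paste0(rownames(tab$values), "_dup"))
  dup <- feature_table(dup_values, unname(tab$kinds),
                       labels = rep(as.character(tab$labels), 2))
  # sufficient statistics double; in the vanishing-smoothing limit the
  # estimated distributions (hence posteriors) are identical
  expect_equal(predict(fit_bayesnet(tab, 1e-9), tab)$prob_positive,
               predict(fit_bayesnet(dup, 1e-9), tab)$prob_positive,
               tolerance = 1e-6)
  # with finite smoothing the decision is unchanged even if the smoothed
  # probabilities shift slightly
  expect_identical(predict(fit_bayesnet(tab, 0.5), tab)$label,
                   predict(fit_bayesnet(dup, 0.5), tab)$label)
})

test_that("log-space prediction survives very wide tables", {
  withr::local_seed(30)
  n <- 40; p <- 10000
  v <- matrix(rbinom(n * p, 1, 0.5), n, p,
              dimnames = list(sprintf("i%d", 1:n), sprintf("a%d", 1:p)))
  labels <- rep(c("negative", "positive"), each = n / 2)
  v[, 1] <- as.numeric(labels == "positive")
  tab <- feature_table(v, "binary", labels = labels)
  model <- fit_bayesnet(tab)
  pred <- predict(model, tab)
  expect_true(all(is.finite(pred$prob_positive)))
  expect_true(all(pred$prob_positive >= 0 & pred$prob_positive <= 1))
})

test_that("gaussian naive Bayes separates an obvious numeric signal", {
  withr::local_seed(31)
  v <- cbind(x = c(rnorm(20, 0, 0.5), rnorm(20, 5, 0.5)))
  rownames(v) <- sprintf("i%d", 1:40)
  tab <- feature_table(v, "numeric",
                       labels = rep(c("negative", "positive"), each = 20))
  model <- fit_naivebayes(tab)
  pred <- predict(model, tab)
  expect_equal(pred$label, as.character(tab$labels))
})

test_that("baselines are deterministic given a seed and learn separable toys", {
  tab <- toy_table(n_per_class = 10)
  for (kind in c("naivebayes", "hoeffding_tree", "random_forest",
                 "random_tree")) {
    m1 <- fit_classifier(kind, tab, seed = 99)
    m2 <- fit_classifier(kind, tab, seed = 99)
    expect_identical(predict(m1, tab)$prob_positive,
                     predict(m2, tab)$prob_positive)
  }
  # naive Bayes on the class-copy toy: training accuracy 1.0
  nb <- fit_classifier("naivebayes", tab, seed = 1)
  expect_equal(predict(nb, tab)$label, as.character(tab$labels))
  expect_error(fit_classifier("deep_net", tab), class = "mirdiag_config_error")
})

test_that("tree learners exceed 0.8 holdout accuracy on strong synthetic signal", {
  hits <- vapply(1:20, function(s) {
    d <- synth_generate(synth_config(n_pos = 100, n_neg = 100, seed = s))
    tab <- synth_feature_table(d)
    train <- ft_subset(tab, seq(1, 200, by = 2))
    test <- ft_subset(tab, seq(2, 200, by = 2))
    m <- fit_classifier("random_tree", train, seed = s)
    mean(predict(m, test)$label == as.character(test$labels))
  }, numeric(1))
  expect_gt(mean(hits > 0.8), 0.9)
})

test_that("model JSON artifacts round-trip fitted parameters and predictions", {
  tab <- toy_table()
  for (kind in c("bayesnet", "naivebayes", "random_forest")) {
    model <- fit_classifier(kind, tab, seed = 3)
    tf <- withr::local_tempfile(fileext = ".json")
    write_model_json(model, tf)
    expect_true(jsonlite::validate(paste(readLines(tf), collapse = "")))
    back <- read_model_json(tf)
    expect_equal(predict(back, tab)$prob_positive,
                 predict(model, tab)$prob_positive, tolerance = 1e-12)
  }
})
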