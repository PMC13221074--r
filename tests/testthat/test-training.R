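test_that("stratified holdout preserves class proportions and is seeded", {
  labs <- setNames(c(rep(1L, 10), rep(0L, 40)),
                   sprintf("g%02d", 1:50))
  sp <- stratified_holdout(labs, 0.8, seed = 3)
  expect_equal(sum(labs[sp$train] == 1), 8)
  expect_equal(sum(labs[sp$train] == 0), 32)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), names(labs))
  expect_identical(sp, stratified_holdout(labs, 0.8, seed = 3))
  expect_false(identical(sp, stratified_holdout(labs, 0.8, seed = 4)))
  expect_error(stratified_holdout(setNames(c(1L, 0L, 0L), c("a", "b", "c")),
                                  0.8), "fewer than 2")
})

test_that("k-fold assignment is stratified, exhaustive, and near-balanced", {
  labs <- setNames(c(rep(1L, 10), rep(0L, 40)), sprintf("g%02d", 1:50))
  ids <- names(labs)
  fold <- kfold_assign(ids, labs, k = 5, seed = 1)
  expect_setequal(names(fold), ids)
  expect_true(all(table(fold) == 10))
  for (f in 1:5)
    expect_equal(sum(labs[names(fold)[fold == f]] == 1), 2)
  expect_warning(kfold_assign(c(ids[1:3], ids[11:20]), labs, k = 5),
                 "fewer members")
})

test_that("two-hop subgraph extraction matches the stated contracts", {
  edges <- data.frame(gene_a = c("a", "b", "c"),
                      gene_b = c("b", "c", "d"), weight = c(1, 2, 3))
  g <- structure(list(node_ids = c("a", "b", "c", "d", "e"),
                      features = matrix(0, 5, 2), edges = edges,
                      labels = rep(NA_integer_, 5),
                      mask = rep("none", 5)), class = "gene_graph")
  # path a-b-c-d, center a: two hops reach {a, b, c}
  sub <- sample_subgraph(g, "a")
  expect_setequal(sub$node_ids, c("a", "b", "c"))
  expect_identical(sub$centers, "a")
  expect_false("d" %in% sub$node_ids)
  # isolated center
  sub_e <- sample_subgraph(g, "e")
  expect_identical(sub_e$node_ids, "e")
  expect_equal(nrow(sub_e$edges), 0L)
  # center b: whole path within two hops, weights preserved
  sub_b <- sample_subgraph(g, "b")
  expect_setequal(sub_b$node_ids, c("a", "b", "c", "d"))
  expect_equal(sort(sub_b$edges$weight), c(1, 2, 3))
})

test_that("Youden threshold maximizes J with the documented tie-breaking", {
  thr <- youden_threshold(c(0.2, 0.3, 0.7, 0.8), c(0, 0, 1, 1))
  expect_equal(as.numeric(thr), 0.7)
  expect_equal(attr(thr, "youden"), 1.0)
  # all scores identical: J = 0 at that score
  thr2 <- youden_threshold(rep(0.4, 6), c(0, 1, 0, 1, 0, 1))
  expect_equal(as.numeric(thr2), 0.4)
  expect_equal(attr(thr2, "youden"), 0)
  expect_error(youden_threshold(c(0.1, 0.9), c(1, 1)), "both classes")
  # oracle equivalence on random instances (with ties in scores)
  for (s in 1:40) {
    set.seed(s)
    n <- sample(5:40, 1)
    sc <- round(runif(n), 2)
    lb <- rbinom(n, 1, 0.4)
    if (length(unique(lb)) < 2) next
    expect_equal(as.numeric(youden_threshold(sc, lb)), bf_youden(sc, lb))
  }
})

test_that("ranking metrics behave at the extremes and F1 uses the >= rule", {
  sc <- c(0.1, 0.2, 0.8, 0.9); lb <- c(0, 0, 1, 1)
  ev <- evaluate_scores(sc, lb, threshold = 0.5)
  expect_equal(ev$auroc, 1.0)
  expect_equal(ev$auprc, 1.0)
  expect_equal(ev$f1, 1.0)
  ev_rev <- evaluate_scores(sc, rev(lb), threshold = 0.5)
  expect_equal(ev_rev$auroc, 0.0)
  # probability exactly at the threshold is called high-risk
  cls <- classify_genes(setNames(c(0.9, 0.5, 0.1), c("a", "b", "c")), 0.5)
  expect_setequal(cls$hrg, c("a", "b"))
  expect_identical(cls$lrg, "c")
  expect_equal(length(cls$hrg) + length(cls$lrg), 3L)
})

test_that("the random AUPRC baseline is the positive prevalence", {
  expect_equal(random_baseline_auprc(24, 826), 24 / 850)
  expect_equal(round(random_baseline_auprc(24, 826), 4), 0.0282)
  expect_equal(random_baseline_auprc(7, 7), 0.5)
  expect_equal(random_baseline_auprc(7, 0), 1.0)
  expect_error(random_baseline_auprc(0, 10), "at least 1")
})

test_that("early stopping halts after `patience` stale epochs", {
  g <- toy_graph(seed = 6)
  # learning rate ~0 freezes the validation metric by construction
  fit <- protogt(g, model = small_model_cfg(),
                 train = pgt_train_config(max_epochs = 50, patience = 5,
                                          learning_rate = 1e-30, seed = 6))
  expect_lte(nrow(fit$history), 6L)
  expect_identical(fit$best_epoch, 1L)
})

test_that("training is reproducible and ignores test-mask labels entirely", {
  g <- toy_graph(seed = 8)
  cfg <- small_model_cfg()
  tcfg <- fast_train_cfg(seed = 8, epochs = 6)
  f1 <- protogt(g, model = cfg, train = tcfg)
  f2 <- protogt(g, model = cfg, train = tcfg)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$threshold, f2$threshold)

  # flipping the labels of test-mask nodes must not touch the fit
  g_flip <- g
  ti <- which(g_flip$mask == "test" & !is.na(g_flip$labels))
  g_flip$labels[ti] <- 1L - g_flip$labels[ti]
  f3 <- protogt(g_flip, model = cfg, train = tcfg)
  expect_identical(f1$params, f3$params)
  expect_identical(f1$history, f3$history)
})

test_that("ablation switches run the same pipeline", {
  g <- toy_graph(seed = 9)
  f_noproto <- protogt(g, model = small_model_cfg(),
                       loss = pgt_loss_config(prototype_loss = FALSE),
                       train = fast_train_cfg(seed = 9, epochs = 3))
  f_noedge <- protogt(g, model = small_model_cfg(),
                      train = fast_train_cfg(seed = 9, epochs = 3),
                      no_edges = TRUE)
  expect_s3_class(f_noproto, "protogt")
  expect_s3_class(f_noedge, "protogt")
  expect_true(all(is.finite(predict(f_noedge)$probability)))
})

test_that("cross-validation selects the best fold and reports per-fold metrics", {
  g <- simulate_gene_graph(n_genes = 120, n_features = 8,
                           class_separation = 2, pos_fraction = 0.25,
                           seed = 10, edge_density = 0.05)
  sp <- stratified_holdout(g$labels, 0.8, seed = 10)
  g <- set_mask(g, train = sp$train, test = sp$test)
  cv <- protogt_cv(g, k = 3, model = small_model_cfg(),
                   train = fast_train_cfg(seed = 10, epochs = 8), seed = 10)
  expect_equal(nrow(cv$folds), 3L)
  expect_identical(cv$best_fold, which.max(cv$folds$val_auprc))
  expect_s3_class(cv$test_eval, "pgt_eval")
  expect_true(cv$test_eval$auroc >= 0 && cv$test_eval$auroc <= 1)
})
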