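test_that("a perfectly separating feature is selected first with accuracy 1", {
  tab <- make_toy_table(12, sep = 6, noise_feats = 20, noise_sd = 0.3,
                        seed = 3)
  # binary target region: C3_m2 separates it perfectly
  tr <- tab[tab$window_index <= 8, ]
  va <- tab[tab$window_index > 8, ]
  sel <- greedy_forward_selection(tr, va, target = "region",
                                  learner = learner_config(50), seed = 2)
  expect_identical(sel$selected[1], "C3_m2")
  expect_equal(sel$accuracy_curve[1], 1.0)
  expect_identical(sel$stopped_because, "tol")
})

test_that("selection on pure noise stays at chance for 8 balanced classes", {
  tr <- make_noise_table(100, n_feats = 10, seed = 5)     # 800 train rows
  va <- make_noise_table(100, n_feats = 10, seed = 6)     # 800 val rows
  sel <- greedy_forward_selection(tr, va, target = "label",
                                  learner = learner_config(50),
                                  max_k = 5, seed = 4)
  n <- nrow(va)
  ci <- qbinom(c(0.005, 0.995), n, 1 / 8) / n
  final <- sel$accuracy_curve[length(sel$accuracy_curve)]
  expect_gte(final, ci[1])
  expect_lte(final, ci[2])
  expect_true(all(sel$accuracy_curve >= 0 & sel$accuracy_curve <= 1))
})

test_that("max_k caps the selection and over-large max_k is clamped", {
  tab <- make_toy_table(8, noise_feats = 2, seed = 9)
  tr <- tab[tab$window_index <= 5, ]; va <- tab[tab$window_index > 5, ]
  sel <- greedy_forward_selection(tr, va, target = "label", max_k = 3,
                                  tol = -1, seed = 1)
  expect_lte(length(sel$selected), 3)
  expect_equal(length(sel$accuracy_curve), length(sel$selected))
  expect_warning(
    greedy_forward_selection(tr, va, target = "region", max_k = 99, seed = 1),
    "clamped")
})

test_that("selection is deterministic and its reported accuracy reproduces", {
  tab <- make_toy_table(10, sep = 2, noise_feats = 5, noise_sd = 1.2, seed = 13)
  tr <- tab[tab$window_index <= 7, ]; va <- tab[tab$window_index > 7, ]
  s1 <- greedy_forward_selection(tr, va, target = "label", max_k = 8, seed = 5)
  s2 <- greedy_forward_selection(tr, va, target = "label", max_k = 8, seed = 5)
  expect_identical(s1$selected, s2$selected)
  expect_identical(s1$accuracy_curve, s2$accuracy_curve)
  # re-evaluate the returned configuration from scratch: exact match
  m <- fit_forest(tr[, s1$selected, drop = FALSE], tr$label,
                  learner_config(100), seed = 5)
  expect_equal(mean(predict_forest(m, va) == va$label),
               s1$accuracy_curve[length(s1$accuracy_curve)])
})

test_that("grid search evaluates the lattice and prefers the winning setting", {
  tab <- make_toy_table(10, sep = 5, seed = 21)
  tr <- tab[tab$window_index <= 7, ]; va <- tab[tab$window_index > 7, ]
  single <- data.frame(n_trees = 70L, max_depth = NA, mtry_rule = "sqrt",
                       stringsAsFactors = FALSE)
  gs <- grid_search(tr, va, target = "label", grid = single, seed = 1)
  expect_equal(gs$best$n_trees, 70L)
  expect_equal(nrow(gs$results), 1)
  expect_error(grid_search(tr, va, grid = single[0, ]), "empty")

  # XOR-style task: depth-1 stumps cannot represent it, deeper trees can
  set.seed(33)
  n <- 240
  a <- rbinom(n, 1, 0.5); b <- rbinom(n, 1, 0.5)
  xo <- data.frame(subject_id = "S01", recording_id = "R1",
                   task_index = 1L, window_index = seq_len(n),
                   region = "hand", side = "left", mode = "real",
                   label = ifelse(xor(a, b), "on", "off"),
                   X1_m2 = a + rnorm(n, 0, 0.05),
                   X2_m3 = b + rnorm(n, 0, 0.05),
                   stringsAsFactors = FALSE)
  class(xo) <- c("feature_table", "data.frame")
  trx <- xo[1:160, ]; vax <- xo[161:240, ]
  grid <- data.frame(n_trees = 100L, max_depth = c(1, NA),
                     mtry_rule = "sqrt", stringsAsFactors = FALSE)
  gs2 <- grid_search(trx, vax, target = "label", grid = grid, seed = 2)
  expect_true(is.na(gs2$best$max_depth))
  expect_gt(max(gs2$results$val_accuracy), 0.95)
  expect_lt(min(gs2$results$val_accuracy), 0.9)
  # determinism of the search
  gs3 <- grid_search(trx, vax, target = "label", grid = grid, seed = 2)
  expect_identical(gs2$best, gs3$best)
})

test_that("selection reports mirror the per-machine moments/channels layout", {
  tab <- make_toy_table(10, sep = 5, noise_feats = 2, seed = 8)
  tr <- tab[tab$window_index <= 6, ]
  va <- tab[tab$window_index %in% 7:8, ]
  model <- train_cascade(tr, va, grid = NULL, seed = 1)
  rep <- selection_report(model)
  expect_identical(rep$machine, c("A", "B0", "B1", "C0", "C1", "C2", "C3"))
  expect_identical(names(rep), c("machine", "moments", "channels"))
  expect_match(rep$moments[rep$machine == "A"], "2")
  expect_match(rep$channels[rep$machine == "A"], "C3")
  f <- withr::local_tempfile(fileext = ".csv")
  selection_report(model, f)
  expect_identical(names(utils::read.csv(f)),
                   c("machine", "moments", "channels"))
})
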