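test_that("Framework 1 splits 60/20/20 stratified within one row per class", {
  tab <- make_toy_table(100, seed = 1)        # 800 balanced rows
  plan <- split_framework1(tab, seed = 5)
  expect_length(plan$train_idx, 480)
  expect_length(plan$val_idx, 160)
  expect_length(plan$test_idx, 160)
  for (part in list(split_train(plan), split_val(plan), split_test(plan)))
    expect_true(all(abs(table(part$label) - nrow(part) / 8) <= 1))
  # disjoint and exhaustive
  all_idx <- c(plan$train_idx, plan$val_idx, plan$test_idx)
  expect_identical(sort(all_idx), seq_len(800))
  # deterministic under the seed
  plan2 <- split_framework1(tab, seed = 5)
  expect_identical(plan$train_idx, plan2$train_idx)
  expect_error(split_framework1(make_toy_table(2), seed = 1), "only 2 rows")
  # odd per-class counts stay within one row of the exact fractions
  odd <- make_toy_table(19, seed = 2)
  p3 <- split_framework1(odd, seed = 3)
  expect_true(abs(length(p3$train_idx) - 0.6 * 152) <= 8)
  expect_true(all(table(split_train(p3)$label) %in% c(11, 12)))
})

test_that("Framework 2 trains on one session and tests on the other (40/10/50)", {
  r1 <- make_toy_table(100, seed = 1, recording_id = "R1")
  r2 <- make_toy_table(100, seed = 2, recording_id = "R2")
  plan <- split_framework2(r1, r2, seed = 7)
  expect_length(plan$train_idx, 640)
  expect_length(plan$val_idx, 160)
  expect_length(plan$test_idx, 800)
  # test rows are exactly the second recording
  expect_true(all(split_test(plan)$recording_id == "R2"))
  expect_true(all(split_train(plan)$recording_id == "R1"))
  expect_true(all(split_val(plan)$recording_id == "R1"))
  other <- make_toy_table(10, seed = 3, subject_id = "S02", recording_id = "R2")
  expect_error(split_framework2(r1, other), "same subject")
  expect_error(split_framework2(r1, r1), "distinct recordings")
})

test_that("Framework 3 trains on two subjects and tests on all others (~18/4/78)", {
  tabs <- lapply(1:9, function(i)
    make_toy_table(100, seed = i, subject_id = sprintf("S%02d", i)))
  names(tabs) <- sprintf("S%02d", 1:9)
  plan <- split_framework3(tabs, "S03", "S07", seed = 2)
  n <- 9 * 800
  expect_equal(length(plan$test_idx), 5600)
  expect_lt(abs(length(plan$train_idx) / n - 0.18), 0.005)
  expect_lt(abs(length(plan$val_idx) / n - 0.04), 0.005)
  expect_equal(length(plan$test_idx) / n, 7 / 9, tolerance = 0.001)
  expect_identical(sort(unique(split_test(plan)$subject_id)),
                   sort(setdiff(names(tabs), c("S03", "S07"))))
  expect_length(intersect(unique(split_train(plan)$subject_id),
                          unique(split_test(plan)$subject_id)), 0)
  expect_error(split_framework3(tabs, "S03", "S03"), "differ")
  expect_error(split_framework3(tabs, "S03", "S99"), "unknown")
  expect_error(split_framework3(tabs[1:2], "S01", "S02"), "at least 3")
})

test_that("confusion matrices count true-by-predicted in protocol order", {
  cls <- protocol_classes()
  truths <- rep(cls, each = 3)
  cm <- confusion_matrix(truths, truths)
  expect_equal(unname(diag(cm)), rep(3, 8))
  expect_equal(sum(cm), 24)
  expect_identical(rownames(cm), cls)
  cm2 <- confusion_matrix(truths, rep(cls[2], 24))
  expect_equal(sum(cm2[, 2]), 24)
  expect_equal(sum(cm2[, -2]), 0)
  expect_equal(unname(rowSums(cm2)), rep(3, 8))
  expect_error(confusion_matrix(truths, rep("walking", 24)), "unknown")
  expect_error(confusion_matrix(cls, cls[1:4]), "equal length")
})

test_that("macro activity accuracy averages the row-normalized diagonal", {
  cm <- diag(5, 8)
  expect_equal(macro_activity_accuracy(cm), 1.0)
  expect_equal(macro_activity_accuracy(matrix(2, 8, 8)), 0.125)
  toy <- matrix(c(9, 1, 2, 8), 2, 2, byrow = TRUE)
  expect_equal(macro_activity_accuracy(toy), 0.85)
  # invariant under simultaneous row/column permutation
  set.seed(3)
  m <- matrix(rpois(64, 5) + 1, 8, 8)
  p <- sample(8)
  expect_equal(macro_activity_accuracy(m[p, p]), macro_activity_accuracy(m))
  bad <- diag(5, 8); bad[3, ] <- 0
  expect_error(macro_activity_accuracy(bad), "empty class")
})

test_that("averaged confusion matrices are row-normalized means", {
  m <- matrix(c(8, 2, 4, 6), 2, 2, byrow = TRUE)
  avg1 <- average_confusion(list(m, m, m))
  expect_equal(avg1, m / rowSums(m))
  p1 <- diag(2); p2 <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(average_confusion(list(3 * p1, 5 * p2)),
               matrix(0.5, 2, 2))
  expect_equal(unname(rowSums(average_confusion(list(m, 2 * m)))), c(1, 1),
               tolerance = 1e-9)
  expect_error(average_confusion(list()), "at least one")
})

test_that("best and worst subjects are the accuracy argmax/argmin with id-order ties", {
  expect_identical(best_worst_subjects(c(s1 = 0.9, s2 = 0.7, s3 = 0.8)),
                   list(best_id = "s1", worst_id = "s2"))
  expect_identical(best_worst_subjects(c(s2 = 0.9, s1 = 0.9))$best_id, "s1")
  expect_error(best_worst_subjects(c(s1 = 0.5)), "at least 2")
})

test_that("framework plans never leak rows between subsets", {
  for (seed in 1:5) {
    tab <- make_toy_table(19, seed = seed)
    plan <- split_framework1(tab, seed = seed)
    expect_length(intersect(plan$train_idx, plan$test_idx), 0)
    expect_length(intersect(plan$train_idx, plan$val_idx), 0)
    expect_length(intersect(plan$val_idx, plan$test_idx), 0)
  }
})
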