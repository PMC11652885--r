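test_that("a separable pair trains without error and predicts itself", {
  x <- rbind(c(0, 0), c(10, 10))
  m <- svm_train(x, c(TRUE, FALSE), gamma = 0.5, C = 10)
  expect_equal(unname(predict(m, x)), c("retained", "rejected"))
  expect_equal(sum(m$dual_coefficients), 0, tolerance = 1e-8)
  expect_error(svm_train(x, c(TRUE, TRUE), 1, 1), "single class")
  expect_error(svm_train(rbind(c(0, Inf), c(1, 1)), c(TRUE, FALSE), 1, 1),
               "non-finite")
})

test_that("the tuned SVM reproduces the printed training-set structure", {
  d <- table5_xy()
  fit <- svm_tune(d$x, d$y, k = 10, seed = 1)
  # training misclassifications after tuning: exactly compound 99
  pred <- predict(fit$model, d$x) == "retained"
  expect_equal(d$ids[pred != d$y], "99")
  # predictions reproduce the printed retention flags
  expect_gte(sum(pred == d$fixture$svm_retained), 31)
  # the printed spot checks
  expect_equal(unname(predict(fit$model,
                              matrix(c(4.5847445, 7.7454643), 1))),
               "retained")
  expect_equal(unname(predict(fit$model,
                              matrix(c(6.7910275, 5.6876111), 1))),
               "rejected")
  expect_lte(fit$cv$loss, 2 / 32)
})

test_that("duplicating the data set preserves the decision pattern", {
  d <- table5_xy()
  m1 <- svm_train(d$x, d$y, gamma = 0.3, C = 100)
  m2 <- svm_train(rbind(d$x, d$x), c(d$y, d$y), gamma = 0.3, C = 100)
  expect_equal(predict(m1, d$x), predict(m2, d$x))
})

test_that("cross-validation loss behaves sanely", {
  set.seed(7)
  blobs <- rbind(matrix(rnorm(40, 0, 0.3), ncol = 2),
                 matrix(rnorm(40, 5, 0.3), ncol = 2))
  lab <- rep(c(TRUE, FALSE), each = 20)
  cv <- svm_cv(blobs, lab, gamma = 1, C = 10, k = 5, seed = 1)
  expect_equal(cv$loss, 0)
  expect_true(all(cv$fold_assignments %in% 1:5))

  # permutation null: shuffled labels cannot beat the majority rate by much
  d <- table5_xy()
  set.seed(99)
  yperm <- sample(d$y)
  fitp <- svm_tune(d$x, yperm, k = 10, seed = 1, grid = coarse_grid(),
                   refine = FALSE)
  expect_gte(fitp$cv$loss, sum(yperm) / length(yperm) - 0.2)
})

test_that("prediction is invariant to serialisation round-trips", {
  d <- table5_xy()
  m <- svm_train(d$x, d$y, gamma = 0.3, C = 100)
  f <- withr::local_tempfile(fileext = ".json")
  svm_to_json(m, f)
  back <- svm_from_json(f)
  expect_equal(svm_decision(back, d$x), svm_decision(m, d$x),
               tolerance = 1e-10)
})

test_that("pair search recovers the planted descriptor pair", {
  d <- table5_xy()
  wins <- 0L
  for (seed in 1:10) {
    tab <- data.frame(compound_id = d$ids,
                      kier_a2 = d$x[, 1], slogp_vsa1 = d$x[, 2])
    set.seed(1000 + seed)
    tab$noise <- stats::rnorm(nrow(tab))
    rank <- pair_search(tab, d$y, k = 10, seed = seed, grid = coarse_grid())
    if (rank$d1[1] == "kier_a2" && rank$d2[1] == "slogp_vsa1") {
      wins <- wins + 1L
    }
  }
  expect_gte(wins, 6)  # majority over 10 seeds
})

test_that("pair search flags degenerate columns", {
  d <- table5_xy()
  tab <- data.frame(compound_id = d$ids, kier_a2 = d$x[, 1],
                    slogp_vsa1 = d$x[, 2], flat = 1,
                    copy = d$x[, 1])
  expect_warning(
    expect_warning(
      res <- pair_search(tab, d$y, k = 5, seed = 1, grid = coarse_grid()),
      "constant"),
    "duplicated")
  expect_equal(nrow(res), 1)  # only (kier_a2, slogp_vsa1) survives
})

test_that("decision maps are consistent under grid refinement", {
  d <- table5_xy()
  fit <- svm_tune(d$x, d$y, k = 10, seed = 1, grid = coarse_grid(),
                  refine = FALSE)
  bounds <- list(x = c(2, 16), y = c(0, 21))
  coarse <- decision_map(fit$model, bounds, grid_step = 2)
  fine <- decision_map(fit$model, bounds, grid_step = 1)
  shared <- merge(coarse, fine, by = c("kier_a2", "slogp_vsa1"))
  expect_true(all(shared$label.x == shared$label.y))
  expect_error(decision_map(fit$model, list(x = c(0, 1), y = c(0, 1)), 0),
               "grid_step")
})

test_that("the decision map reflects the validation-set geography", {
  d <- table5_xy()
  fit <- svm_tune(d$x, d$y, k = 10, seed = 1)
  # all printed retained training points fall in the retained region
  yes <- d$x[d$fixture$svm_retained, , drop = FALSE]
  expect_true(all(predict(fit$model, yes) == "retained"))
  # validation compounds (computed descriptors; linalyl acetate uses its
  # printed coordinates, it is training compound 4)
  t6 <- load_fixture("T6")
  dm <- descriptor_matrix(t6[, c("compound_id", "smiles")])
  coords <- function(cid) {
    as.numeric(dm[dm$compound_id == cid, c("kier_a2", "slogp_vsa1")])
  }
  retained_ids <- c("5284507", "637566", "31289", "638011")  # Fig-7 greens
  for (cid in retained_ids) {
    expect_equal(unname(predict(fit$model, matrix(coords(cid), 1))),
                 "retained", label = cid)
  }
  linalyl <- d$x[d$ids == "4", , drop = FALSE]
  expect_equal(unname(predict(fit$model, linalyl)), "retained")
  expect_equal(unname(predict(fit$model, matrix(coords("379"), 1))),
               "rejected")  # octanoic acid
})
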