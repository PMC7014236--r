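# Experiment pipelines: label assignment, accuracy metric, classifier
# training, and the graded-response analysis. The long coding
# experiments are exercised at reduced scale here; the full study
# conditions live in the acceptance suite.

test_that("label assignment matches brute force over all permutations", {
  # diagonal dominance -> identity
  m <- matrix(c(9, 1, 0, 0, 8, 1, 1, 0, 7), 3, 3, byrow = TRUE,
              dimnames = list(c("rest", "flexion", "extension"),
                              c("18", "19", "20")))
  a <- assign_labels_from_matrix(m)
  expect_identical(as.integer(a), c(18L, 19L, 20L))
  # permuted diagonal -> the inverse permutation
  mp <- m[, c(2, 3, 1)]
  colnames(mp) <- c("18", "19", "20")
  ap <- assign_labels_from_matrix(mp)
  expect_identical(as.integer(ap), c(20L, 18L, 19L))
  # random matrices against exhaustive search
  set.seed(42)
  for (i in 1:10) {
    r <- matrix(runif(9), 3, 3,
                dimnames = list(c("a", "b", "c"), c("1", "2", "3")))
    got <- assign_labels_from_matrix(r)
    perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                  c(3, 1, 2), c(3, 2, 1))
    scores <- vapply(perms, function(p) sum(r[cbind(1:3, p)]), 1)
    best <- perms[[which.max(scores)]]
    expect_identical(as.integer(got), as.integer(best))
  }
  # degenerate all-zero flagged but deterministic
  z <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("1", "2", "3")))
  expect_true(attr(assign_labels_from_matrix(z), "degenerate"))
})

test_that("the rate-ratio accuracy metric follows its printed definition", {
  set.seed(1)
  net <- build_emg_classifier(8, 3)
  cls <- attr(net, "classifiers")
  # synthetic responses: own 9 Hz, others 0.5 Hz each -> 0.9
  resp <- matrix(0.5, 3, 3, dimnames = list(c("rest", "flexion",
                                              "extension"),
                                            as.character(cls)))
  diag(resp) <- 9
  a <- assign_labels_from_matrix(resp)
  per <- resp[cbind(1:3, match(a, cls))] / rowSums(resp)
  expect_equal(unname(per), rep(0.9, 3))
  # scale invariance: doubling all rates leaves the ratio unchanged
  per2 <- (2 * resp)[cbind(1:3, match(a, cls))] / rowSums(2 * resp)
  expect_equal(per, per2)
})

test_that("temporal coding at reduced scale depresses late-rank synapses", {
  r <- run_temporal_coding(4, rule = "pair", train_s = 300, seed = 1)
  expect_true(all(r$weights >= 0 & r$weights <= 1))
  # early ranks end above late ranks
  expect_gt(mean(r$weights[1:4]), mean(r$weights[7:10]))
  expect_lt(r$rank_cor, 0)
})

test_that("unsupervised training separates the three gestures", {
  # machinery smoke test on one seed; the accuracy distribution over
  # seeds is covered by the acceptance suite
  emg <- generate_emg(seed = 7)
  fit <- snn_emg_classifier(emg, seed = 7)
  expect_identical(length(unique(fit$assignment)), 3L)
  expect_gt(fit$report$overall, 0.45) # well above the 1/3 chance level
  # locality: weights of a never-firing network are untouched
  set.seed(7)
  net <- build_emg_classifier(8, 3)
  net$neurons$D[net$neurons$layer == "rest_detector"] <- 0
  rest_only <- generate_emg(data.frame(gesture = "rest", duration = 5,
                                       effort = 0), seed = 7)
  tr <- train_unsupervised(net, rest_only, seed = 7)
  expect_identical(tr$synapses$w, net$synapses$w)
})

test_that("supervised training associates the commanded target map", {
  emg <- generate_emg(seed = 8)
  fit <- snn_emg_classifier(emg, method = "supervised", seed = 8)
  expect_identical(unname(unclass(fit$assignment))[1:3],
                   unname(fit$targets[names(fit$assignment)]))
  expect_gt(fit$report$overall, 0.9)
  # non-bijective target maps are rejected
  set.seed(8)
  net <- build_emg_classifier(8, 3)
  bad <- stats::setNames(rep(attr(net, "classifiers")[1], 3),
                         c("rest", "flexion", "extension"))
  expect_error(train_supervised(net, emg, bad), "bijection")
})

test_that("training determinism: same seed, same final weights", {
  emg <- generate_emg(seed = 3)
  set.seed(3); net <- build_emg_classifier(8, 3)
  a <- train_unsupervised(net, emg, seed = 31)
  b <- train_unsupervised(net, emg, seed = 31)
  expect_identical(a$synapses$w, b$synapses$w)
})

test_that("graded response grows with effort and fits a line", {
  emg <- generate_emg(seed = 9)
  fit <- snn_emg_classifier(emg, seed = 9)
  gr <- gradual_response(fit$net, "flexion",
                         classifier = fit$assignment[["flexion"]],
                         pattern_s = 5, seed = 9)
  expect_true(all(diff(gr$mav) > 0))
  expect_gt(gr$pearson_r, 0.9)
  expect_gt(gr$slope, 0)
  expect_error(gradual_response(fit$net, effort_levels = c(0.5, 1)),
               "3 effort levels")
})

test_that("weight profiles mirror channel amplitude profiles after training", {
  emg <- generate_emg(seed = 9)
  fit <- snn_emg_classifier(emg, seed = 9)
  wap <- weight_amplitude_profile(fit$net, emg, fit$assignment)
  expect_true(all(wap > 0.5))
  # constructed identity: weights equal to the amplitude profile
  net <- fit$net
  sens <- attr(net, "sensory")
  amp <- colMeans(abs(emg$samples[emg$labels == "flexion", ]))
  cls <- fit$assignment[["flexion"]]
  idx <- match(paste(sens, cls), paste(net$synapses$pre, net$synapses$post))
  net$synapses$w[idx] <- amp / max(amp)
  wap2 <- weight_amplitude_profile(net, emg, fit$assignment, "flexion")
  expect_equal(unname(wap2), 1, tolerance = 1e-6)
})

test_that("prediction on held-out EMG recovers the gesture sequence", {
  fit <- snn_emg_classifier(generate_emg(seed = 9), seed = 9)
  new_emg <- generate_emg(default_gesture_schedule(cycles = 1), seed = 99)
  pred <- predict(fit, new_emg, window_ms = 1000)
  truth <- new_emg$labels[round((pred$start_ms + 500) / 1000 * new_emg$fs)]
  expect_gt(mean(pred$gesture == truth, na.rm = TRUE), 0.45)
  rep <- attr(pred, "report")
  expect_s3_class(rep, "classifier_report")
})
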