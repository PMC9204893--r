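test_that("zero shrinkage reduces to plain nearest centroids; full shrinkage to priors", {
  blobs <- two_blob_expr(n_per = 10, genes = 15, sep = 3, seed = 21)
  m0 <- train_nsc(blobs$expr, blobs$labels, delta = 0)
  sc <- larsig:::shrunken_centroids(m0)
  expect_equal(unname(sc), unname(m0$centroids), tolerance = 1e-12)

  # unequal class sizes so the prior argmax is unambiguous
  lab_uneq <- rep(c("A", "B"), c(8, 12))
  m_base <- train_nsc(blobs$expr, lab_uneq, delta = 0)
  mfull <- train_nsc(blobs$expr, lab_uneq,
                     delta = max(abs(m_base$dprime)) + 1)
  expect_true(all(mfull$dprime == 0))
  test <- toy_expr(genes = 15, samples = 8, seed = 22)
  rownames(test) <- mfull$genes
  pr <- predict(mfull, test)
  expect_true(all(pr$label == names(which.max(mfull$priors))))
})

test_that("soft thresholding is monotone with nested support", {
  blobs <- two_blob_expr(n_per = 12, genes = 40, sep = 2, seed = 23)
  deltas <- c(0, 0.4, 0.8, 1.6)
  fits <- lapply(deltas, function(d) train_nsc(blobs$expr, blobs$labels, d))
  for (i in 2:length(fits)) {
    expect_true(all(abs(fits[[i]]$dprime) <= abs(fits[[i - 1]]$dprime) + 1e-12))
    nz_hi <- which(rowSums(fits[[i]]$dprime != 0) > 0)
    nz_lo <- which(rowSums(fits[[i - 1]]$dprime != 0) > 0)
    expect_true(all(nz_hi %in% nz_lo))
  }
  expect_true(all(abs(fits[[1]]$dprime) <=
                    abs(sweep(sweep(fits[[1]]$centroids -
                                      fits[[1]]$overall_centroid, 1,
                                    fits[[1]]$pooled_sd + fits[[1]]$s0, "/"),
                              2, larsig:::m_k_factor(fits[[1]]$n_per_class),
                              "/")) + 1e-12))
})

test_that("prediction at a shrunken centroid returns that class; priors break ties", {
  # 2-gene toy with hand-checkable geometry
  x <- matrix(c(0, 0,  0, 0,  4, 4,  4, 4), 2, 4,
              dimnames = list(c("G1", "G2"), paste0("S", 1:4)))
  lab <- c("LAR", "LAR", "non-LAR", "non-LAR")
  # add within-class spread so pooled sd is nonzero
  x <- x + matrix(c(-.5, .5, -.5, .5), 2, 4, byrow = TRUE)
  m <- train_nsc(expression_matrix(x, "log_normalized"), lab, delta = 0,
                 priors = c(0.5, 0.5))
  cent <- larsig:::shrunken_centroids(m)
  at_lar <- expression_matrix(matrix(cent[, "LAR"], 2,
                                     dimnames = list(rownames(x), "T1")),
                              "log_normalized")
  expect_equal(predict(m, at_lar)$label, "LAR")

  # exactly equidistant sample: priors decide (0.7 on LAR wins)
  mid <- expression_matrix(matrix(rowMeans(cent), 2,
                                  dimnames = list(rownames(x), "T1")),
                           "log_normalized")
  m_p <- train_nsc(expression_matrix(x, "log_normalized"), lab, delta = 0,
                   priors = c(0.7, 0.3))
  expect_equal(predict(m_p, mid)$label, "LAR")
  # with equal priors the equidistant tie resolves to non-LAR (conservative)
  expect_equal(predict(m, mid)$label, "non-LAR")
})

test_that("predictions are invariant to per-gene shifts and common scaling", {
  blobs <- two_blob_expr(n_per = 10, genes = 20, sep = 2, seed = 25)
  test <- toy_expr(genes = 20, samples = 15, seed = 26)
  rownames(test) <- rownames(blobs$expr)
  m <- train_nsc(blobs$expr, blobs$labels, delta = 0.5)
  p0 <- predict(m, test)

  shift <- rnorm(20)
  a <- 3.7
  tr2 <- expression_matrix(a * (as_plain_mat(blobs$expr) + shift),
                           "log_normalized")
  te2 <- expression_matrix(a * (as_plain_mat(test) + shift), "log_normalized")
  m2 <- train_nsc(tr2, blobs$labels, delta = a * 0.5)
  expect_identical(predict(m2, te2)$label, p0$label)
})

test_that("missing model genes are dropped, with a floor on coverage", {
  blobs <- two_blob_expr(n_per = 10, genes = 20, sep = 4, seed = 27)
  m <- train_nsc(blobs$expr, blobs$labels, delta = 0)
  test <- toy_expr(genes = 20, samples = 6, seed = 28)
  rownames(test) <- m$genes
  partial <- test[1:12, ]   # 60% of the signature present
  expect_message(p <- predict(m, partial), "dropping 8")
  expect_equal(nrow(p), 6L)
  tiny <- test[1:5, ]       # 25% coverage is refused
  expect_error(predict(m, tiny), "insufficient signature coverage")
})

test_that("cross-validated shrinkage classifies a planted two-subtype cohort", {
  set.seed(29)
  n <- 60; g <- 200
  lab <- rep(c("LAR", "non-LAR"), c(20, 40))
  x <- matrix(rnorm(g * n), g, n,
              dimnames = list(sprintf("G%03d", 1:g), sprintf("S%02d", 1:n)))
  x[1:50, lab == "LAR"] <- x[1:50, lab == "LAR"] + 1.5  # 50 informative genes
  ex <- expression_matrix(x, "log_normalized")
  m <- train_nsc(ex, lab, delta = "cv", seed = 1)
  expect_gt(m$delta, 0)
  acc <- mean(predict(m, ex)$label == lab)
  expect_gte(acc, 0.95)
})

test_that("binarization maps aliases case-insensitively and defaults to non-LAR", {
  expect_equal(binarize_labels(c("BL1", "LAR", "M")),
               c("non-LAR", "LAR", "non-LAR"))
  expect_equal(binarize_labels(c("BL1", "LAR"), lar_aliases = character(0)),
               c("non-LAR", "non-LAR"))
  expect_equal(binarize_labels(c("Luminal-AR", "lar", "basal"),
                               lar_aliases = c("LAR", "luminal-AR")),
               c("LAR", "LAR", "non-LAR"))
})

test_that("kappa matches the closed form and its invariances", {
  same <- rep(c("x", "y"), 10)
  expect_equal(cohens_kappa(same, same)$kappa, 1)

  # confusion [[40,10],[10,40]]: p_o = .8, p_e = .5, kappa = .6
  a <- rep(c("P", "N"), each = 50)
  b <- c(rep("P", 40), rep("N", 10), rep("P", 10), rep("N", 40))
  k <- cohens_kappa(a, b)
  expect_equal(k$kappa, 0.6)
  expect_equal(k$observed, 0.8)
  expect_equal(k$expected, 0.5)
  # symmetry and label-renaming invariance
  expect_equal(cohens_kappa(b, a)$kappa, 0.6)
  ren <- c(P = "LAR", N = "non-LAR")
  expect_equal(cohens_kappa(ren[a], ren[b])$kappa, 0.6)

  set.seed(31)
  r1 <- sample(c("L", "N"), 10000, TRUE)
  r2 <- sample(c("L", "N"), 10000, TRUE)
  expect_lt(abs(cohens_kappa(r1, r2)$kappa), 0.05)

  expect_equal(cohens_kappa(rep("L", 5), rep("L", 5))$kappa, 1)
  # two constant-but-different raters: p_o = p_e = 0, kappa = 0
  expect_equal(cohens_kappa(c("L", "L"), c("N", "N"))$kappa, 0)
})

test_that("pairwise kappa reports match a direct per-pair recomputation", {
  set.seed(32)
  ids <- sprintf("S%03d", 1:90)
  ds <- setNames(rep(c("d1", "d2", "d3"), each = 30), ids)
  truth <- setNames(sample(c("LAR", "non-LAR"), 90, TRUE, c(.3, .7)), ids)
  flip <- function(v, rate) {
    i <- runif(length(v)) < rate
    v[i] <- ifelse(v[i] == "LAR", "non-LAR", "LAR")
    v
  }
  calls <- list(m1 = truth, m2 = flip(truth, 0.1), m3 = flip(truth, 0.3))
  rep_ <- pairwise_kappa(calls, ds)
  expect_equal(nrow(rep_$per_dataset), 9L)
  for (r in seq_len(nrow(rep_$per_dataset))) {
    row <- rep_$per_dataset[r, ]
    ids_r <- ids[ds == row$dataset]
    expect_equal(row$kappa,
                 cohens_kappa(calls[[row$method_a]][ids_r],
                              calls[[row$method_b]][ids_r])$kappa)
  }
  # identical methods are perfectly concordant everywhere
  dup <- pairwise_kappa(list(a = truth, b = truth), ds)
  expect_true(all(dup$per_dataset$kappa == 1))
  # a method missing one dataset only loses that dataset from its pairs
  calls$m3 <- calls$m3[ds != "d3"]
  rep2 <- pairwise_kappa(calls, ds)
  m3_rows <- rep2$per_dataset$method_a == "m3" | rep2$per_dataset$method_b == "m3"
  expect_false("d3" %in% rep2$per_dataset$dataset[m3_rows])
  expect_true("d3" %in% rep2$per_dataset$dataset[!m3_rows])
})
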