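test_that("dinucleotide composition counts overlapping pairs over N-1", {
  v <- dnc("ACGT")
  expect_equal(unname(v[c("AC", "CG", "GT")]), rep(1 / 3, 3))
  expect_equal(sum(v), 1)
  expect_equal(unname(dnc("AAAA")["AA"]), 1)
  expect_error(dnc("ACGN"), "position")
  expect_error(dnc("A"), "shorter")
  ## random sequences: sliding-window oracle and unit sum
  set.seed(91)
  for (rep in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
               collapse = "")
    v2 <- dnc(s)
    expect_equal(sum(v2), 1, tolerance = 1e-9)
    ch <- strsplit(s, "")[[1]]
    for (pair in c("AA", "CT", "GC")) {
      cnt <- sum(ch[-1000] == substr(pair, 1, 1) &
                 ch[-1] == substr(pair, 2, 2))
      expect_equal(unname(v2[pair]), cnt / 999)
    }
  }
})

test_that("kmer3 uses the printed denominator N", {
  expect_equal(unname(kmer3("AAAA")["AAA"]), 2 / 4)   # 2 windows over N=4
  expect_equal(unname(kmer3("ACG")["ACG"]), 1 / 3)
  set.seed(92)
  for (rep in 1:5) {
    n <- sample(50:400, 1)
    s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
               collapse = "")
    expect_equal(sum(kmer3(s)), (n - 2) / n, tolerance = 1e-9)
  }
  ## frame mode counts in-frame codons
  vf <- kmer3("AAATTT", mode = "frame")
  expect_equal(unname(vf[c("AAA", "TTT")]), c(0.5, 0.5))
})

test_that("evolution features validate and derive the paralog average", {
  f <- evolution_features(list(mean_conservation = 0.7, dn_ds = 0.2,
                               n_species_with_gene = 90,
                               n_sequences = 10, n_unique_species = 8))
  expect_equal(f[["avg_paralog_number"]], 1.25)
  expect_equal(f[["occurrence_count"]], 90)
  f2 <- evolution_features(list(mean_conservation = 1, dn_ds = 0,
                                n_species_with_gene = 1,
                                n_sequences = 5, n_unique_species = 5))
  expect_equal(f2[["avg_paralog_number"]], 1)
  expect_error(evolution_features(list(mean_conservation = 1.2,
                                       dn_ds = 0, n_species_with_gene = 1,
                                       n_sequences = 5,
                                       n_unique_species = 5)),
               "conservation")
  expect_error(evolution_features(list(mean_conservation = 0.5,
                                       dn_ds = 0, n_species_with_gene = 1,
                                       n_sequences = 3,
                                       n_unique_species = 5)),
               "n_sequences")
})

test_that("minority oversampling balances the classes", {
  labels <- rep(c(1, 0), c(30, 70))
  idx <- oversample_minority(labels, seed = 93)
  expect_length(idx, 140)
  expect_equal(sum(labels[idx] == 1), 70)
  expect_equal(sum(labels[idx] == 0), 70)
  ## originals all retained, majority untouched
  expect_true(all(seq_along(labels) %in% idx))
  expect_equal(sum(idx %in% which(labels == 0)), 70)
  ## already balanced -> identity
  bal <- rep(c(1, 0), 10)
  expect_identical(oversample_minority(bal, 1), seq_along(bal))
  expect_error(oversample_minority(rep(1, 5), 1), "two classes")
  ## deterministic under seed; balanced for random inputs
  set.seed(94)
  for (rep in 1:10) {
    l <- rbinom(50, 1, 0.3)
    if (length(unique(l)) < 2) next
    i1 <- oversample_minority(l, seed = rep)
    i2 <- oversample_minority(l, seed = rep)
    expect_identical(i1, i2)
    expect_equal(sum(l[i1] == 0), sum(l[i1] == 1))
  }
})

test_that("AUC agrees with trapezoidal integration and pROC", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))$auc, 1)
  set.seed(95)
  for (rep in 1:10) {
    n <- 40
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    scores <- rnorm(n) + labels
    got <- roc_auc(scores, labels)
    ## trapezoidal integration of the ROC curve
    roc <- got$roc
    trap <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                 utils::tail(roc$tpr, -1)) / 2)
    expect_equal(got$auc, trap, tolerance = 1e-10)
    ## independent cross-check
    pr <- suppressMessages(pROC::auc(labels, scores,
                                     direction = "<", quiet = TRUE))
    expect_equal(got$auc, as.numeric(pr), tolerance = 1e-10)
  }
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("label-independent scores give chance-level AUC", {
  set.seed(96)
  n <- 10000
  labels <- rbinom(n, 1, 0.5)
  scores <- rnorm(n)
  auc <- roc_auc(scores, labels)$auc
  n1 <- sum(labels == 1); n0 <- n - n1
  se <- sqrt((n + 1) / (12 * n1 * n0))
  expect_lt(abs(auc - 0.5), 3 * se)
})

test_that("chi-square ranking separates informative features", {
  set.seed(97)
  n <- 200
  labels <- rep(c(1, 0), each = n / 2)
  X <- cbind(constant = rep(0.5, n),
             indicator = as.numeric(labels),
             noise = runif(n))
  out <- feature_importance_chi2(X, labels)
  expect_equal(out$feature[1], "indicator")
  expect_equal(out$statistic[out$feature == "constant"], 0)
  expect_equal(out$feature[nrow(out)], "constant")
  expect_error(feature_importance_chi2(cbind(x = c(-1, 1)), c(0, 1)),
               "negative")
  ## statistics match a contingency-table oracle on mass aggregates
  for (j in colnames(X)) {
    obs <- c(sum(X[labels == 1, j]), sum(X[labels == 0, j]))
    expd <- sum(obs) * c(mean(labels == 1), mean(labels == 0))
    expect_equal(out$statistic[out$feature == j],
                 sum((obs - expd)^2 / expd), tolerance = 1e-12)
  }
})

test_that("evolution features lift AUC over sequence features alone", {
  gs <- generate_sequences(120, 150, 0.05, seed = 98)
  Xseq <- cbind(t(vapply(gs$sequences, dnc, numeric(16))),
                t(vapply(gs$sequences, kmer3, numeric(64))))
  Xall <- cbind(Xseq, as.matrix(gs$evo[, -1]))
  auc_seq <- ml_evaluate(Xseq, gs$labels, "rf", seed = 99)$auc
  auc_all <- ml_evaluate(Xall, gs$labels, "rf", seed = 99)$auc
  expect_gt(auc_all, auc_seq)
})

test_that("leave-one-species-out splitting holds out the species", {
  gs <- generate_sequences(60, 120, 0.2, seed = 100)
  X <- t(vapply(gs$sequences, kmer3, numeric(64)))
  species <- rep(c("spA", "spB", "spC", "spD"), length.out = nrow(X))
  ev <- ml_evaluate(X, gs$labels, "rf", species = species,
                    test_species = "spD", seed = 101)
  expect_equal(ev$n_test, sum(species == "spD"))
  expect_gt(ev$auc, 0.6)
})
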