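#' @title Sequence and evolution features for essential-gene prediction
#' @description
#' Dinucleotide composition (overlapping counts over N-1), trinucleotide
#' Kmer frequencies (overlapping counts over N, following the printed
#' definition; counts sum to (N-2)/N), evolution-based features
#' (conservation, dN/dS, occurrence, average paralog number), minority
#' oversampling, ROC/AUC by the rank formulation, chi-square feature
#' ranking, and a thin fit/score interface over standard classifier
#' backends.
#' @name essml
NULL

.NUC <- c("A", "C", "G", "T")

.check_seq <- function(sequence, min_len) {
  s <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!s %in% .NUC)
  if (length(bad))
    stop("ambiguous/non-ACGT base(s) at position(s) ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "")
  if (length(s) < min_len)
    stop("sequence shorter than ", min_len, " bases")
  s
}

#' Dinucleotide composition
#'
#' Overlapping dinucleotide counts divided by N-1, in fixed order
#' AA, AC, AG, AT, CA, ..., TT; entries sum to 1.
#' @param sequence nucleotide string (A/C/G/T only, length >= 2).
#' @return named numeric vector of length 16.
#' @export
dnc <- function(sequence) {
  s <- .check_seq(sequence, 2L)
  n <- length(s)
  pairs <- paste0(s[-n], s[-1L])
  lv <- as.vector(outer(.NUC, .NUC, paste0))
  lv <- lv[order(lv)]
  stats::setNames(as.numeric(table(factor(pairs, levels = lv))) / (n - 1),
                  lv)
}

#' Trinucleotide (k = 3) Kmer frequencies
#'
#' Overlapping trinucleotide counts divided by the sequence length N
#' (the printed denominator; overlapping counts total N-2, so the vector
#' sums to (N-2)/N).  `mode = "frame"` counts in-frame codons instead
#' (denominator N/3).
#' @param sequence nucleotide string (A/C/G/T only, length >= 3).
#' @param mode "overlapping" (default) or "frame".
#' @return named numeric vector of length 64, lexicographic order.
#' @export
kmer3 <- function(sequence, mode = c("overlapping", "frame")) {
  mode <- match.arg(mode)
  s <- .check_seq(sequence, 3L)
  n <- length(s)
  lv <- as.vector(outer(outer(.NUC, .NUC, paste0), .NUC, paste0))
  lv <- lv[order(lv)]
  if (mode == "overlapping") {
    tri <- paste0(s[1:(n - 2)], s[2:(n - 1)], s[3:n])
    den <- n
  } else {
    starts <- seq(1, n - 2, by = 3)
    tri <- paste0(s[starts], s[starts + 1], s[starts + 2])
    den <- length(tri)
  }
  stats::setNames(as.numeric(table(factor(tri, levels = lv))) / den, lv)
}

#' Evolution-based features from an ortholog-group summary
#'
#' The average paralog number is the number of sequences in the OG
#' divided by the number of unique species in it; occurrence is the
#' number of species carrying the gene.
#' @param og_summary list/one-row data.frame with `mean_conservation`
#'   (in [0,1]), `dn_ds` (>= 0), `n_species_with_gene`, `n_sequences`,
#'   `n_unique_species`.
#' @return named numeric vector: `conservation_score`, `dn_ds`,
#'   `occurrence_count`, `avg_paralog_number`.
#' @export
evolution_features <- function(og_summary) {
  g <- as.list(og_summary)
  need <- c("mean_conservation", "dn_ds", "n_species_with_gene",
            "n_sequences", "n_unique_species")
  if (!all(need %in% names(g)))
    stop("evolution_features: need fields ", paste(need, collapse = ", "))
  if (g$n_unique_species < 1)
    stop("evolution_features: n_unique_species must be >= 1")
  if (g$n_sequences < g$n_unique_species)
    stop("evolution_features: n_sequences < n_unique_species")
  if (g$mean_conservation < 0 || g$mean_conservation > 1)
    stop("evolution_features: conservation outside [0, 1]")
  if (g$dn_ds < 0) stop("evolution_features: negative dN/dS")
  c(conservation_score = as.numeric(g$mean_conservation),
    dn_ds = as.numeric(g$dn_ds),
    occurrence_count = as.numeric(g$n_species_with_gene),
    avg_paralog_number = as.numeric(g$n_sequences / g$n_unique_species))
}

#' Balance classes by oversampling the minority
#'
#' Returns an index multiset: every original index once, plus minority
#' indices resampled with replacement until the class counts are equal.
#' @param labels binary vector (two classes required).
#' @param seed integer seed.
#' @return integer vector of indices into `labels`.
#' @export
oversample_minority <- function(labels, seed = 1) {
  tab <- table(labels)
  if (length(tab) != 2)
    stop("oversample_minority: need exactly two classes")
  if (tab[1] == tab[2]) return(seq_along(labels))
  minority <- names(tab)[which.min(tab)]
  idx_min <- which(labels == minority)
  extra_n <- max(tab) - min(tab)
  extra <- .with_seed(seed, sample(idx_min, extra_n, replace = TRUE))
  c(seq_along(labels), extra)
}

#' ROC curve and AUC
#'
#' ROC by threshold sweep over the unique scores; AUC by the rank
#' (Mann-Whitney) formulation, ties contributing one half.
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels binary labels (1 = positive).
#' @return list: `roc` (data.frame threshold/fpr/tpr) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(unique(labels)) != 2 || !all(labels %in% c(0, 1)))
    stop("roc_auc: need both classes, labels in {0, 1}")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(th, function(t) sum(scores >= t & labels == 1) / n1,
                numeric(1))
  fpr <- vapply(th, function(t) sum(scores >= t & labels == 0) / n0,
                numeric(1))
  roc <- data.frame(threshold = c(Inf, th), fpr = c(0, fpr),
                    tpr = c(0, tpr))
  list(roc = roc, auc = auc)
}

#' Chi-square feature ranking
#'
#' Per feature, the chi-square statistic between class-aggregated
#' feature mass and the class priors (non-negative features required);
#' features are ranked by descending statistic.
#' @param features numeric matrix/data.frame (samples x features).
#' @param labels class labels.
#' @return data.frame `feature`, `statistic`, sorted descending.
#' @export
feature_importance_chi2 <- function(features, labels) {
  X <- as.matrix(features)
  if (any(X < 0)) stop("feature_importance_chi2: negative feature value")
  f <- factor(labels)
  classes <- levels(f)
  prior <- as.numeric(table(f)) / length(f)
  stat <- vapply(seq_len(ncol(X)), function(j) {
    obs <- vapply(classes, function(cl) sum(X[f == cl, j]), numeric(1))
    exp <- sum(obs) * prior
    if (all(exp == 0)) return(0)
    sum((obs - exp)^2 / exp)
  }, numeric(1))
  out <- data.frame(feature = colnames(X) %||%
                      paste0("V", seq_len(ncol(X))),
                    statistic = stat, stringsAsFactors = FALSE)
  out[order(-out$statistic, out$feature), , drop = FALSE]
}

#' Fit / score interface over classifier backends
#'
#' Backends are consumed, not re-implemented: random forest
#' (`randomForest`) and support-vector machine (`e1071::svm`, radial
#' kernel, probability output).
#' @param features samples x features matrix.
#' @param labels binary labels (coerced to factor).
#' @param method "rf" or "svm".
#' @param seed integer seed for the stochastic backends.
#' @return classifier object with class `gemevo_clf`.
#' @export
ml_fit <- function(features, labels, method = c("rf", "svm"), seed = 1) {
  method <- match.arg(method)
  X <- as.matrix(features)
  y <- factor(labels)
  fit <- .with_seed(seed, {
    if (method == "rf")
      randomForest::randomForest(x = X, y = y, ntree = 300)
    else
      e1071::svm(x = X, y = y, kernel = "radial", probability = TRUE)
  })
  structure(list(fit = fit, method = method, positive = levels(y)[2]),
            class = "gemevo_clf")
}

#' @rdname ml_fit
#' @param object a fitted `gemevo_clf`.
#' @param newdata samples x features matrix.
#' @return numeric vector of positive-class probabilities.
#' @export
ml_score <- function(object, newdata) {
  X <- as.matrix(newdata)
  if (object$method == "rf") {
    p <- stats::predict(object$fit, X, type = "prob")
    as.numeric(p[, object$positive])
  } else {
    pr <- stats::predict(object$fit, X, probability = TRUE)
    as.numeric(attr(pr, "probabilities")[, object$positive])
  }
}

#' Train/test evaluation of essential-gene classification
#'
#' Random split (fraction `train_frac`) or leave-one-species-out (give
#' `species` and `test_species`), with minority oversampling of the
#' training set, returning confusion metrics at score 0.5 and the AUC.
#' @param features samples x features matrix.
#' @param labels binary labels (1 = essential).
#' @param method "rf" or "svm".
#' @param train_frac fraction for the random split (default 0.8).
#' @param species,test_species optional species assignment per sample
#'   and the held-out species.
#' @param oversample balance training classes (default TRUE).
#' @param seed integer seed.
#' @return list: `metrics` (from [confusion_metrics()]), `auc`, `n_train`,
#'   `n_test`.
#' @export
ml_evaluate <- function(features, labels, method = c("rf", "svm"),
                        train_frac = 0.8, species = NULL,
                        test_species = NULL, oversample = TRUE,
                        seed = 1) {
  method <- match.arg(method)
  X <- as.matrix(features)
  y <- as.numeric(labels)
  n <- nrow(X)
  if (!is.null(species) && !is.null(test_species)) {
    test_idx <- which(species %in% test_species)
  } else {
    test_idx <- .with_seed(seed + 1L,
                           sample.int(n, round((1 - train_frac) * n)))
  }
  train_idx <- setdiff(seq_len(n), test_idx)
  if (oversample) {
    os <- oversample_minority(y[train_idx], seed = seed + 2L)
    train_idx <- train_idx[os]
  }
  clf <- ml_fit(X[train_idx, , drop = FALSE], y[train_idx],
                method = method, seed = seed + 3L)
  sc <- ml_score(clf, X[test_idx, , drop = FALSE])
  yt <- y[test_idx]
  pred <- as.numeric(sc >= 0.5)
  counts <- list(TP = sum(pred == 1 & yt == 1),
                 TN = sum(pred == 0 & yt == 0),
                 FP = sum(pred == 1 & yt == 0),
                 FN = sum(pred == 0 & yt == 1))
  list(metrics = confusion_metrics(counts),
       auc = roc_auc(sc, yt)$auc,
       n_train = length(train_idx), n_test = length(test_idx))
}
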