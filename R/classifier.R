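#' Two-threshold labelling of bursting regimes
#'
#' An epoch is labelled high-amplitude (1) when both the voltage-envelope
#' amplitude exceeds `v_thr` and the [Na+]_i oscillation amplitude exceeds
#' `na_thr`; otherwise low-amplitude (0).  Vectorised.
#'
#' @param v_amp envelope voltage amplitude (V).
#' @param na_amp [Na+]_i oscillation amplitude (M).
#' @param v_thr voltage threshold (V), default 20 mV.
#' @param na_thr concentration threshold (M), default 1 mM.
#' @return integer vector of 0/1 labels.
#' @export
two_threshold_label <- function(v_amp, na_amp, v_thr = 0.020,
                                na_thr = 0.001) {
  as.integer(v_amp > v_thr & na_amp > na_thr)
}

#' Fit a Gaussian naive Bayes classifier
#'
#' Maximum-likelihood per-class, per-feature means and variances with
#' empirical class priors.  Variances are floored at `var_floor_frac`
#' times the largest overall feature variance so that degenerate
#' (zero-variance) features keep the posteriors finite.
#'
#' @param x numeric matrix or data frame of features (rows = samples).
#' @param y labels (any two or more distinct values); both classes must be
#'   present.
#' @param var_floor_frac variance floor, as a fraction of the largest
#'   feature variance.
#' @return an object of class `hn_gnb`.
#' @export
gnb_fit <- function(x, y, var_floor_frac = 1e-9) {
  x <- as.matrix(x)
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("gnb_fit: training set has a single class")
  vfun <- function(v) stats::var(v) * (length(v) - 1) / length(v)  # MLE
  floor_v <- var_floor_frac * max(apply(x, 2, vfun), .Machine$double.eps)
  mu <- t(vapply(classes, function(k) colMeans(x[y == k, , drop = FALSE]),
                 numeric(ncol(x))))
  s2 <- t(vapply(classes, function(k) {
    pmax(apply(x[y == k, , drop = FALSE], 2, vfun), floor_v)
  }, numeric(ncol(x))))
  structure(list(classes = classes,
                 prior = as.vector(table(factor(y, classes)) / length(y)),
                 mean = mu, var = s2, var_floor = floor_v,
                 features = colnames(x)),
            class = "hn_gnb")
}

#' Predict with a Gaussian naive Bayes classifier
#'
#' Assigns each row to the class maximising log prior plus the sum of
#' per-feature log Gaussian densities; posteriors are normalised per row.
#'
#' @param model an `hn_gnb` from [gnb_fit()].
#' @param x feature matrix or data frame.
#' @return list with `label` (character vector) and `posterior`
#'   (matrix, one column per class, rows summing to 1).
#' @export
gnb_predict <- function(model, x) {
  x <- as.matrix(x)
  loglik <- vapply(seq_along(model$classes), function(k) {
    log(model$prior[k]) +
      Reduce(`+`, lapply(seq_len(ncol(x)), function(j) {
        stats::dnorm(x[, j], model$mean[k, j], sqrt(model$var[k, j]),
                     log = TRUE)
      }))
  }, numeric(nrow(x)))
  loglik <- matrix(loglik, nrow = nrow(x))
  post <- exp(loglik - apply(loglik, 1, max))
  post <- post / rowSums(post)
  colnames(post) <- model$classes
  list(label = model$classes[max.col(post, ties.method = "first")],
       posterior = post)
}

#' Classification report
#'
#' Per-class precision (true positives over predicted positives), recall
#' (true positives over actual positives), F1 (harmonic mean of the two)
#' and support, plus overall accuracy and macro / support-weighted
#' averages.
#'
#' @param true,predicted equal-length label vectors.
#' @return list with `per_class` (data frame), `accuracy`, `macro_avg`,
#'   `weighted_avg`.
#' @export
classification_report <- function(true, predicted) {
  if (!length(true)) stop("classification_report: empty input")
  stopifnot(length(true) == length(predicted))
  true <- as.character(true); predicted <- as.character(predicted)
  classes <- sort(unique(c(true, predicted)))
  per <- do.call(rbind, lapply(classes, function(k) {
    tp <- sum(true == k & predicted == k)
    fp <- sum(true != k & predicted == k)
    fn <- sum(true == k & predicted != k)
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0) {
      2 * precision * recall / (precision + recall)
    } else 0
    data.frame(class = k, precision = precision, recall = recall,
               f1 = f1, support = tp + fn)
  }))
  w <- per$support / sum(per$support)
  avg <- function(weights) {
    c(precision = sum(per$precision * weights),
      recall = sum(per$recall * weights), f1 = sum(per$f1 * weights))
  }
  list(per_class = per,
       accuracy = mean(true == predicted),
       macro_avg = avg(rep(1 / nrow(per), nrow(per))),
       weighted_avg = avg(w))
}

#' Seeded, stratified train/test split
#'
#' Draws `train_frac` of the rows for training, stratified by class when
#' every class has at least two members, and returns index vectors.  The
#' draw is reproducible for a given seed and does not disturb the global
#' RNG state.
#'
#' @param labels class labels, one per row.
#' @param train_frac fraction of rows used for training.
#' @param seed integer seed.
#' @return list with integer vectors `train` and `test`.
#' @export
train_test_split <- function(labels, train_frac = 0.35, seed = 1) {
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()),
            add = TRUE)
  }
  set.seed(seed)
  idx <- seq_along(labels)
  strat <- all(table(labels) >= 2)
  train <- if (strat) {
    unlist(lapply(split(idx, labels), function(i) {
      sample(i, max(1, round(train_frac * length(i))))
    }), use.names = FALSE)
  } else {
    sample(idx, max(1, round(train_frac * length(idx))))
  }
  list(train = sort(train), test = setdiff(idx, train))
}
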