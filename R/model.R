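# Chained neural-network harness. NN1 maps the six morphological metrics to
# intravascular oxygen (OXY_V); NN2 maps the metrics plus OXY_V to tissue
# oxygen (OXY_T). NN2 is trained with the true oracle OXY_V (teacher
# forcing) and chained onto NN1's prediction at inference; the chained,
# clipped output is the VNQI. Architectures are chosen by a seeded random
# search over single-hidden-layer width x weight-decay candidates, scored
# by mean squared error on an inner validation split.

#' Training specification for the chained networks
#'
#' @param hidden_widths Candidate hidden-layer widths (units).
#' @param decay Candidate weight-decay (L2) values.
#' @param maxit Maximum optimizer iterations per fit.
#' @param search_budget Number of width x decay candidates drawn per network.
#' @param val_frac Fraction of the training set held out as the inner
#'   validation split used to rank candidates.
#' @param rng_seed Integer seed; fixes candidate draws, inner split and
#'   weight initialization, making training fully reproducible.
#' @return Object of class `chain_spec`.
#' @export
chain_spec <- function(hidden_widths = c(4L, 8L, 16L, 32L, 64L),
                       decay = c(1e-4, 1e-3, 1e-2),
                       maxit = 500L,
                       search_budget = 10L,
                       val_frac = 0.2,
                       rng_seed = 1L) {
  if (any(hidden_widths < 1)) stopf("hidden widths must be >= 1")
  if (search_budget < 1) stopf("search_budget must be >= 1")
  if (val_frac <= 0 || val_frac >= 1) stopf("val_frac must be in (0, 1)")
  structure(list(hidden_widths = as.integer(hidden_widths),
                 decay = as.numeric(decay), maxit = as.integer(maxit),
                 search_budget = as.integer(search_budget),
                 val_frac = val_frac, rng_seed = as.integer(rng_seed)),
            class = "chain_spec")
}

#' Seeded train/test split
#'
#' @param records Data frame of samples (>= 10 rows).
#' @param train_frac Training fraction in (0, 1); the training set gets
#'   `ceiling(train_frac * n)` rows, e.g. 400/100 at n = 500.
#' @param seed Integer seed for the shuffle.
#' @return List with `train` and `test` data frames (disjoint, exhaustive).
#' @export
split_dataset <- function(records, train_frac = 0.8, seed = 1L) {
  if (train_frac <= 0 || train_frac >= 1) stopf("train_frac must be in (0, 1)")
  n <- nrow(records)
  if (n < 10) stopf("need at least 10 records to split")
  n_train <- ceiling(train_frac * n)
  perm <- with_seed(seed, sample.int(n))
  list(train = records[perm[seq_len(n_train)], , drop = FALSE],
       test = records[perm[(n_train + 1):n], , drop = FALSE])
}

# --- internal fitting machinery ---------------------------------------------

make_scaler <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0] <- 1
  list(center = ctr, scale = scl)
}

apply_scaler <- function(x, scaler) {
  scale(as.matrix(x), center = scaler$center, scale = scaler$scale)
}

feature_matrix <- function(records) {
  miss <- setdiff(metric_columns, names(records))
  if (length(miss)) stopf("missing metric columns: %s", paste(miss, collapse = ", "))
  x <- as.matrix(records[, metric_columns])
  if (anyNA(x)) stopf("missing values in metric columns")
  x
}

# Random search over (width, decay) candidates; returns the refitted winner.
search_fit <- function(x, y, spec, seed) {
  y <- as.matrix(y)
  with_seed(seed, {
    n <- nrow(x)
    n_val <- max(1L, round(spec$val_frac * n))
    perm <- sample.int(n)
    val_idx <- perm[seq_len(n_val)]
    tr_idx <- perm[(n_val + 1):n]
    width <- sample(spec$hidden_widths, spec$search_budget, replace = TRUE)
    decay <- sample(spec$decay, spec$search_budget, replace = TRUE)
    best <- NULL
    for (i in seq_len(spec$search_budget)) {
      fit <- nnet::nnet(x[tr_idx, , drop = FALSE], y[tr_idx, , drop = FALSE],
                        size = width[i], decay = decay[i], maxit = spec$maxit,
                        linout = TRUE, trace = FALSE, MaxNWts = 20000L)
      pred <- predict(fit, x[val_idx, , drop = FALSE])
      mse <- mean((y[val_idx, , drop = FALSE] - pred)^2)
      if (!is.finite(mse))
        stopf("training diverged for candidate %d (width %d, decay %g)",
              i, width[i], decay[i])
      if (is.null(best) || mse < best$val_mse)
        best <- list(width = width[i], decay = decay[i], val_mse = mse)
    }
    final <- nnet::nnet(x, y, size = best$width, decay = best$decay,
                        maxit = spec$maxit, linout = TRUE, trace = FALSE,
                        MaxNWts = 20000L)
    list(fit = final, width = best$width, decay = best$decay,
         val_mse = best$val_mse)
  })
}

check_labels <- function(records, cols) {
  for (col in cols) {
    if (!col %in% names(records)) stopf("missing label column '%s'", col)
    if (anyNA(records[[col]])) stopf("missing values in '%s'", col)
  }
}

# --- chained model -----------------------------------------------------------

#' Fit the chained neural network (NN1 + NN2)
#'
#' NN1 regresses OXY_V on the six standardized metrics; NN2 regresses OXY_T
#' on the metrics plus the *oracle* OXY_V (teacher forcing). Input
#' standardization statistics are computed on the training set only.
#'
#' @param train Data frame with the six metric columns plus `oxy_v`, `oxy_t`.
#' @param spec A [chain_spec()].
#' @return Object of class `vnqi_chain`: fitted networks, scaler statistics
#'   and a training manifest (seed and selected architectures).
#' @export
fit_chain <- function(train, spec = chain_spec()) {
  check_labels(train, c("oxy_v", "oxy_t"))
  x <- feature_matrix(train)
  scaler <- make_scaler(x)
  xs <- apply_scaler(x, scaler)
  ov_center <- mean(train$oxy_v)
  ov_scale <- sd(train$oxy_v)
  if (ov_scale == 0) ov_scale <- 1
  nn1 <- search_fit(xs, train$oxy_v, spec, derive_seed(spec$rng_seed, 1))
  x2 <- cbind(xs, oxy_v = (train$oxy_v - ov_center) / ov_scale)
  nn2 <- search_fit(x2, train$oxy_t, spec, derive_seed(spec$rng_seed, 2))
  structure(list(
    nn1 = nn1$fit, nn2 = nn2$fit,
    scaler = scaler, ov_center = ov_center, ov_scale = ov_scale,
    spec = spec,
    manifest = list(
      rng_seed = spec$rng_seed, n_train = nrow(train),
      nn1_width = nn1$width, nn1_decay = nn1$decay, nn1_val_mse = nn1$val_mse,
      nn2_width = nn2$width, nn2_decay = nn2$decay, nn2_val_mse = nn2$val_mse
    )
  ), class = "vnqi_chain")
}

#' @export
print.vnqi_chain <- function(x, ...) {
  cat(sprintf(
    "<vnqi_chain> NN1 width %d (decay %g), NN2 width %d (decay %g), n_train %d\n",
    x$manifest$nn1_width, x$manifest$nn1_decay,
    x$manifest$nn2_width, x$manifest$nn2_decay, x$manifest$n_train))
  invisible(x)
}

#' NN1's intravascular-oxygen prediction
#'
#' @param chain A fitted [fit_chain()] object.
#' @param records Data frame with the six metric columns.
#' @return Numeric vector of raw (unclipped) OXY_V predictions.
#' @export
predict_oxy_v <- function(chain, records) {
  stopifnot(inherits(chain, "vnqi_chain"))
  xs <- apply_scaler(feature_matrix(records), chain$scaler)
  as.numeric(predict(chain$nn1, xs))
}

#' Chained VNQI prediction
#'
#' VNQI = clip(NN2(metrics, NN1(metrics)), 0, 1). NN1's raw prediction is
#' fed to NN2 (standardized with the training statistics); only the final
#' output is clipped to the unit interval.
#'
#' @param chain A fitted [fit_chain()] object.
#' @param records Data frame with the six metric columns (one row per
#'   sample).
#' @return Numeric vector of VNQI scores in `[0, 1]`.
#' @export
predict_vnqi <- function(chain, records) {
  if (!inherits(chain, "vnqi_chain")) stopf("not a fitted vnqi_chain")
  xs <- apply_scaler(feature_matrix(records), chain$scaler)
  ov <- as.numeric(predict(chain$nn1, xs))
  x2 <- cbind(xs, oxy_v = (ov - chain$ov_center) / chain$ov_scale)
  clip01(as.numeric(predict(chain$nn2, x2)))
}

#' @export
predict.vnqi_chain <- function(object, newdata, ...) {
  predict_vnqi(object, newdata)
}

# --- baseline architectures --------------------------------------------------

baseline_variants <- c("multi_output", "single_oxy_v", "single_oxy_t",
                       "oxy_t_with_true_oxy_v")

#' Fit one of the four comparison architectures
#'
#' The non-chained architectures of the comparison harness: a multi-output
#' network predicting OXY_V and OXY_T jointly from morphology; single-output
#' networks for OXY_V or OXY_T from morphology; and a single-output OXY_T
#' network whose inputs include the true (oracle) OXY_V. All use the same
#' seeded search protocol as [fit_chain()].
#'
#' @param train Data frame with metric and label columns.
#' @param variant One of `"multi_output"`, `"single_oxy_v"`,
#'   `"single_oxy_t"`, `"oxy_t_with_true_oxy_v"`.
#' @param spec A [chain_spec()].
#' @return Object of class `vnqi_model` with a `predict()` method
#'   (predictions clipped to `[0, 1]`). The `oxy_t_with_true_oxy_v` variant
#'   requires an `oxy_v` column in new data at prediction time.
#' @export
fit_baseline <- function(train, variant, spec = chain_spec()) {
  if (!variant %in% baseline_variants)
    stopf("unknown variant '%s'", variant)
  check_labels(train, c("oxy_v", "oxy_t"))
  x <- feature_matrix(train)
  scaler <- make_scaler(x)
  xs <- apply_scaler(x, scaler)
  ov_center <- mean(train$oxy_v); ov_scale <- sd(train$oxy_v)
  if (ov_scale == 0) ov_scale <- 1
  y <- switch(variant,
    multi_output = cbind(oxy_v = train$oxy_v, oxy_t = train$oxy_t),
    single_oxy_v = train$oxy_v,
    single_oxy_t = train$oxy_t,
    oxy_t_with_true_oxy_v = train$oxy_t
  )
  xin <- if (variant == "oxy_t_with_true_oxy_v") {
    cbind(xs, oxy_v = (train$oxy_v - ov_center) / ov_scale)
  } else xs
  res <- search_fit(xin, y, spec, derive_seed(spec$rng_seed, 3))
  structure(list(variant = variant, fit = res$fit, scaler = scaler,
                 ov_center = ov_center, ov_scale = ov_scale, spec = spec,
                 manifest = list(rng_seed = spec$rng_seed,
                                 width = res$width, decay = res$decay,
                                 val_mse = res$val_mse,
                                 n_train = nrow(train))),
            class = "vnqi_model")
}

#' @export
predict.vnqi_model <- function(object, newdata, ...) {
  xs <- apply_scaler(feature_matrix(newdata), object$scaler)
  xin <- if (object$variant == "oxy_t_with_true_oxy_v") {
    if (!"oxy_v" %in% names(newdata))
      stopf("variant oxy_t_with_true_oxy_v needs an oxy_v column")
    cbind(xs, oxy_v = (newdata$oxy_v - object$ov_center) / object$ov_scale)
  } else xs
  p <- predict(object$fit, xin)
  if (object$variant == "multi_output") {
    colnames(p) <- c("oxy_v", "oxy_t")
    clip01(p)
  } else clip01(as.numeric(p))
}

# --- evaluation --------------------------------------------------------------

#' Regression accuracy metrics and residuals
#'
#' @param y_true,y_pred Numeric vectors of equal length (>= 2).
#' @return Object of class `vnqi_eval`: list with `r2` (1 - SSE/SST; `NA`
#'   with a warning when `y_true` has zero variance), `mae`, `mse`, `rmse`
#'   and `residuals` (measured - predicted).
#' @export
evaluate_predictions <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stopf("length mismatch")
  if (length(y_true) < 2) stopf("need at least 2 observations")
  res <- y_true - y_pred
  sse <- sum(res^2)
  sst <- sum((y_true - mean(y_true))^2)
  r2 <- if (sst == 0) {
    warning("zero variance in y_true: R^2 undefined", call. = FALSE)
    NA_real_
  } else 1 - sse / sst
  mse <- mean(res^2)
  structure(list(r2 = r2, mae = mean(abs(res)), mse = mse,
                 rmse = sqrt(mse), residuals = res),
            class = "vnqi_eval")
}

#' @export
print.vnqi_eval <- function(x, ...) {
  cat(sprintf("<vnqi_eval> R2 %.4f  MAE %.4f  MSE %.4f  RMSE %.4f  (n = %d)\n",
              x$r2, x$mae, x$mse, x$rmse, length(x$residuals)))
  invisible(x)
}

eval_row <- function(ev) {
  data.frame(r2 = ev$r2, mae = ev$mae, mse = ev$mse, rmse = ev$rmse)
}

#' Pearson correlation ranking of metrics and VNQI against measured oxygen
#'
#' @param records Data frame with the six metric columns, the target column
#'   and optionally a grouping column (>= 3 rows per correlation).
#' @param vnqi Numeric vector of VNQI scores aligned with `records`.
#' @param target `"oxy_t"` (default) or `"oxy_v"`: the measured oxygen
#'   variable to correlate against.
#' @param group Optional name of a grouping column for per-group tables.
#' @return Data frame with columns `variable` (six metrics then `"vnqi"`),
#'   `pearson_r`, and `group` when grouped. Constant variables give `NA`.
#' @export
pearson_ranking <- function(records, vnqi, target = "oxy_t", group = NULL) {
  target <- match.arg(target, c("oxy_t", "oxy_v"))
  if (nrow(records) < 3) stopf("need at least 3 records")
  if (length(vnqi) != nrow(records)) stopf("vnqi length mismatch")
  tab <- cbind(records[, c(metric_columns, target)], vnqi = vnqi)
  one_group <- function(d) {
    y <- d[[target]]
    r <- vapply(c(metric_columns, "vnqi"), function(v) {
      x <- d[[v]]
      if (sd(x) == 0 || sd(y) == 0) {
        warning(sprintf("constant column '%s': Pearson r undefined", v),
                call. = FALSE)
        return(NA_real_)
      }
      cor(x, y)
    }, numeric(1))
    data.frame(variable = c(metric_columns, "vnqi"), pearson_r = unname(r))
  }
  if (is.null(group)) return(one_group(tab))
  tab$group <- records[[group]]
  out <- lapply(split(tab, tab$group), one_group)
  res <- do.call(rbind, Map(function(g, d) cbind(group = g, d),
                            names(out), out))
  rownames(res) <- NULL
  res
}

#' Train and evaluate all five architectures on one shared split
#'
#' One seeded 80/20 split is shared by all architectures (chained plus the
#' four baselines); each is trained with the same seeded search protocol and
#' evaluated on the held-out test set. The multi-output network is scored on
#' its pooled OXY_V and OXY_T residuals; the OXY_V-augmented baseline sees
#' the oracle OXY_V of the test samples.
#'
#' @param records Sample table (metrics + `oxy_v` + `oxy_t`).
#' @param spec A [chain_spec()].
#' @param split_seed Seed of the shared train/test split.
#' @param train_frac Training fraction.
#' @return Data frame with one row per architecture: `architecture`,
#'   `input`, `target`, `r2`, `mae`, `mse`, `rmse`.
#' @export
compare_architectures <- function(records, spec = chain_spec(),
                                  split_seed = 1L, train_frac = 0.8) {
  sp <- split_dataset(records, train_frac, split_seed)
  train <- sp$train; test <- sp$test
  rows <- list()
  m <- fit_baseline(train, "multi_output", spec)
  p <- predict(m, test)
  ev <- evaluate_predictions(c(test$oxy_v, test$oxy_t),
                             c(p[, "oxy_v"], p[, "oxy_t"]))
  rows$multi <- cbind(data.frame(architecture = "multi_output",
                                 input = "morphology",
                                 target = "oxy_v+oxy_t"), eval_row(ev))
  m <- fit_baseline(train, "single_oxy_v", spec)
  ev <- evaluate_predictions(test$oxy_v, predict(m, test))
  rows$sv <- cbind(data.frame(architecture = "single_oxy_v",
                              input = "morphology", target = "oxy_v"),
                   eval_row(ev))
  m <- fit_baseline(train, "single_oxy_t", spec)
  ev <- evaluate_predictions(test$oxy_t, predict(m, test))
  rows$st <- cbind(data.frame(architecture = "single_oxy_t",
                              input = "morphology", target = "oxy_t"),
                   eval_row(ev))
  m <- fit_baseline(train, "oxy_t_with_true_oxy_v", spec)
  ev <- evaluate_predictions(test$oxy_t, predict(m, test))
  rows$aug <- cbind(data.frame(architecture = "oxy_t_with_true_oxy_v",
                               input = "morphology+oxy_v", target = "oxy_t"),
                    eval_row(ev))
  ch <- fit_chain(train, spec)
  ev <- evaluate_predictions(test$oxy_t, predict_vnqi(ch, test))
  rows$chain <- cbind(data.frame(architecture = "chained",
                                 input = "morphology", target = "oxy_t"),
                      eval_row(ev))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Repartitioning stability of the two chained networks
#'
#' Repeats split -> fit -> evaluate over `n_partitions` split seeds and
#' reports the mean and standard deviation of each accuracy metric for NN1
#' (OXY_V from morphology) and NN2 (OXY_T from morphology + true OXY_V,
#' i.e. teacher-forced, as trained).
#'
#' @param records Sample table.
#' @param spec A [chain_spec()]; each partition reuses its split seed as the
#'   training seed, so supplying identical seeds reproduces identical fits.
#' @param n_partitions Number of repartitionings (>= 2).
#' @param partition_seeds Optional integer vector overriding the derived
#'   seeds (length `n_partitions`).
#' @param train_frac Training fraction per partition.
#' @return Data frame: `network` x `metric` with `mean` and `sd` columns
#'   (2 networks x 4 metrics).
#' @export
stability_analysis <- function(records, spec = chain_spec(),
                               n_partitions = 10, partition_seeds = NULL,
                               train_frac = 0.8) {
  if (n_partitions < 2) stopf("need at least 2 partitions")
  if (is.null(partition_seeds))
    partition_seeds <- vapply(seq_len(n_partitions),
                              function(i) derive_seed(spec$rng_seed, 100 + i),
                              integer(1))
  if (length(partition_seeds) != n_partitions)
    stopf("partition_seeds must have length n_partitions")
  res <- list()
  for (i in seq_len(n_partitions)) {
    s <- partition_seeds[i]
    sp <- split_dataset(records, train_frac, s)
    spec_i <- spec; spec_i$rng_seed <- s
    ch <- fit_chain(sp$train, spec_i)
    ev1 <- evaluate_predictions(sp$test$oxy_v, predict_oxy_v(ch, sp$test))
    x2 <- cbind(apply_scaler(feature_matrix(sp$test), ch$scaler),
                oxy_v = (sp$test$oxy_v - ch$ov_center) / ch$ov_scale)
    ev2 <- evaluate_predictions(sp$test$oxy_t,
                                as.numeric(predict(ch$nn2, x2)))
    res[[i]] <- rbind(cbind(network = "nn1", eval_row(ev1)),
                      cbind(network = "nn2", eval_row(ev2)))
  }
  all <- do.call(rbind, res)
  metrics <- c("r2", "mae", "mse", "rmse")
  out <- do.call(rbind, lapply(c("nn1", "nn2"), function(nw) {
    d <- all[all$network == nw, ]
    do.call(rbind, lapply(metrics, function(m) {
      data.frame(network = nw, metric = m,
                 mean = mean(d[[m]]), sd = sd(d[[m]]))
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Learning curve of the chained model
#'
#' Splits once into a training pool and a fixed validation set, then for
#' each requested size fits the chain on a seeded subsample of the pool and
#' records the chained (VNQI vs OXY_T) mean absolute error on both sets.
#'
#' @param records Sample table.
#' @param spec A [chain_spec()].
#' @param sizes Training-set sizes to evaluate (each `<=` pool size).
#' @param seed Seed of the pool/validation split and of the subsampling.
#' @param train_frac Fraction of records forming the training pool.
#' @return Data frame with `size`, `train_mae`, `val_mae`.
#' @export
learning_curve <- function(records, spec = chain_spec(),
                           sizes = c(50, 100, 200, 300, 400),
                           seed = spec$rng_seed, train_frac = 0.8) {
  if (length(sizes) == 0) stopf("sizes must be non-empty")
  sp <- split_dataset(records, train_frac, seed)
  pool <- sp$train; val <- sp$test
  if (max(sizes) > nrow(pool))
    stopf("max(sizes) = %d exceeds training pool of %d", max(sizes), nrow(pool))
  out <- lapply(seq_along(sizes), function(i) {
    m <- sizes[i]
    sub_idx <- with_seed(derive_seed(seed, 200 + i),
                         sample.int(nrow(pool), m))
    sub <- pool[sub_idx, , drop = FALSE]
    spec_i <- spec; spec_i$rng_seed <- derive_seed(seed, 300 + i)
    ch <- fit_chain(sub, spec_i)
    data.frame(size = m,
               train_mae = mean(abs(sub$oxy_t - predict_vnqi(ch, sub))),
               val_mae = mean(abs(val$oxy_t - predict_vnqi(ch, val))))
  })
  do.call(rbind, out)
}
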