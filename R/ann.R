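#' Encode a kinetic dataset for neural-network regression
#'
#' Builds the design matrix used by the perceptron comparator: storage day
#' and temperature (z-scored) followed by one 0/1 indicator column per
#' treatment in the dataset's fixed treatment order (control first). For
#' the full 14-treatment design this gives the canonical 16 input columns.
#' The target is TBARS in percent of day 0.
#'
#' @param dataset A [kinetic_dataset()] on the percent scale.
#' @return A list of class `ann_features`: `x` (matrix), `y` (numeric
#'   target), `center`/`scale` (standardization of the two numeric
#'   columns), `treatments`.
#' @export
encode_features <- function(dataset) {
  stopifnot(inherits(dataset, "kinetic_dataset"))
  if (dataset$scale[1] != "percent") {
    stop("dataset must be on the percent scale", call. = FALSE)
  }
  trts <- treatments(dataset)
  if (!all(dataset$treatment %in% trts)) {
    stop("encoding error: unknown treatment label", call. = FALSE)
  }
  num <- cbind(day = dataset$day, temperature_c = dataset$temperature_c)
  center <- colMeans(num)
  scale_ <- apply(num, 2, sd)
  scale_[scale_ == 0] <- 1
  num_std <- sweep(sweep(num, 2, center), 2, scale_, "/")
  ind <- sapply(trts, function(tr) as.numeric(dataset$treatment == tr))
  colnames(ind) <- make.names(trts)
  structure(list(x = cbind(num_std, ind), y = dataset$tbars,
                 center = center, scale = scale_, treatments = trts),
            class = "ann_features")
}

#' Specify a multilayer-perceptron regressor
#'
#' One hidden layer; trained by a BFGS quasi-Newton minimization of the
#' sum-of-squares error with early stopping on a validation subset.
#'
#' @param n_hidden Hidden-layer size, 3 to 10.
#' @param hidden_activation `"tanh"`, `"exponential"` or `"logistic"`.
#' @param output_activation `"identity"` or `"exponential"`.
#' @param max_epochs Maximum BFGS iterations (default 200).
#' @param seed Integer seed controlling weight initialization and the data
#'   split.
#' @param error_function Only `"sum_of_squares"` is supported.
#' @return An object of class `ann_spec`.
#' @export
ann_spec <- function(n_hidden, hidden_activation = c("tanh", "exponential",
                                                     "logistic"),
                     output_activation = c("exponential", "identity"),
                     max_epochs = 200L, seed = 1L,
                     error_function = "sum_of_squares") {
  hidden_activation <- match.arg(hidden_activation)
  output_activation <- match.arg(output_activation)
  stopifnot(n_hidden >= 3L, n_hidden <= 10L,
            identical(error_function, "sum_of_squares"))
  structure(list(n_hidden = as.integer(n_hidden),
                 hidden_activation = hidden_activation,
                 output_activation = output_activation,
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed),
                 error_function = error_function),
            class = "ann_spec")
}

activation_fns <- list(
  tanh = list(f = tanh, df = function(h) 1 - h^2),
  logistic = list(f = function(z) 1 / (1 + exp(-z)),
                  df = function(h) h * (1 - h)),
  exponential = list(f = exp, df = function(h) h),
  identity = list(f = identity, df = function(h) rep(1, length(h)))
)

#' Split record indices into training/validation/test subsets
#'
#' Random (optionally stratified) assignment in the ratio 2:1:1, each
#' subset within one record of its exact share; reproducible given the
#' seed.
#'
#' @param n Number of records.
#' @param seed Integer seed.
#' @param strata Optional factor of length `n`; when given, the ratio is
#'   enforced within each stratum.
#' @return A character vector of length `n` with values `"train"`,
#'   `"valid"`, `"test"`.
#' @export
split_221 <- function(n, seed = 1L, strata = NULL) {
  assign_one <- function(m, perm) {
    n_train <- round(m / 2)
    n_valid <- round(m / 4)
    out <- character(m)
    out[perm[seq_len(n_train)]] <- "train"
    out[perm[n_train + seq_len(n_valid)]] <- "valid"
    out[perm[-(seq_len(n_train + n_valid))]] <- "test"
    out
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  if (is.null(strata)) return(assign_one(n, sample.int(n)))
  stopifnot(length(strata) == n)
  out <- character(n)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    out[idx] <- assign_one(length(idx), sample.int(length(idx)))
  }
  out
}

# forward pass + SOS loss and analytic gradient, on a flat parameter vector
mlp_unpack <- function(par, p, h) {
  list(W1 = matrix(par[seq_len(p * h)], p, h),
       b1 = par[p * h + seq_len(h)],
       w2 = par[p * h + h + seq_len(h)],
       b2 = par[p * h + 2 * h + 1])
}

mlp_forward <- function(par, x, spec) {
  w <- mlp_unpack(par, ncol(x), spec$n_hidden)
  act <- activation_fns[[spec$hidden_activation]]
  out <- activation_fns[[spec$output_activation]]
  z <- sweep(x %*% w$W1, 2, w$b1, "+")
  hmat <- act$f(z)
  u <- drop(hmat %*% w$w2) + w$b2
  list(yhat = out$f(u), hmat = hmat, u = u, w = w)
}

mlp_loss <- function(par, x, ys, spec) {
  fw <- mlp_forward(par, x, spec)
  sum((fw$yhat - ys)^2)
}

mlp_grad <- function(par, x, ys, spec) {
  fw <- mlp_forward(par, x, spec)
  act <- activation_fns[[spec$hidden_activation]]
  out <- activation_fns[[spec$output_activation]]
  d <- 2 * (fw$yhat - ys) * out$df(fw$yhat)
  dW2 <- drop(crossprod(fw$hmat, d))
  db2 <- sum(d)
  dH <- outer(d, fw$w$w2)
  dZ <- dH * act$df(fw$hmat)
  dW1 <- crossprod(x, dZ)
  db1 <- colSums(dZ)
  c(as.vector(dW1), db1, dW2, db2)
}

#' Train a perceptron regressor
#'
#' Minimizes the sum-of-squares error by BFGS ([stats::optim()]), in
#' rounds of `check_every` iterations with early stopping: training halts
#' when the validation-subset error has failed to improve for `patience`
#' consecutive rounds, and the weights with the best validation error are
#' kept. Targets are scaled internally (z-scored for identity output;
#' divided by their mean for exponential output, the network modelling the
#' log of that ratio); all reported metrics are on the original percent
#' scale. Deterministic given the spec's seed.
#'
#' @param spec An [ann_spec()].
#' @param features An [encode_features()] result; at least 40 records.
#' @param split Optional subset assignment from [split_221()]; default is a
#'   random 2:1:1 split drawn with the spec's seed.
#' @param check_every,patience Early-stopping cadence (iterations per
#'   validation check) and tolerance (checks without improvement).
#' @return An object of class `ann_fit`: the spec, trained weights, split,
#'   per-subset Pearson `performance` and sum-of-squares `error`, total
#'   BFGS iterations run, and full-data `r2` and `rmse`.
#' @export
train_mlp <- function(spec, features, split = NULL, check_every = 50L,
                      patience = 3L) {
  stopifnot(inherits(spec, "ann_spec"), inherits(features, "ann_features"))
  x <- features$x
  y <- features$y
  if (nrow(x) < 40L) stop("need at least 40 records", call. = FALSE)
  if (is.null(split)) split <- split_221(nrow(x), seed = spec$seed)
  if (!all(c("train", "valid", "test") %in% split)) {
    stop("degenerate split: empty subset", call. = FALSE)
  }

  # internal target scaling (see Details)
  if (spec$output_activation == "identity") {
    mu <- mean(y[split == "train"]); sdy <- sd(y[split == "train"])
    if (sdy == 0) sdy <- 1
    ys <- (y - mu) / sdy
    unscale <- function(v) mu + sdy * v
  } else {
    mu <- mean(y[split == "train"])
    ys <- y / mu
    unscale <- function(v) mu * v
  }

  p <- ncol(x); h <- spec$n_hidden
  n_par <- p * h + h + h + 1L
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(spec$seed)
  par <- runif(n_par, -0.5, 0.5) / sqrt(p)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())

  xtr <- x[split == "train", , drop = FALSE]
  ytr <- ys[split == "train"]
  xva <- x[split == "valid", , drop = FALSE]
  yva <- ys[split == "valid"]

  best_par <- par
  best_val <- mlp_loss(par, xva, yva, spec)
  stale <- 0L
  iters <- 0L
  while (iters < spec$max_epochs && stale <= patience) {
    res <- tryCatch(
      optim(par, mlp_loss, mlp_grad, x = xtr, ys = ytr, spec = spec,
            method = "BFGS",
            control = list(maxit = min(check_every,
                                       spec$max_epochs - iters))),
      error = function(e) e)
    if (inherits(res, "error") || !all(is.finite(res$par))) {
      stop("training failure: non-finite loss", call. = FALSE)
    }
    par <- res$par
    iters <- iters + min(check_every, spec$max_epochs - iters)
    val <- mlp_loss(par, xva, yva, spec)
    if (is.finite(val) && val < best_val - 1e-12) {
      best_val <- val
      best_par <- par
      stale <- 0L
    } else {
      stale <- stale + 1L
    }
    if (res$convergence == 0 && stale == 0L) break  # converged on train
  }
  par <- best_par

  yhat <- unscale(mlp_forward(par, x, spec)$yhat)
  subset_metric <- function(which) {
    idx <- split == which
    c(performance = if (sd(yhat[idx]) > 0 && sd(y[idx]) > 0)
        cor(y[idx], yhat[idx]) else 0,
      error = sum((y[idx] - yhat[idx])^2))
  }
  mets <- sapply(c("train", "valid", "test"), subset_metric)
  sst <- sum((y - mean(y))^2)
  structure(list(
    spec = spec,
    weights = par,
    split = split,
    performance = mets["performance", ],
    error = mets["error", ],
    n_iterations = iters,
    r2 = 1 - sum((y - yhat)^2) / sst,
    rmse = sqrt(mean((y - yhat)^2)),
    features = features
  ), class = "ann_fit")
}

#' @export
print.ann_fit <- function(x, ...) {
  cat(sprintf("<ann_fit> MLP %d-%d-1 (%s/%s): R2 = %.4f, RMSE = %.2f, val error = %.1f\n",
              ncol(x$features$x), x$spec$n_hidden, x$spec$hidden_activation,
              x$spec$output_activation, x$r2, x$rmse, x$error[["valid"]]))
  invisible(x)
}

#' Predict from a trained perceptron
#'
#' @param object An `ann_fit`.
#' @param newdata Optional [kinetic_dataset()]; default is the training
#'   dataset's own features.
#' @param ... Unused.
#' @return Predicted TBARS (percent of day 0).
#' @export
predict.ann_fit <- function(object, newdata = NULL, ...) {
  ft <- object$features
  if (is.null(newdata)) {
    x <- ft$x
  } else {
    num <- cbind(day = newdata$day, temperature_c = newdata$temperature_c)
    num_std <- sweep(sweep(num, 2, ft$center), 2, ft$scale, "/")
    ind <- sapply(ft$treatments,
                  function(tr) as.numeric(newdata$treatment == tr))
    x <- cbind(num_std, ind)
  }
  y <- ft$y[object$split == "train"]
  raw <- mlp_forward(object$weights, x, object$spec)$yhat
  if (object$spec$output_activation == "identity") {
    mean(y) + sd(y) * raw
  } else {
    mean(y) * raw
  }
}

#' Train a grid of perceptrons and keep the best few
#'
#' Trains every spec on a shared data split, ranks by validation-subset
#' error (ascending) and returns the top `n_keep`. Individual training
#' failures are recorded and excluded rather than aborting the scan.
#'
#' @param specs List of [ann_spec()]s.
#' @param features An [encode_features()] result.
#' @param n_keep Number of networks to retain (<= length(specs)).
#' @param split_seed Seed for the shared 2:1:1 split.
#' @return A list of class `ann_selection`: `fits` (ranked `ann_fit`s),
#'   `failures` (data frame of spec index + message).
#' @export
select_best_networks <- function(specs, features, n_keep = 5L,
                                 split_seed = 1L) {
  stopifnot(n_keep <= length(specs))
  split <- split_221(nrow(features$x), seed = split_seed)
  fits <- list()
  fails <- list()
  for (i in seq_along(specs)) {
    f <- tryCatch(train_mlp(specs[[i]], features, split = split),
                  error = function(e) e)
    if (inherits(f, "error")) {
      fails[[length(fails) + 1L]] <-
        data.frame(spec = i, message = conditionMessage(f))
    } else {
      fits[[length(fits) + 1L]] <- f
    }
  }
  val_err <- vapply(fits, function(f) f$error[["valid"]], numeric(1))
  # stable sort: ties broken by original order
  fits <- fits[order(val_err)]
  structure(list(fits = fits[seq_len(min(n_keep, length(fits)))],
                 failures = if (length(fails)) do.call(rbind, fails)
                            else data.frame()),
            class = "ann_selection")
}

#' Default 20-network scan grid
#'
#' Hidden sizes 3 to 10 crossed with tanh/exponential hidden and
#' exponential/identity output activations, truncated to 20 specs with
#' distinct seeds derived from `seed`.
#'
#' @param seed Base seed.
#' @param max_epochs Passed to each [ann_spec()].
#' @return A list of 20 `ann_spec`s.
#' @export
default_ann_grid <- function(seed = 1L, max_epochs = 200L) {
  grid <- expand.grid(n_hidden = 3:10,
                      hidden_activation = c("tanh", "exponential"),
                      output_activation = c("exponential", "identity"),
                      stringsAsFactors = FALSE)
  grid <- grid[seq_len(20L), ]
  lapply(seq_len(nrow(grid)), function(i) {
    ann_spec(grid$n_hidden[i], grid$hidden_activation[i],
             grid$output_activation[i], max_epochs = max_epochs,
             seed = seed + i)
  })
}

#' Summarize a network selection as a table
#'
#' One column per retained network: structure label, per-subset Pearson
#' performance and sum-of-squares error, training algorithm, activations,
#' full-data R2 and RMSE.
#'
#' @param selection An `ann_selection` from [select_best_networks()].
#' @return A data frame, one row per network.
#' @export
ann_table <- function(selection) {
  stopifnot(inherits(selection, "ann_selection"))
  do.call(rbind, c(lapply(selection$fits, function(f) {
    data.frame(
      structure = sprintf("MLP %d-%d-1", ncol(f$features$x),
                          f$spec$n_hidden),
      training_performance = f$performance[["train"]],
      test_performance = f$performance[["test"]],
      validation_performance = f$performance[["valid"]],
      training_error = f$error[["train"]],
      test_error = f$error[["test"]],
      validation_error = f$error[["valid"]],
      training_algorithm = sprintf("BFGS %d", f$n_iterations),
      error_function = "SOS",
      hidden_activation = f$spec$hidden_activation,
      output_activation = f$spec$output_activation,
      r2 = f$r2,
      rmse = f$rmse,
      stringsAsFactors = FALSE)
  }), make.row.names = FALSE))
}
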