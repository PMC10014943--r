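#' Build classifier features from metrics records
#'
#' The classifier consumes four metrics per cell: mean instantaneous speed,
#' mean alpha-value, directionality ratio and event count. Speed units
#' differ between experimental recordings (um/h) and lattice simulations
#' (lattice units per step), so speed is z-scored across the pooled input;
#' the other three metrics are shared-unit and passed through unchanged.
#' The normalization constants are returned so that a model trained on one
#' table can be applied to another.
#'
#' @param records data frame with columns `mean_speed`, `mean_alpha`, `dr`,
#'   `n_events`.
#' @param center,scale optional precomputed speed normalization (from a
#'   trained model); by default computed from `records`.
#' @return list with `features` (numeric matrix, 4 columns) and the speed
#'   `center` and `scale`.
#' @export
build_features <- function(records, center = NULL, scale = NULL) {
  need <- c("mean_speed", "mean_alpha", "dr", "n_events")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing metric column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  bad <- which(!stats::complete.cases(records[need]))
  if (length(bad)) stop("missing metric value(s) for record(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (is.null(center) || is.null(scale)) {
    if (nrow(records) < 2) {
      stop("speed normalization needs >= 2 records", call. = FALSE)
    }
    center <- mean(records$mean_speed)
    scale <- stats::sd(records$mean_speed)
    if (scale == 0) scale <- 1  # zero-spread guard: all normalized speeds 0
  }
  f <- cbind(speed_z = (records$mean_speed - center) / scale,
             mean_alpha = records$mean_alpha,
             dr = records$dr,
             n_events = as.numeric(records$n_events))
  list(features = f, center = center, scale = scale)
}

# ---- minimal fully-connected ReLU network, batch quasi-Newton training ----
# Architecture: length(hidden) hidden ReLU layers plus a softmax output
# layer (four fully-connected layers with the default of three hidden
# layers). Trained by BFGS on the cross-entropy with L2 penalty `reg`.

mlp_shapes <- function(n_in, hidden, n_out) {
  sizes <- c(n_in, hidden, n_out)
  lapply(seq_len(length(sizes) - 1), function(i) c(sizes[i] + 1, sizes[i + 1]))
}

mlp_unflatten <- function(theta, shapes) {
  out <- list(); pos <- 0
  for (s in shapes) {
    k <- s[1] * s[2]
    out[[length(out) + 1]] <- matrix(theta[pos + seq_len(k)], s[1], s[2])
    pos <- pos + k
  }
  out
}

mlp_forward <- function(W, X) {
  acts <- list(X)
  A <- X
  L <- length(W)
  for (l in seq_len(L)) {
    Z <- cbind(1, A) %*% W[[l]]
    A <- if (l < L) pmax(Z, 0) else Z
    acts[[l + 1]] <- A
  }
  # softmax with row-wise shift
  Z <- acts[[L + 1]]
  Z <- Z - apply(Z, 1, max)
  P <- exp(Z); P <- P / rowSums(P)
  list(P = P, acts = acts)
}

mlp_loss_grad <- function(theta, shapes, X, Yind, reg) {
  W <- mlp_unflatten(theta, shapes)
  L <- length(W)
  fw <- mlp_forward(W, X)
  P <- fw$P; acts <- fw$acts
  n <- nrow(X)
  loss <- -sum(log(pmax(P[Yind], 1e-12))) / n +
    reg * sum(vapply(W, function(w) sum(w^2), numeric(1)))
  delta <- P
  delta[Yind] <- delta[Yind] - 1
  delta <- delta / n
  grads <- vector("list", L)
  for (l in L:1) {
    A <- acts[[l]]
    grads[[l]] <- crossprod(cbind(1, A), delta) + 2 * reg * W[[l]]
    if (l > 1) {
      delta <- (delta %*% t(W[[l]][-1, , drop = FALSE])) * (acts[[l]] > 0)
    }
  }
  list(loss = loss, grad = unlist(grads))
}

#' Train the migration-phenotype classifier
#'
#' A small fully-connected neural network (rectified-linear hidden layers,
#' softmax output) mapping the four track metrics to condition labels
#' (typically WT / S273A / S273D). Trained as a single batch with a
#' quasi-Newton optimizer (BFGS) on the cross-entropy with an L2 penalty;
#' training is deterministic under `seed`.
#'
#' @param records metrics data frame (see [build_features()]).
#' @param labels factor or character vector of condition labels.
#' @param hidden hidden-layer widths; the default `c(16, 16, 16)` gives
#'   four fully-connected layers in total.
#' @param reg L2 regularization strength.
#' @param maxit maximum BFGS iterations.
#' @param seed random seed for weight initialization.
#' @return a `racpax_classifier` (weights, layer sizes, label set, speed
#'   normalization, training diagnostics).
#' @export
train_classifier <- function(records, labels, hidden = c(16, 16, 16),
                             reg = 1e-5, maxit = 1000, seed = 1) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need >= 2 classes", call. = FALSE)
  if (length(labels) != nrow(records)) {
    stop("labels and records lengths differ", call. = FALSE)
  }
  bf <- build_features(records)
  X <- bf$features
  n_out <- nlevels(labels)
  shapes <- mlp_shapes(ncol(X), hidden, n_out)
  set.seed(seed)
  theta0 <- unlist(lapply(shapes, function(s) {
    stats::rnorm(s[1] * s[2], 0, sqrt(2 / s[1]))
  }))
  Yind <- cbind(seq_along(labels), as.integer(labels))
  fn <- function(th) mlp_loss_grad(th, shapes, X, Yind, reg)$loss
  gr <- function(th) mlp_loss_grad(th, shapes, X, Yind, reg)$grad
  opt <- stats::optim(theta0, fn, gr, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-10))
  if (opt$convergence != 0) {
    warning("optimizer did not report convergence (code ", opt$convergence,
            "); model returned anyway")
  }
  structure(list(weights = mlp_unflatten(opt$par, shapes), shapes = shapes,
                 hidden = hidden, labels = levels(labels),
                 center = bf$center, scale = bf$scale, reg = reg, seed = seed,
                 solver = "BFGS (batch quasi-Newton)",
                 final_loss = opt$value, converged = opt$convergence == 0),
            class = "racpax_classifier")
}

#' @export
print.racpax_classifier <- function(x, ...) {
  cat(sprintf("fully-connected ReLU classifier: 4 -> %s -> %d (%s)\n",
              paste(x$hidden, collapse = " -> "), length(x$labels),
              paste(x$labels, collapse = "/")))
  cat(sprintf("  solver %s, L2 %.1e, final loss %.4g\n",
              x$solver, x$reg, x$final_loss))
  invisible(x)
}

#' Predict condition labels from track metrics
#'
#' @param object a `racpax_classifier`.
#' @param records metrics data frame (see [build_features()]); speed is
#'   normalized with the constants stored in the model.
#' @param ... unused.
#' @return factor of predicted labels with a `summary` attribute
#'   (counts per predicted label).
#' @export
predict.racpax_classifier <- function(object, records, ...) {
  if (nrow(records) == 0) {
    return(factor(character(), levels = object$labels))
  }
  X <- build_features(records, center = object$center,
                      scale = object$scale)$features
  if (ncol(X) + 1 != object$shapes[[1]][1]) {
    stop("feature dimension mismatch", call. = FALSE)
  }
  P <- mlp_forward(object$weights, X)$P
  pred <- factor(object$labels[max.col(P)], levels = object$labels)
  attr(pred, "summary") <- table(predicted = pred)
  pred
}

#' Persist a trained classifier as structured text
#'
#' Writes layer sizes, weights, label order and normalization constants to
#' a YAML file readable by [load_classifier()].
#'
#' @param model a `racpax_classifier`.
#' @param file output path.
#' @export
save_classifier <- function(model, file) {
  yaml::write_yaml(list(
    hidden = model$hidden, labels = model$labels,
    center = model$center, scale = model$scale, reg = model$reg,
    seed = model$seed, solver = model$solver,
    weights = lapply(model$weights, function(w) {
      list(nrow = nrow(w), ncol = ncol(w), data = as.numeric(w))
    })
  ), file, precision = 15)
  invisible(file)
}

#' @rdname save_classifier
#' @param file path to a YAML file written by [save_classifier()].
#' @export
load_classifier <- function(file) {
  d <- yaml::read_yaml(file)
  W <- lapply(d$weights, function(w) matrix(w$data, w$nrow, w$ncol))
  shapes <- lapply(W, dim)
  structure(list(weights = W, shapes = shapes, hidden = unlist(d$hidden),
                 labels = unlist(d$labels), center = d$center,
                 scale = d$scale, reg = d$reg, seed = d$seed,
                 solver = d$solver, final_loss = NA, converged = NA),
            class = "racpax_classifier")
}
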