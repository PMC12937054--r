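#' Training configuration for the EIC profile classifier
#'
#' Mirrors the standard training protocol: mini-batches of 64, 30% of the
#' training data reserved for a stratified validation split, validation
#' evaluated every 30 iterations, and early stopping after five
#' consecutive validation checks without improvement ("improvement" means
#' validation loss strictly below the best seen). The checkpoint with the
#' best validation loss — not the last — is returned.
#'
#' @param batch_size mini-batch size.
#' @param validation_fraction fraction of the data held out for
#'   validation, in (0, 1).
#' @param validation_interval iterations (mini-batches) between validation
#'   checks.
#' @param patience consecutive non-improving checks before stopping.
#' @param max_epochs upper bound on passes over the training split.
#' @param seed RNG seed fixing the split, initialisation and batch order.
#' @param hidden_units width of the hidden layer.
#' @param learning_rate,momentum SGD hyper-parameters.
#' @param class_weights optional named per-class loss weights (default
#'   none: the usual training sets are near-balanced).
#' @param downsample side of the block-averaged input grid fed to the
#'   network (pixels).
#' @return classed list `train_config`.
#' @export
train_config <- function(batch_size = 64L, validation_fraction = 0.30,
                         validation_interval = 30L, patience = 5L,
                         max_epochs = 60L, seed = 1L, hidden_units = 32L,
                         learning_rate = 0.1, momentum = 0.9,
                         class_weights = NULL, downsample = 28L) {
  stopifnot(validation_fraction > 0, validation_fraction < 1, patience >= 1L,
            batch_size >= 1L, validation_interval >= 1L, max_epochs >= 1L,
            hidden_units >= 1L, learning_rate > 0)
  structure(list(batch_size = as.integer(batch_size),
                 validation_fraction = validation_fraction,
                 validation_interval = as.integer(validation_interval),
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs), seed = as.integer(seed),
                 hidden_units = as.integer(hidden_units),
                 learning_rate = learning_rate, momentum = momentum,
                 class_weights = class_weights,
                 downsample = as.integer(downsample)),
            class = "train_config")
}

.eic_classes <- c("high_sn", "low_sn", "background")

# block-average an eic_image to a d x d grid of ink density, flattened
.image_features <- function(img, d) {
  g <- 1 - img[, , 1L]                       # ink = 1 - grayscale
  s <- nrow(g)
  if (s %% d != 0L) stop("image side must be a multiple of the downsample grid")
  b <- s %/% d
  # average b x b blocks via two rowsum passes
  gi <- rep(seq_len(d), each = b)
  m <- rowsum(g, gi, reorder = TRUE)                 # d x s
  m <- t(rowsum(t(m), gi, reorder = TRUE)) / (b * b) # d x d
  as.numeric(m)
}

.softmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

.forward <- function(w, X) {
  H <- tanh(sweep(X %*% w$W1, 2L, w$b1, `+`))
  P <- .softmax(sweep(H %*% w$W2, 2L, w$b2, `+`))
  list(H = H, P = P)
}

.xent <- function(P, y, wts) {
  p <- pmax(P[cbind(seq_along(y), y)], 1e-12)
  sum(-log(p) * wts[y]) / sum(wts[y])
}

#' Train the EIC profile classifier
#'
#' Fits the reference profile classifier — a compact feed-forward network
#' (one tanh hidden layer over a block-downsampled render, softmax output)
#' trained by seeded mini-batch SGD with momentum — under the protocol in
#' [train_config()]: stratified validation split, periodic validation
#' checks, early stopping, best-checkpoint return. The three profile
#' classes are high S/N and low S/N endogenous species and background.
#' The architecture is pluggable: any object with a compatible `predict`
#' method and matching `renderer_version` can stand in downstream; this
#' implementation is sized to train on one CPU in well under the
#' customary desk budget at a few hundred images per class.
#'
#' @param images list of `eic_image` from [render_eic_image()], all from
#'   the same renderer version.
#' @param labels character/factor of per-image classes, subset of
#'   `c("high_sn", "low_sn", "background")`; at least two classes must be
#'   present.
#' @param cfg a [train_config()].
#' @return object of class `eic_classifier`: weights at the best
#'   validation checkpoint, `classes`, `renderer_version`, the full
#'   training `log` (one row per validation check), `best_check`, and the
#'   held-in validation indices. Plain R data — serialise with
#'   `saveRDS()`.
#' @export
train_eic_classifier <- function(images, labels, cfg = train_config()) {
  stopifnot(length(images) == length(labels), length(images) >= 4L)
  labels <- as.character(labels)
  if (!all(labels %in% .eic_classes))
    stop("labels must be in {", paste(.eic_classes, collapse = ", "), "}")
  classes <- .eic_classes[.eic_classes %in% unique(labels)]
  if (length(classes) < 2L) stop("need at least two classes to train")
  rv <- unique(vapply(images, function(i) attr(i, "renderer_version"), character(1)))
  if (length(rv) != 1L) stop("images from mixed renderer versions")
  X <- t(vapply(images, .image_features, numeric(cfg$downsample^2),
                d = cfg$downsample))
  y <- match(labels, classes)
  K <- length(classes)
  wts <- rep(1, K)
  if (!is.null(cfg$class_weights)) {
    stopifnot(all(classes %in% names(cfg$class_weights)))
    wts <- unname(cfg$class_weights[classes])
  }

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(cfg$seed)

  # stratified validation split
  val <- unlist(lapply(seq_len(K), function(k) {
    idx <- which(y == k)
    nv <- max(1L, floor(length(idx) * cfg$validation_fraction))
    sample(idx, nv)
  }), use.names = FALSE)
  tr <- setdiff(seq_along(y), val)
  if (!length(tr)) stop("validation split leaves no training data")
  Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
  Xv <- X[val, , drop = FALSE]; yv <- y[val]

  d <- ncol(X); h <- cfg$hidden_units
  w <- list(W1 = matrix(stats::rnorm(d * h, 0, sqrt(1 / d)), d, h),
            b1 = numeric(h),
            W2 = matrix(stats::rnorm(h * K, 0, sqrt(1 / h)), h, K),
            b2 = numeric(K))
  vel <- lapply(w, function(p) p * 0)
  best <- list(loss = Inf, w = w, check = 0L)
  misses <- 0L
  it <- 0L
  log_rows <- list()
  run_loss <- 0; run_n <- 0L
  stopped <- FALSE

  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample(length(ytr))
    starts <- seq(1L, length(ord), by = cfg$batch_size)
    for (s in starts) {
      bi <- ord[s:min(s + cfg$batch_size - 1L, length(ord))]
      Xb <- Xtr[bi, , drop = FALSE]; yb <- ytr[bi]
      fw <- .forward(w, Xb)
      run_loss <- run_loss + .xent(fw$P, yb, wts); run_n <- run_n + 1L
      # backprop of weighted cross-entropy
      n <- length(yb)
      G <- fw$P
      G[cbind(seq_len(n), yb)] <- G[cbind(seq_len(n), yb)] - 1
      G <- G * (wts[yb] / sum(wts[yb]))
      gW2 <- crossprod(fw$H, G); gb2 <- colSums(G)
      GH <- (G %*% t(w$W2)) * (1 - fw$H^2)
      gW1 <- crossprod(Xb, GH); gb1 <- colSums(GH)
      gr <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
      for (p in names(w)) {
        vel[[p]] <- cfg$momentum * vel[[p]] - cfg$learning_rate * gr[[p]]
        w[[p]] <- w[[p]] + vel[[p]]
      }
      it <- it + 1L
      if (it %% cfg$validation_interval == 0L) {
        fv <- .forward(w, Xv)
        vloss <- .xent(fv$P, yv, wts)
        if (!is.finite(vloss)) stop("non-finite validation loss at iteration ", it)
        vacc <- mean(max.col(fv$P, ties.method = "first") == yv)
        chk <- length(log_rows) + 1L
        log_rows[[chk]] <- data.frame(
          check = chk, iteration = it, epoch = epoch,
          train_loss = run_loss / max(run_n, 1L),
          val_loss = vloss, val_acc = vacc)
        run_loss <- 0; run_n <- 0L
        if (vloss < best$loss) {
          best <- list(loss = vloss, w = w, check = chk)
          misses <- 0L
        } else {
          misses <- misses + 1L
          if (misses >= cfg$patience) { stopped <- TRUE; break }
        }
      }
    }
    if (stopped) break
  }
  log <- do.call(rbind, log_rows)
  structure(list(W1 = best$w$W1, b1 = best$w$b1, W2 = best$w$W2,
                 b2 = best$w$b2, classes = classes,
                 class_counts = table(factor(labels, levels = classes)),
                 renderer_version = rv, downsample = cfg$downsample,
                 cfg = cfg, log = log, best_check = best$check,
                 early_stopped = stopped, val_idx = sort(val)),
            class = "eic_classifier")
}

#' @export
print.eic_classifier <- function(x, ...) {
  cat(sprintf("<eic_classifier> %s; %d-px input grid, %d hidden units\n",
              paste(x$classes, collapse = "/"), x$downsample,
              ncol(x$W1)))
  cat(sprintf("  renderer %s; %d validation checks, best at check %d (val loss %.4f)%s\n",
              x$renderer_version, nrow(x$log), x$best_check,
              min(x$log$val_loss),
              if (x$early_stopped) ", early-stopped" else ""))
  invisible(x)
}

#' @rdname classify_eics
#' @param object an `eic_classifier`.
#' @param type `"class"` or `"prob"`.
#' @param ... unused.
#' @export
predict.eic_classifier <- function(object, images, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  rv <- vapply(images, function(i) {
    v <- attr(i, "renderer_version")
    if (is.null(v)) NA_character_ else v
  }, character(1))
  if (any(is.na(rv)) || any(rv != object$renderer_version))
    stop("renderer version mismatch: model expects ", object$renderer_version)
  X <- t(vapply(images, .image_features, numeric(object$downsample^2),
                d = object$downsample))
  P <- .forward(object, X)$P
  colnames(P) <- object$classes
  if (type == "prob") return(P)
  apply(P, 1L, function(p) {
    top <- which(p == max(p))
    if (length(top) > 1L) {
      # conservative tie-break: background, then low_sn, then high_sn
      pref <- match(c("background", "low_sn", "high_sn"), object$classes)
      top <- top[order(match(top, pref))]
    }
    object$classes[top[1L]]
  })
}

#' Classify EIC images into species classes
#'
#' Runs the classifier over rendered profiles and reports the three-class
#' scores, the argmax class (exact ties broken toward background —
#' conservative, since flagged species can be rescued in review), and the
#' derived binary label: high- and low-S/N map to `endogenous`,
#' background stays `background`.
#'
#' @param model an `eic_classifier`.
#' @param images list of `eic_image` rendered with the model's renderer
#'   version.
#' @param feature_ids optional identifiers (default: the images'
#'   `mz_center` attributes, else indices).
#' @return data.frame of class `eic_predictions`: `feature`, one
#'   `score_*` column per class, `class`, `binary`.
#' @export
classify_eics <- function(model, images, feature_ids = NULL) {
  P <- predict(model, images, type = "prob")
  cls <- predict(model, images, type = "class")
  if (is.null(feature_ids)) {
    feature_ids <- vapply(seq_along(images), function(i) {
      m <- attr(images[[i]], "mz_center")
      if (is.null(m)) NA_real_ else m
    }, double(1))
    if (anyNA(feature_ids)) feature_ids <- seq_along(images)
  }
  out <- data.frame(feature = feature_ids)
  for (k in seq_along(model$classes))
    out[[paste0("score_", model$classes[k])]] <- P[, k]
  out$class <- cls
  out$predicted_class <- cls
  out$overridden <- FALSE
  out$binary <- ifelse(cls %in% c("high_sn", "low_sn"), "endogenous", "background")
  class(out) <- c("eic_predictions", "data.frame")
  out
}

#' Apply manual review overrides to classifier predictions
#'
#' Replaces predicted classes for the named features, keeping provenance:
#' `predicted_class` always holds the model's call, `class` the final one,
#' and `overridden` marks edited rows. Applying the same overrides twice
#' is a no-op. The binary label is rederived.
#'
#' @param predictions an `eic_predictions` data.frame.
#' @param overrides data.frame with columns `feature` and `class`.
#' @return corrected `eic_predictions`.
#' @export
review_overrides <- function(predictions, overrides) {
  stopifnot(inherits(predictions, "eic_predictions"))
  if (is.null(overrides) || !nrow(overrides)) return(predictions)
  stopifnot(all(c("feature", "class") %in% names(overrides)),
            all(overrides$class %in% .eic_classes))
  idx <- match(overrides$feature, predictions$feature)
  if (anyNA(idx)) stop("unknown feature in overrides: ",
                       overrides$feature[is.na(idx)][1L])
  predictions$class[idx] <- overrides$class
  predictions$overridden[idx] <- TRUE
  predictions$binary <- ifelse(predictions$class %in% c("high_sn", "low_sn"),
                               "endogenous", "background")
  predictions
}
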