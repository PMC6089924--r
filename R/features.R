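#' Compute the 16 guide-wire event features
#'
#' Quantifies a segmented event by 16 features over three groups, computed
#' from the TV-MEP `P_m(n)`, the frequency-averaged TV-AR spectrum
#' `S_f(n)` and the plateau intervals:
#'
#' * Overshoot (F1-F6): `F1 = (OS_H / OS_W) * sum(P_m over overshoot) /
#'   sum(P_m over event)` (0 when no overshoot is present); `F2 = max P_m`;
#'   `F3 = max(P_m * S_f)`; `F4 = F2 / sum(P_m)`; `F5 = F3 / sum(P_m * S_f)`;
#'   `F6 = F3 / ((1/(t_off - t_on)) * sum(P_m * S_f))`, all over the event.
#' * Plateau (F7-F14): `F7 = Var(PL1) / Length(PL1)`; `F8`, `F9` are the
#'   peak counts of the MEP derivative over the event and over
#'   `[t_on, t_on + delta]`; `F10 = Length(PL1) / (t_off - t_on)`;
#'   `F11 = Length(PL1) / Std(PL1)`; `F12 = Length(PL2) / (t_off - t_on)`;
#'   `F13 = Length(PL2)`; `F14 = Length(PL3)`. Lengths are in seconds;
#'   `Var`/`Std` act on the MEP values inside the plateau. Peaks are local
#'   maxima of the derivative with prominence at least its MAD.
#' * Spectrum (F15-F16): mean off-diagonal inter-window Pearson correlation
#'   of the TV-AR spectrum columns over the event and over the
#'   maximal-energy sub-interval; both are invariant to global rescaling of
#'   the spectrum.
#'
#' @param mep an [mep_track()].
#' @param spec a [tvar_spectrum()] whose window grid covers the event (it may
#'   be restricted to the event span; windows are matched to the MEP grid by
#'   their center times).
#' @param seg an [event_segment()].
#' @param os a [detect_overshoot()] result.
#' @param pl a [detect_plateaus()] result.
#' @return a named numeric vector of class `aemid_features` (`F1` ... `F16`).
#' @export
compute_features <- function(mep, spec, seg, os, pl) {
  stopifnot(inherits(mep, "mep_track"), inherits(spec, "tv_spectrum"),
            inherits(seg, "event_segment"))
  ev <- which(mep$times >= seg$t_on & mep$times <= seg$t_off)
  dl <- which(mep$times >= seg$t_on & mep$times <= seg$t_on + seg$delta)
  if (length(ev) < 2)
    stop("degenerate event segment: fewer than two analysis windows",
         call. = FALSE)
  # match event windows of the MEP grid to spectrum columns by center time
  spec_col <- function(ix) {
    j <- vapply(mep$times[ix],
                function(t) which.min(abs(spec$times - t)), 0L)
    if (any(abs(spec$times[j] - mep$times[ix]) > mep$hop_s / 2))
      stop("spectrum does not cover the event windows", call. = FALSE)
    j
  }
  ev_s <- spec_col(ev)
  dl_s <- spec_col(dl)
  dur <- seg$t_off - seg$t_on
  Pm <- mep$values
  Sf_ev <- spec$mean_over_f[ev_s]
  PS_ev <- Pm[ev] * Sf_ev

  if (isTRUE(os$present)) {
    osw <- which(mep$times >= os$OS_on & mep$times <= os$OS_off)
    F1 <- (os$OS_H / os$OS_W) * sum(Pm[osw]) / sum(Pm[ev])
  } else F1 <- 0
  F2 <- max(Pm[ev])
  F3 <- max(PS_ev)
  F4 <- F2 / sum(Pm[ev])
  F5 <- F3 / sum(PS_ev)
  F6 <- F3 / (sum(PS_ev) / dur)

  plateau_len <- function(ix) if (length(ix)) (length(ix) - 1) * mep$hop_s else 0
  L1 <- plateau_len(pl$PL1); L2 <- plateau_len(pl$PL2); L3 <- plateau_len(pl$PL3)
  F7 <- if (L1 > 0) var(Pm[pl$PL1]) / L1 else 0

  count_peaks <- function(ix) {
    if (length(ix) < 3) return(0L)
    d <- diff(Pm[ix]) / mep$hop_s
    if (length(d) < 3) return(0L)
    pk <- local_maxima(d)
    if (!length(pk)) return(0L)
    tol <- mad(d)
    if (tol <= 0) return(length(pk))
    sum(vapply(pk, function(i) peak_prominence(d, i), 0) >= tol)
  }
  F8 <- count_peaks(ev)
  F9 <- count_peaks(dl)
  F10 <- L1 / dur
  F11 <- if (L1 > 0) {
    s1 <- sd(Pm[pl$PL1])
    L1 / max(s1, 1e-9)
  } else 0
  F12 <- L2 / dur
  F13 <- L2
  F14 <- L3

  mean_offdiag_cor <- function(cols) {
    if (length(cols) < 2) return(NA_real_)
    C <- suppressWarnings(cor(spec$S[, cols]))
    C[!is.finite(C)] <- 0
    mean(C[upper.tri(C)])
  }
  F15 <- mean_offdiag_cor(ev_s)
  F16 <- mean_offdiag_cor(dl_s)

  out <- c(F1 = F1, F2 = F2, F3 = F3, F4 = F4, F5 = F5, F6 = F6,
           F7 = F7, F8 = as.numeric(F8), F9 = as.numeric(F9), F10 = F10,
           F11 = F11, F12 = F12, F13 = F13, F14 = F14, F15 = F15, F16 = F16)
  class(out) <- c("aemid_features", "numeric")
  out
}

#' @export
print.aemid_features <- function(x, ...) {
  print(round(unclass(x), 4))
  invisible(x)
}

#' Train the perforation-vs-artefact classifier
#'
#' Standardizes the 16-dimensional feature vectors (mean/sd estimated on the
#' training data only) and fits a radial-basis support vector machine.
#' Hyperparameters (`cost`, `gamma`) are selected by deterministic
#' stratified 5-fold cross-validation on the training set.
#'
#' @param features matrix/data.frame of feature rows, or list of
#'   [compute_features()] vectors.
#' @param labels character/factor vector: `"perforation"` or `"artefact"`.
#' @param cost_grid,gamma_grid hyperparameter grids searched by
#'   cross-validation.
#' @return an object of class `aemid_classifier`.
#' @export
train_classifier <- function(features, labels,
                             cost_grid = c(1, 10, 100),
                             gamma_grid = c(0.02, 1 / 16, 0.25)) {
  X <- as_feature_matrix(features)
  y <- factor(as.character(labels), levels = c("artefact", "perforation"))
  if (anyNA(y)) stop("labels must be 'perforation' or 'artefact'", call. = FALSE)
  if (nlevels(droplevels(y)) < 2)
    stop("both classes must be present in the training data", call. = FALSE)
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl < 1e-12] <- 1
  Xs <- scale(X, center = ctr, scale = scl)

  # deterministic stratified folds: within each class, cycle fold ids in
  # input order
  nfold <- min(5L, min(table(y)))
  fold <- integer(nrow(Xs))
  for (lv in levels(y)) {
    ix <- which(y == lv)
    fold[ix] <- (seq_along(ix) - 1L) %% nfold + 1L
  }
  grid <- expand.grid(cost = cost_grid, gamma = gamma_grid)
  cv_acc <- vapply(seq_len(nrow(grid)), function(g) {
    acc <- vapply(seq_len(nfold), function(k) {
      tr <- fold != k
      fit <- e1071::svm(Xs[tr, , drop = FALSE], y[tr], kernel = "radial",
                        cost = grid$cost[g], gamma = grid$gamma[g],
                        scale = FALSE)
      mean(predict(fit, Xs[!tr, , drop = FALSE]) == y[!tr])
    }, 0)
    mean(acc)
  }, 0)
  best <- grid[which.max(cv_acc), ]
  fit <- e1071::svm(Xs, y, kernel = "radial", cost = best$cost,
                    gamma = best$gamma, scale = FALSE)
  structure(list(svm = fit, center = ctr, scale = scl,
                 cost = best$cost, gamma = best$gamma,
                 cv_accuracy = max(cv_acc),
                 levels = levels(y), features = colnames(X),
                 version = 1L),
            class = "aemid_classifier")
}

as_feature_matrix <- function(features) {
  if (is.list(features) && !is.data.frame(features))
    features <- do.call(rbind, lapply(features, unclass))
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("F", seq_len(ncol(X)))
  X
}

#' @export
print.aemid_classifier <- function(x, ...) {
  cat(sprintf("<aemid_classifier> RBF SVM (cost %g, gamma %g), CV accuracy %.3f, %d features\n",
              x$cost, x$gamma, x$cv_accuracy, length(x$features)))
  invisible(x)
}

#' Classify a guide-wire event
#'
#' @param model an [train_classifier()] result.
#' @param fv a single feature vector or a matrix of feature rows.
#' @return character vector of labels (`"perforation"` / `"artefact"`).
#' @export
classify_event <- function(model, fv) {
  if (!inherits(model, "aemid_classifier"))
    stop("`model` must be a trained aemid_classifier", call. = FALSE)
  X <- if (is.null(dim(fv))) matrix(unclass(fv), nrow = 1,
                                    dimnames = list(NULL, names(fv)))
       else as_feature_matrix(fv)
  Xs <- scale(X, center = model$center, scale = model$scale)
  as.character(predict(model$svm, Xs))
}

#' Confusion-matrix metrics for perforation detection
#'
#' Sensitivity is the proportion of true perforations recognized,
#' `TP / (TP + FN)`; specificity is the proportion of artefacts recognized,
#' `TN / (TN + FP)`.
#'
#' @param predicted,truth equal-length label vectors
#'   (`"perforation"` / `"artefact"`), or pass counts directly via
#'   `TP`, `FN`, `FP`, `TN`.
#' @param TP,FN,FP,TN alternatively, the confusion counts themselves.
#' @return an object of class `confusion_metrics` with the four counts and
#'   `sensitivity`, `specificity`.
#' @examples
#' confusion_metrics(TP = 418, FN = 42, FP = 10, TN = 205)
#' @export
confusion_metrics <- function(predicted = NULL, truth = NULL,
                              TP = NULL, FN = NULL, FP = NULL, TN = NULL) {
  if (is.null(TP)) {
    if (length(predicted) == 0L || length(predicted) != length(truth))
      stop("predicted and truth must be non-empty and of equal length",
           call. = FALSE)
    pos <- truth == "perforation"
    hit <- predicted == "perforation"
    TP <- sum(pos & hit); FN <- sum(pos & !hit)
    FP <- sum(!pos & hit); TN <- sum(!pos & !hit)
  }
  structure(list(TP = TP, FN = FN, FP = FP, TN = TN,
                 sensitivity = TP / (TP + FN),
                 specificity = TN / (TN + FP)),
            class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf("<confusion_metrics> TP %d  FN %d  FP %d  TN %d\n",
              x$TP, x$FN, x$FP, x$TN))
  cat(sprintf("  sensitivity %.1f%%  specificity %.1f%%\n",
              100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}
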