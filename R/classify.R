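#' Training samples for cut-off calibration
#'
#' @param r numeric R scores (the `Inf` sentinel is allowed; it is excluded
#'   from moment estimates).
#' @param label binary labels (`"positive"`/`"negative"`, logical, or 0/1).
#' @param pk_flag 0/1 pseudoknot presence per sample.
#' @param pk_energy pseudoknot energy per sample (model units).
#' @return data frame of class `training_samples`.
#' @export
training_samples <- function(r, label, pk_flag = 0L, pk_energy = 0) {
  if (is.character(label)) label <- label == "positive"
  label <- as.logical(label)
  stopifnot(length(r) == length(label), !anyNA(label), all(r >= 0 | is.infinite(r)))
  out <- data.frame(r = as.numeric(r), label = label,
                    pk_flag = as.integer(rep_len(pk_flag, length(r))),
                    pk_energy = as.numeric(rep_len(pk_energy, length(r))))
  class(out) <- c("training_samples", "data.frame")
  out
}

#' Calibrate a one-dimensional R cut-off by linear discriminant analysis
#'
#' Fisher LDA on the R scores alone: pooled within-class variance, class
#' priors proportional to class sizes. Returns the R value where the two
#' class discriminant scores are equal; with equal priors and variances this
#' is the midpoint of the class means. Infinite (perfect-match sentinel)
#' scores are dropped before estimation.
#'
#' @param samples a [training_samples()] data frame (>= 2 finite samples per
#'   class, class means must differ).
#' @return object of class `ires_cutoff` with the cut-off and fit moments.
#' @export
fit_cutoff_1d <- function(samples) {
  stopifnot(inherits(samples, "data.frame"), all(c("r", "label") %in% names(samples)))
  s <- samples[is.finite(samples$r), , drop = FALSE]
  rp <- s$r[s$label]
  rn <- s$r[!s$label]
  if (length(rp) < 2L || length(rn) < 2L)
    stop("calibration needs at least 2 finite samples per class", call. = FALSE)
  mp <- mean(rp); mn <- mean(rn)
  if (abs(mp - mn) < 1e-12)
    stop("class means are identical; no discriminant exists", call. = FALSE)
  n1 <- length(rp); n2 <- length(rn)
  pooled <- ((n1 - 1) * var(rp) + (n2 - 1) * var(rn)) / (n1 + n2 - 2)
  cutoff <- (mp + mn) / 2 + pooled * log(n2 / n1) / (mp - mn)
  structure(list(cutoff_r = cutoff, mean_pos = mp, mean_neg = mn,
                 pooled_var = pooled, n_pos = n1, n_neg = n2),
            class = "ires_cutoff")
}

#' @export
print.ires_cutoff <- function(x, ...) {
  cat(sprintf("<ires_cutoff> R cut-off %.4f (pos %.3f, neg %.3f, n=%d/%d)\n",
              x$cutoff_r, x$mean_pos, x$mean_neg, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
coef.ires_cutoff <- function(object, ...) c(cutoff_r = object$cutoff_r)

#' Two-feature linear discriminant on (R, pseudoknot)
#'
#' Standard two-class LDA on the features `(r, pk)`, where the pseudoknot
#' feature is the binary flag or the energy. Returns the discriminant line
#' `weight_r * r + weight_pk * pk + bias`, positive on the positive-class
#' side. If the pooled covariance is (near-)singular the fit falls back to
#' the one-dimensional R cut-off with a warning.
#'
#' @param samples a [training_samples()] data frame.
#' @param pk_feature `"flag"` (default) or `"energy"`.
#' @return object of class `ires_lda2d` with `weight_r`, `weight_pk`, `bias`.
#' @export
fit_lda_2d <- function(samples, pk_feature = c("flag", "energy")) {
  pk_feature <- match.arg(pk_feature)
  stopifnot(inherits(samples, "data.frame"))
  pk <- if (pk_feature == "flag") samples$pk_flag else samples$pk_energy
  s <- data.frame(r = samples$r, pk = as.numeric(pk), label = samples$label)
  s <- s[is.finite(s$r), , drop = FALSE]
  xp <- as.matrix(s[s$label, c("r", "pk")])
  xn <- as.matrix(s[!s$label, c("r", "pk")])
  if (nrow(xp) < 2L || nrow(xn) < 2L)
    stop("calibration needs at least 2 finite samples per class", call. = FALSE)
  mp <- colMeans(xp); mn <- colMeans(xn)
  n1 <- nrow(xp); n2 <- nrow(xn)
  S <- ((n1 - 1) * var(xp) + (n2 - 1) * var(xn)) / (n1 + n2 - 2)
  singular <- !is.finite(rcond_2x2(S)) || rcond_2x2(S) < 1e-10
  if (singular) {
    warning("pooled covariance is singular; falling back to 1-D cut-off on R",
            call. = FALSE)
    cut <- fit_cutoff_1d(training_samples(s$r, s$label))
    fit <- list(weight_r = 1, weight_pk = 0, bias = -cut$cutoff_r,
                pk_feature = pk_feature, fallback_1d = TRUE)
    return(structure(fit, class = "ires_lda2d"))
  }
  w <- solve(S, mp - mn)
  bias <- -sum(w * (mp + mn) / 2) + log(n1 / n2)
  structure(list(weight_r = unname(w["r"]), weight_pk = unname(w["pk"]),
                 bias = unname(bias), pk_feature = pk_feature,
                 fallback_1d = FALSE),
            class = "ires_lda2d")
}

rcond_2x2 <- function(S) {
  d <- det(S)
  if (!is.finite(d) || abs(d) == 0) return(0)
  1 / (norm(S, "1") * norm(solve(S), "1"))
}

#' @export
print.ires_lda2d <- function(x, ...) {
  cat(sprintf("<ires_lda2d> %.4f*r %+.4f*pk(%s) %+.4f >= 0 => positive%s\n",
              x$weight_r, x$weight_pk, x$pk_feature, x$bias,
              if (isTRUE(x$fallback_1d)) " (1-D fallback)" else ""))
  invisible(x)
}

#' @export
coef.ires_lda2d <- function(object, ...) {
  c(weight_r = object$weight_r, weight_pk = object$weight_pk,
    bias = object$bias)
}

#' @export
predict.ires_lda2d <- function(object, newdata, ...) {
  stopifnot(all(c("r", "pk") %in% names(newdata)))
  score <- object$weight_r * newdata$r + object$weight_pk * newdata$pk +
    object$bias
  score >= 0
}

#' Per-group IRES model
#'
#' An IRES group's template structure, frozen R cut-off and optional
#' two-feature discriminant. Default cut-offs per group: 1.61 (CrPV-like),
#' 1.98 (HCV-like), 1.87 (EMCV-like), 1.58 (PV-like).
#'
#' @param group_id integer in 1..4.
#' @param name group standard name (e.g. `"CrPV"`).
#' @param template an [arc_annotated()] nested template structure.
#' @param cutoff_r R cut-off (defaults to the group's frozen value).
#' @param lda2d optional [fit_lda_2d()] discriminant.
#' @param accession accession string carried as opaque metadata.
#' @return object of class `group_model`.
#' @export
group_model <- function(group_id, name, template, cutoff_r = NULL,
                        lda2d = NULL, accession = NA_character_) {
  group_id <- as.integer(group_id)
  stopifnot(group_id %in% 1:4, inherits(template, "arc_annotated"),
            template$nested)
  if (is.null(cutoff_r)) cutoff_r <- DEFAULT_CUTOFFS[group_id]
  structure(list(group_id = group_id, name = as.character(name),
                 template = template, cutoff_r = as.numeric(cutoff_r),
                 lda2d = lda2d, accession = accession),
            class = "group_model")
}

DEFAULT_CUTOFFS <- c(1.61, 1.98, 1.87, 1.58)

#' @export
print.group_model <- function(x, ...) {
  cat(sprintf("<group_model> group %d (%s): template %d nt / %d arcs, cutoff R >= %.2f%s\n",
              x$group_id, x$name, x$template$length, NROW(x$template$arcs),
              x$cutoff_r, if (!is.null(x$lda2d)) ", 2-D LDA" else ""))
  invisible(x)
}

#' Decide whether a candidate is called for a group
#'
#' `r_only` mode calls a candidate positive when `r >= cutoff_r`.
#' `r_plus_pk` mode uses the group's calibrated 2-D discriminant when
#' present; otherwise the declared fallback rule: positive when
#' `r >= cutoff_r`, or when a pseudoknot is present and
#' `r >= cutoff_r - relax`.
#'
#' @param r R score (the `Inf` sentinel is positive in every mode).
#' @param pk a `pk_result` from [detect_pseudoknot()] (may be `NULL` in
#'   `r_only` mode).
#' @param model a [group_model()].
#' @param mode `"r_plus_pk"` (default) or `"r_only"`.
#' @param relax cut-off relaxation for the pseudoknot rescue rule.
#' @return logical.
#' @export
decide_candidate <- function(r, pk = NULL, model,
                             mode = c("r_plus_pk", "r_only"), relax = 0.10) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "group_model"), r >= 0)
  if (is.infinite(r)) return(TRUE)
  if (mode == "r_only") return(r >= model$cutoff_r)
  if (!is.null(model$lda2d)) {
    stopifnot(inherits(pk, "pk_result"))
    feat <- if (model$lda2d$pk_feature == "flag") as.numeric(pk$has_pk)
            else pk$pk_energy
    return(unname(predict(model$lda2d, data.frame(r = r, pk = feat))))
  }
  if (is.null(relax))
    stop("r_plus_pk mode needs a 2-D discriminant or a relax value",
         call. = FALSE)
  if (r >= model$cutoff_r) return(TRUE)
  if (is.null(pk)) return(FALSE)
  stopifnot(inherits(pk, "pk_result"))
  pk$has_pk && r >= model$cutoff_r - relax
}
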