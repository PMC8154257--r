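## Pose classification and ranking from complementarity fits.
##
## Crystallographic/minimised reference complexes occupy a narrow band of
## slope (a) and intercept (b) values; docked poses scatter widely. The
## reference envelope is the min-max rectangle spanned by the reference
## fits, poses are classified by whether their slope falls inside the
## closed slope interval, and pose ranking is ascending in a (most
## negative slope = tightest complementarity first). Because a and b are
## nearly collinear across poses, the slope alone carries the signal; the
## b interval is reported for diagnostics only.

#' Build a reference envelope from fits
#'
#' @param fits List of `complementarity_fit` objects (>= 2), typically
#'   from crystallographic and/or minimised complexes.
#' @return Object of class `reference_envelope`: min/max/mean/sd of the
#'   slope `a` and intercept `b`, and `n_refs`.
#' @export
reference_envelope <- function(fits) {
  fits <- .as_fit_list(fits)
  if (length(fits) < 2L)
    .stopf("need at least 2 reference fits to build an envelope, got %d",
           length(fits))
  a <- vapply(fits, `[[`, numeric(1), "a")
  b <- vapply(fits, `[[`, numeric(1), "b")
  structure(
    list(a_min = min(a), a_max = max(a), a_mean = mean(a),
         a_sd = stats::sd(a),
         b_min = min(b), b_max = max(b), b_mean = mean(b),
         b_sd = stats::sd(b), n_refs = length(fits)),
    class = "reference_envelope")
}

#' @export
print.reference_envelope <- function(x, ...) {
  cat(sprintf(
    "reference_envelope (n = %d): a in [%.3f, %.3f] (mean %.3f +/- %.3f), b in [%.3f, %.3f]\n",
    x$n_refs, x$a_min, x$a_max, x$a_mean, x$a_sd, x$b_min, x$b_max))
  invisible(x)
}

#' Classify a pose against a reference envelope
#'
#' A pose is complementarity-consistent when its slope lies inside the
#' closed reference interval `[a_min, a_max]`. A pose inside the envelope
#' but far (in RMSD) from the reference pose is a candidate alternative or
#' metastable pose, not an error.
#'
#' @param fit A `complementarity_fit`.
#' @param envelope A [reference_envelope()].
#' @return Logical flag.
#' @export
classify_pose <- function(fit, envelope) {
  fit$a >= envelope$a_min & fit$a <= envelope$a_max
}

#' Rank poses by slope
#'
#' Ascending in `a` (most negative slope first); ties broken by higher
#' R^2, then by label.
#'
#' @param fits List of `complementarity_fit` objects (>= 1).
#' @param envelope Optional [reference_envelope()] used to flag each pose.
#' @param rmsd Optional named numeric vector of RMSDs to a reference pose
#'   (names matched against fit labels).
#' @param n_clusters Optional named integer vector of contact-cluster
#'   counts per pose.
#' @return Data frame (one row per pose, in rank order) with columns
#'   `rank`, `label`, `a`, `b`, `r2`, `adj_r2`, `n_points`, and when
#'   available `inside_envelope`, `rmsd`, `n_clusters`.
#' @export
rank_poses <- function(fits, envelope = NULL, rmsd = NULL,
                       n_clusters = NULL) {
  fits <- .as_fit_list(fits)
  if (length(fits) < 1L) .stopf("need at least one fit to rank")
  out <- data.frame(
    label = vapply(fits, `[[`, character(1), "label"),
    a = vapply(fits, `[[`, numeric(1), "a"),
    b = vapply(fits, `[[`, numeric(1), "b"),
    r2 = vapply(fits, `[[`, numeric(1), "r2"),
    adj_r2 = vapply(fits, `[[`, numeric(1), "adj_r2"),
    n_points = vapply(fits, `[[`, integer(1), "n_points"),
    stringsAsFactors = FALSE)
  if (!is.null(envelope))
    out$inside_envelope <- vapply(fits, classify_pose, logical(1), envelope)
  if (!is.null(rmsd)) out$rmsd <- unname(rmsd[out$label])
  if (!is.null(n_clusters)) out$n_clusters <- unname(n_clusters[out$label])
  out <- out[order(out$a, -out$r2, out$label), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("rank", setdiff(names(out), "rank"))]
}

#' Intercept-versus-slope regression across poses
#'
#' Across complexes the fitted (a, b) pairs fall on one line (adjusted
#' R^2 close to 1 on real systems), which is why the slope alone suffices
#' for classification.
#'
#' @param fits List of `complementarity_fit` objects (>= 3, with >= 2
#'   distinct slopes).
#' @return List with `slope`, `intercept`, `r2`, `adj_r2`, `n`.
#' @export
slope_intercept_line <- function(fits) {
  fits <- .as_fit_list(fits)
  if (length(fits) < 3L)
    .stopf("need at least 3 fits for the intercept-vs-slope line, got %d",
           length(fits))
  a <- vapply(fits, `[[`, numeric(1), "a")
  b <- vapply(fits, `[[`, numeric(1), "b")
  if (length(unique(a)) < 2L) .stopf("singular fit: all slopes identical")
  fit <- stats::lm(b ~ a)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((b - mean(b))^2)
  r2 <- 1 - rss / tss
  n <- length(a)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = r2, adj_r2 = 1 - (1 - r2) * (n - 1) / (n - 2), n = n)
}

.as_fit_list <- function(fits) {
  if (inherits(fits, "complementarity_fit")) return(list(fits))
  stopifnot(is.list(fits))
  fits
}
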