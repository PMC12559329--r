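#' Non-negative decomposition of a mutant trace into indel templates
#'
#' The mutant chromatogram's four channels over the fitting window are
#' flattened into one observation vector and regressed on the per-shift
#' template matrix under a non-negativity constraint (Lawson-Hanson
#' active-set NNLS). Standard errors come from the variance-covariance
#' matrix of the unconstrained normal equations restricted to the active
#' (non-zero) components, with residual degrees of freedom
#' `observations - active parameters`; each active component gets a
#' two-tailed t test.
#'
#' @name decompose
NULL

#' Decompose a mutant chromatogram into indel components
#'
#' @param mutant a `chromatogram` covering the fitting window.
#' @param templates a `template_set` from [build_templates()].
#' @param alpha significance threshold for reporting a component
#'   (default 0.001).
#' @param bonferroni if `TRUE`, divide `alpha` by the number of fitted
#'   shifts.
#' @param baseline if `TRUE` (default), a non-negative constant column
#'   is fitted alongside the templates. Measured chromatograms sit on a
#'   noise floor (and a zero-clipped noise model leaves a positive mean
#'   on empty channels); without the baseline term that floor leaks
#'   into the shift components and inflates false positives under the
#'   null. The baseline coefficient is reported separately and excluded
#'   from the component fractions.
#' @return a `decomposition` object: data.frame `components` with one
#'   row per shift (`shift`, `coefficient`, `fraction` of total
#'   decomposed signal, `se`, `t`, `p`, `significant`), plus
#'   `r_squared`, `df`, `alpha`, `baseline`, and the template metadata.
#' @export
decompose <- function(mutant, templates, alpha = 0.001,
                      bonferroni = FALSE, baseline = TRUE) {
  stopifnot(inherits(mutant, "chromatogram"),
            inherits(templates, "template_set"))
  w0 <- templates$window$start
  ww <- templates$window$width
  if (nrow(mutant$scans) < w0 + ww)
    abort_invalid("mutant trace does not cover the fitting window")
  y <- as.vector(mutant$scans[(w0 + 1L):(w0 + ww), , drop = FALSE])
  a <- vapply(templates$templates, as.vector, numeric(4L * ww))
  # a rank-deficient template matrix (e.g. repeat-phased shifts inside a
  # periodic tract) makes the shift split unidentifiable: refuse early
  qa <- qr(a)
  if (qa$rank < ncol(a)) {
    bad <- templates$shifts[qa$pivot[-seq_len(qa$rank)]]
    abort_degenerate(sprintf(
      "collinear templates: shifts (%s) are not distinguishable within the fitting window",
      paste(bad, collapse = ", ")))
  }
  n_shift <- ncol(a)
  if (baseline) a <- cbind(a, baseline = 1)
  fit <- pracma::lsqnonneg(a, y)
  x <- fit$x
  tol <- max(abs(x)) * 1e-10
  active <- x > tol
  n_obs <- length(y)
  df <- n_obs - sum(active)
  resid <- y - a %*% x
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  r_squared <- if (tss > 0) 1 - rss / tss else 1
  se <- t_stat <- p_val <- rep(NA_real_, length(x))
  if (any(active)) {
    aa <- a[, active, drop = FALSE]
    xtx <- crossprod(aa)
    if (rcond(xtx) < .Machine$double.eps * 1e3) {
      qa <- qr(aa)
      shifts_ext <- c(templates$shifts,
                      if (baseline) NA_integer_ else NULL)
      bad <- shifts_ext[active][qa$pivot[-seq_len(qa$rank)]]
      abort_degenerate(sprintf(
        "collinear templates in the active set (shifts: %s)",
        paste(bad, collapse = ", ")))
    }
    sigma2 <- if (df > 0) rss / df else 0
    covm <- sigma2 * solve(xtx)
    se[active] <- sqrt(pmax(diag(covm), 0))
    t_stat[active] <- ifelse(se[active] > 0, x[active] / se[active], Inf)
    p_val[active] <- if (df > 0)
      2 * stats::pt(-abs(t_stat[active]), df) else 0
  }
  keep <- seq_len(n_shift)
  xs <- x[keep]
  total <- sum(xs)
  thr <- if (bonferroni) alpha / n_shift else alpha
  comp <- data.frame(
    shift = templates$shifts,
    coefficient = xs,
    fraction = if (total > 0) xs / total else xs,
    se = se[keep], t = t_stat[keep], p = p_val[keep],
    significant = !is.na(p_val[keep]) & p_val[keep] < thr)
  structure(list(components = comp, r_squared = r_squared, df = df,
                 rss = rss, alpha = thr, bonferroni = bonferroni,
                 baseline = if (baseline) x[n_shift + 1L] else NA_real_,
                 window = templates$window,
                 expected_insert_bases = templates$expected_insert_bases,
                 target_site = templates$target_site),
            class = "decomposition")
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf("trace decomposition: R^2 = %.4f, df = %d, alpha = %g\n",
              x$r_squared, x$df, x$alpha))
  sig <- x$components[x$components$significant, , drop = FALSE]
  if (nrow(sig) == 0) {
    cat("no significant components\n")
  } else {
    print(sig, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Summarize indel components of a decomposition
#'
#' Reports the dominant significant non-zero-shift component, checks
#' the identity of the expected insert against the substrate's loop
#' sequence (and its reverse complement), and totals the insertion and
#' shortening (deletion) signal under both normalisations: as a share
#' of the total decomposed signal, and as raw coefficients (which
#' include the unexplained residual implicitly, since coefficients need
#' not sum to one).
#'
#' @param result a `decomposition`.
#' @param substrate optional `heteroduplex`, enabling the loop-identity
#'   check.
#' @return an `indel_summary` list; its `table` field is a one-row
#'   data.frame suitable for TSV export.
#' @export
summarize_indels <- function(result, substrate = NULL) {
  comp <- result$components
  nz <- comp[comp$shift != 0 & comp$significant, , drop = FALSE]
  dominant <- if (nrow(nz) > 0) nz[which.max(nz$fraction), ] else NULL
  ins <- comp$shift > 0
  del <- comp$shift < 0
  insertion_fraction <- sum(comp$fraction[ins & comp$significant])
  shortening_fraction <- sum(comp$fraction[del & comp$significant])
  insertion_coef <- sum(comp$coefficient[ins & comp$significant])
  shortening_coef <- sum(comp$coefficient[del & comp$significant])
  identity <- NA
  if (!is.null(dominant) && !is.null(substrate) && dominant$shift > 0) {
    insert <- phased_insert(result$expected_insert_bases, dominant$shift)
    identity <- if (insert == revcomp(substrate$loop$loop_sequence))
      "loop reverse complement"
    else if (insert == substrate$loop$loop_sequence) "loop sequence"
    else "other"
  }
  out <- list(
    dominant_shift = if (is.null(dominant)) NA_integer_ else dominant$shift,
    dominant_fraction = if (is.null(dominant)) NA_real_ else dominant$fraction,
    dominant_p = if (is.null(dominant)) NA_real_ else dominant$p,
    insert_identity = identity,
    insertion_fraction = insertion_fraction,
    shortening_fraction = shortening_fraction,
    insertion_coefficient = insertion_coef,
    shortening_coefficient = shortening_coef,
    r_squared = result$r_squared,
    significant_shifts = nz$shift)
  out$table <- data.frame(
    dominant_shift = out$dominant_shift,
    dominant_fraction = out$dominant_fraction,
    insert_identity = if (is.na(identity)) NA_character_ else identity,
    insertion_fraction = insertion_fraction,
    shortening_fraction = shortening_fraction,
    insertion_coefficient = insertion_coef,
    shortening_coefficient = shortening_coef,
    r_squared = result$r_squared)
  class(out) <- "indel_summary"
  out
}

#' @export
print.indel_summary <- function(x, ...) {
  if (is.na(x$dominant_shift)) {
    cat("no significant indel\n")
  } else {
    cat(sprintf(
      "dominant indel: %+d nt (%.1f%% of decomposed signal, p = %.3g)\n",
      x$dominant_shift, 100 * x$dominant_fraction, x$dominant_p))
    if (!is.na(x$insert_identity) && x$dominant_shift > 0)
      cat(sprintf("insert identity: %s\n", x$insert_identity))
    cat(sprintf("total insertion signal: %.1f%%; total shortening signal: %.1f%%\n",
                100 * x$insertion_fraction, 100 * x$shortening_fraction))
  }
  invisible(x)
}

#' Write decomposition results as TSV and JSON
#'
#' @param result a `decomposition`.
#' @param out_prefix output path prefix.
#' @param substrate optional substrate for the summary identity check.
#' @export
export_decomposition <- function(result, out_prefix, substrate = NULL) {
  tsv <- paste0(out_prefix, ".components.tsv")
  json <- paste0(out_prefix, ".decomposition.json")
  utils::write.table(result$components, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  s <- summarize_indels(result, substrate)
  jsonlite::write_json(
    list(r_squared = result$r_squared, df = result$df, alpha = result$alpha,
         dominant_shift = s$dominant_shift,
         dominant_fraction = s$dominant_fraction,
         insert_identity = s$insert_identity,
         insertion_fraction = s$insertion_fraction,
         shortening_fraction = s$shortening_fraction,
         components = result$components),
    json, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv = tsv, json = json))
}
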