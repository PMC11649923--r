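# Differential methylation between conditions across replicates.

#' Summarize per-replicate Methscores at one site
#'
#' @param scores numeric vector of per-replicate scores; `NA` (undefined)
#'   replicates are dropped and counted.
#' @return list with `mean`, `sem` (sample sd / sqrt(n); `NA` when n < 2),
#'   `n` and `n_dropped`. An all-undefined input yields an `NA` summary with
#'   `n = 0`.
#' @examples
#' aggregate_replicates(c(0.8, 1.0))  # mean 0.9, sem 0.1
#' @export
aggregate_replicates <- function(scores) {
  n_dropped <- sum(is.na(scores))
  x <- scores[!is.na(scores)]
  n <- length(x)
  if (n == 0L) {
    return(list(mean = NA_real_, sem = NA_real_, n = 0L, n_dropped = n_dropped))
  }
  list(mean = mean(x),
       sem = if (n >= 2L) stats::sd(x) / sqrt(n) else NA_real_,
       n = n, n_dropped = n_dropped)
}

#' Two-sample t-test on per-replicate Methscores
#'
#' Student's pooled-variance two-sample t statistic with a two-tailed p-value
#' on `n1 + n2 - 2` degrees of freedom, matching the mean +/- SEM replicate
#' summaries the comparison reports. Welch's unequal-variance form is
#' available via `var_equal = FALSE`.
#'
#' Degenerate case: zero pooled variance with unequal means has an infinite
#' statistic; the p-value is reported as the double floor and the result is
#' flagged.
#'
#' @param control,treated numeric score vectors, each of length >= 2.
#' @param var_equal pooled (Student, default) vs Welch variance.
#' @return list with `t`, `p`, `df`, `flag` (`NA` or `"zero_variance"`).
#' @export
test_site_difference <- function(control, treated, var_equal = TRUE) {
  control <- control[is.finite(control)]
  treated <- treated[is.finite(treated)]
  n1 <- length(control); n2 <- length(treated)
  if (n1 < 2L || n2 < 2L) {
    stop_invalid("each group needs >= 2 finite replicate scores (got ",
                 n1, " and ", n2, ")")
  }
  m1 <- mean(control); m2 <- mean(treated)
  v1 <- stats::var(control); v2 <- stats::var(treated)
  if (var_equal) {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- se^4 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  if (se == 0) {
    if (m1 == m2) {
      return(list(t = 0, p = 1, df = df, flag = NA_character_))
    }
    return(list(t = sign(m2 - m1) * Inf, p = .Machine$double.xmin, df = df,
                flag = "zero_variance"))
  }
  t <- (m2 - m1) / se
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df, flag = NA_character_)
}

# Per-replicate site score: mean of the raw (unclamped) 5p/3p track values at
# the site, falling back to whichever end is defined. The raw value is used
# because clamping at 0 truncates the null sampling distribution and would
# distort the t-test at weakly methylated positions.
site_scores_by_replicate <- function(tracks, position, use = c("raw", "score")) {
  use <- match.arg(use)
  reps <- unique(vapply(tracks, `[[`, character(1), "replicate"))
  vapply(reps, function(r) {
    vals <- vapply(tracks[vapply(tracks, `[[`, character(1), "replicate") == r],
                   function(t) t[[use]][position], numeric(1))
    if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  }, numeric(1))
}

#' Differential methylation table across conditions
#'
#' For every site, summarizes per-replicate Methscores in each condition
#' (mean +/- SEM), tests the difference with a two-tailed Student t-test and
#' reports Benjamini-Hochberg FDR across the tested sites alongside the raw
#' p-values (the raw p remains the primary column).
#'
#' Each replicate contributes one score per site: the mean of its 5p- and
#' 3p-derived track values at that position (raw, unclamped scale by
#' default).
#'
#' @param control_tracks,treated_tracks lists of per-replicate
#'   `methscore_track`s (both ends) in site coordinates.
#' @param sites data.frame with at least `position` (typically the consensus
#'   calls on the control condition); `NULL` with `all_positions = TRUE`
#'   tests every position defined in all replicates.
#' @param reference optional [rrna_reference()] used to label sites.
#' @param all_positions test every defined position instead of a call set.
#' @param use `"raw"` (default) or `"score"` (clamped) replicate values.
#' @param var_equal passed to [test_site_difference()].
#' @return data.frame, one row per site, sorted by position: condition
#'   summaries, `delta` (treated - control), `t`, `p`, `fdr`, `sig_p`,
#'   `sig_fdr`, `flag`.
#' @export
summarize_diffmeth <- function(control_tracks, treated_tracks, sites = NULL,
                               reference = NULL, all_positions = FALSE,
                               use = "raw", var_equal = TRUE) {
  all_tracks <- c(control_tracks, treated_tracks)
  mol <- unique(vapply(all_tracks, `[[`, character(1), "molecule"))
  if (length(mol) != 1L) {
    stop_invalid("tracks span multiple molecules: ", paste(mol, collapse = ", "))
  }
  L <- unique(vapply(all_tracks, function(t) length(t$score), integer(1)))
  if (length(L) != 1L) stop_invalid("tracks have inconsistent lengths")
  if (is.null(sites)) {
    if (!all_positions) {
      stop_invalid("supply a site set or request all_positions = TRUE")
    }
    defined <- Reduce(`&`, lapply(all_tracks, function(t) !is.na(t$raw)))
    positions <- which(defined)
  } else {
    positions <- sites$position
  }
  if (length(positions) == 0L) {
    return(data.frame(molecule = character(), position = integer(),
                      label = character(), mean_control = numeric(),
                      sem_control = numeric(), n_control = integer(),
                      mean_kd = numeric(), sem_kd = numeric(),
                      n_kd = integer(), delta = numeric(), t = numeric(),
                      p = numeric(), fdr = numeric(), sig_p = logical(),
                      sig_fdr = logical(), flag = character()))
  }
  rows <- lapply(positions, function(pos) {
    sc <- site_scores_by_replicate(control_tracks, pos, use = use)
    st <- site_scores_by_replicate(treated_tracks, pos, use = use)
    ac <- aggregate_replicates(sc)
    at <- aggregate_replicates(st)
    if (ac$n >= 2L && at$n >= 2L) {
      tt <- test_site_difference(sc[!is.na(sc)], st[!is.na(st)],
                                 var_equal = var_equal)
    } else {
      tt <- list(t = NA_real_, p = NA_real_, flag = "insufficient_replicates")
    }
    data.frame(molecule = mol, position = pos,
               label = if (!is.null(reference)) name_site(pos, reference)
                       else paste0("pos", pos),
               mean_control = ac$mean, sem_control = ac$sem, n_control = ac$n,
               mean_kd = at$mean, sem_kd = at$sem, n_kd = at$n,
               delta = at$mean - ac$mean, t = tt$t, p = tt$p,
               flag = tt$flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$position), , drop = FALSE]
  out$fdr <- bh_adjust(out$p)
  out$sig_p <- !is.na(out$p) & out$p < 0.05
  out$sig_fdr <- !is.na(out$fdr) & out$fdr < 0.05
  rownames(out) <- NULL
  out[, c("molecule", "position", "label", "mean_control", "sem_control",
          "n_control", "mean_kd", "sem_kd", "n_kd", "delta", "t", "p",
          "fdr", "sig_p", "sig_fdr", "flag")]
}
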