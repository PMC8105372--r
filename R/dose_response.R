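#' Fraction of responding cells per energy density
#'
#' Per-experiment percentages of cells classified as responders at each
#' energy density, plus the unweighted cross-experiment mean and standard
#' error (each experiment contributes one observation per energy).
#'
#' @param calls Data frame of response calls with columns `roi_id`,
#'   `energy_density`, `is_responder`, and optionally `experiment_id`
#'   (a single experiment is assumed when absent).
#' @return List of class `responder_fractions`: `per_experiment` (one row
#'   per experiment x energy: `n_total`, `n_responders`, `fraction_pct`)
#'   and `summary` (per energy: `mean_pct`, `sem_pct`, `n_experiments`).
#' @export
responder_fractions <- function(calls) {
  calls <- .ensure_experiment(calls)
  stopifnot(all(c("roi_id", "energy_density", "is_responder") %in% names(calls)))
  if (nrow(calls) == 0) stop("empty call set")
  per <- stats::aggregate(is_responder ~ experiment_id + energy_density,
                          data = calls,
                          FUN = function(v) c(n = length(v), r = sum(v)))
  per <- data.frame(experiment_id = per$experiment_id,
                    energy_density = per$energy_density,
                    n_total = per$is_responder[, "n"],
                    n_responders = per$is_responder[, "r"])
  per$fraction_pct <- 100 * per$n_responders / per$n_total
  per <- per[order(per$experiment_id, per$energy_density), ]
  rownames(per) <- NULL
  sm <- stats::aggregate(fraction_pct ~ energy_density, data = per,
                         FUN = function(v) c(m = mean(v),
                                             s = if (length(v) > 1)
                                               stats::sd(v) / sqrt(length(v)) else 0,
                                             n = length(v)))
  summary <- data.frame(energy_density = sm$energy_density,
                        mean_pct = sm$fraction_pct[, "m"],
                        sem_pct = sm$fraction_pct[, "s"],
                        n_experiments = sm$fraction_pct[, "n"])
  structure(list(per_experiment = per, summary = summary),
            class = "responder_fractions")
}

.ensure_experiment <- function(calls) {
  if (!"experiment_id" %in% names(calls)) calls$experiment_id <- "exp1"
  calls
}

#' Responder multiplicity categorisation
#'
#' Counts, for each cell, the number of energy densities at which it was
#' classified as a responder, partitions responders into the classes
#' 1x (exactly one energy), 2x (exactly two) and 3x+4x (three or four), and
#' decomposes each energy's responder count by the class of its cells.
#' Cells not evaluated at every energy are excluded with a warning.
#'
#' @param calls Response-call data frame (see [responder_fractions()]).
#' @return List of class `multiplicity_table`: `per_cell` (one row per
#'   cell: `n_responsive`, `class`), `counts` (named vector for the three
#'   responder classes), `per_energy` (rows per energy with `n_1x`,
#'   `n_2x`, `n_3x4x`, `n_responders`).
#' @export
multiplicity_categories <- function(calls) {
  calls <- .ensure_experiment(calls)
  energies <- sort(unique(calls$energy_density))
  cell <- paste(calls$experiment_id, calls$roi_id, sep = "\r")
  n_eval <- tapply(calls$energy_density, cell,
                   function(e) length(unique(e)))
  bad <- names(n_eval)[n_eval < length(energies)]
  if (length(bad) > 0) {
    warning(length(bad), " cell(s) not evaluated at every energy density: excluded")
    calls <- calls[!(cell %in% bad), , drop = FALSE]
    cell <- cell[!(cell %in% bad)]
  }
  if (nrow(calls) == 0) stop("no cells evaluated at every energy density")

  nresp <- tapply(calls$is_responder, cell, sum)
  ids <- do.call(rbind, strsplit(names(nresp), "\r", fixed = TRUE))
  per_cell <- data.frame(experiment_id = ids[, 1], roi_id = ids[, 2],
                         n_responsive = as.integer(nresp),
                         row.names = NULL)
  per_cell$class <- multiplicity_class(per_cell$n_responsive)

  counts <- c("1x" = sum(per_cell$class == "1x"),
              "2x" = sum(per_cell$class == "2x"),
              "3x+4x" = sum(per_cell$class == "3x+4x"))

  cls_of <- stats::setNames(per_cell$class,
                            paste(per_cell$experiment_id, per_cell$roi_id,
                                  sep = "\r"))
  resp <- calls[calls$is_responder, , drop = FALSE]
  rcls <- cls_of[paste(resp$experiment_id, resp$roi_id, sep = "\r")]
  per_energy <- do.call(rbind, lapply(energies, function(e) {
    ce <- rcls[resp$energy_density == e]
    data.frame(energy_density = e,
               n_1x = sum(ce == "1x"), n_2x = sum(ce == "2x"),
               n_3x4x = sum(ce == "3x+4x"), n_responders = length(ce))
  }))
  structure(list(per_cell = per_cell, counts = counts,
                 per_energy = per_energy),
            class = "multiplicity_table")
}

#' Multiplicity class labels from responsive-energy counts
#'
#' @param n Integer vector, number of energies a cell responds to (0-4).
#' @return Character vector in `{"0", "1x", "2x", "3x+4x"}`.
#' @export
multiplicity_class <- function(n) {
  stopifnot(all(n >= 0), all(n <= 4))
  c("0", "1x", "2x", "3x+4x", "3x+4x")[n + 1]
}

#' Normalised amplitude dose-response curve
#'
#' Restricts to the cells that respond at every energy in
#' `require_energies` (by default all levels above the weakest stimulus),
#' then reports the mean peak dF/F0 (+/- SEM) at every energy over that
#' subset, normalised to the mean at the reference energy (100%). Peak
#' amplitudes are included for the subset even at energies where a given
#' cell was not itself a responder. Tukey outliers among the peaks are
#' removed per experiment and energy before aggregation (see
#' [tukey_outliers()]).
#'
#' @param calls Response-call data frame with `peak_dff` (see
#'   [analyze_traces()]).
#' @param require_energies Energies a cell must respond to for inclusion.
#' @param reference_energy Energy whose mean defines 100%; default the
#'   highest available energy.
#' @param remove_outliers Apply per-experiment Tukey outlier removal to the
#'   peaks before averaging.
#' @return Data frame of class `dose_response_curve`: `energy_density`,
#'   `n_cells`, `mean_peak`, `sem_peak`, `normalized_pct`.
#' @export
normalized_dose_response <- function(calls,
                                     require_energies = c(0.47, 0.58, 0.70),
                                     reference_energy = NULL,
                                     remove_outliers = TRUE) {
  calls <- .ensure_experiment(calls)
  stopifnot("peak_dff" %in% names(calls))
  energies <- sort(unique(calls$energy_density))
  if (is.null(reference_energy)) reference_energy <- max(energies)
  if (!reference_energy %in% energies) stop("reference energy not present")

  cell <- paste(calls$experiment_id, calls$roi_id, sep = "\r")
  ok <- tapply(seq_len(nrow(calls)), cell, function(i) {
    sub <- calls[i, ]
    all(vapply(require_energies, function(e)
      any(sub$energy_density == e & sub$is_responder), TRUE))
  })
  keep <- names(ok)[ok]
  if (length(keep) == 0) stop("no cell responds at all required energies")
  sub <- calls[cell %in% keep, , drop = FALSE]

  if (remove_outliers) {
    grp <- paste(sub$experiment_id, sub$energy_density, sep = "\r")
    drop <- unlist(lapply(split(seq_len(nrow(sub)), grp), function(i) {
      if (length(i) < 4) return(integer(0))
      i[suppressWarnings(tukey_outliers(sub$peak_dff[i])$outlier)]
    }))
    if (length(drop) > 0) sub <- sub[-drop, , drop = FALSE]
  }

  agg <- lapply(energies, function(e) {
    v <- sub$peak_dff[sub$energy_density == e]
    data.frame(energy_density = e, n_cells = length(v), mean_peak = mean(v),
               sem_peak = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0)
  })
  out <- do.call(rbind, agg)
  ref <- out$mean_peak[out$energy_density == reference_energy]
  if (!is.finite(ref) || ref <= 0) stop("reference mean peak must be > 0")
  out$normalized_pct <- 100 * out$mean_peak / ref
  class(out) <- c("dose_response_curve", class(out))
  out
}

#' Percent of a reference value
#'
#' Utility used for normalised dose-response summaries computed from group
#' means: `100 * x / x[reference]`.
#'
#' @param x Numeric vector of (mean) amplitudes.
#' @param reference Index of the reference entry; default the last.
#' @return Numeric vector of percentages, 100 at the reference.
#' @examples
#' percent_of_reference(c(0.0148, 0.0470, 0.0654, 0.0729))
#' @export
percent_of_reference <- function(x, reference = length(x)) {
  stopifnot(length(x) >= 1, reference >= 1, reference <= length(x))
  if (!is.finite(x[reference]) || x[reference] <= 0)
    stop("reference value must be > 0")
  100 * x / x[reference]
}

#' Two-sample t test (pooled variance)
#'
#' Student's two-sample t test with pooled variance (Welch available via
#' `var_equal = FALSE`), two-sided. Degenerate zero-variance samples are
#' handled explicitly: equal means give t = 0, p = 1; unequal means are
#' flagged with an infinite statistic and p = 0.
#'
#' @param a,b Numeric samples (each of length >= 2).
#' @param var_equal Pool the variances (default TRUE).
#' @return A `stat_result` list: `method`, `statistic`, `df`, `p_value`,
#'   `comparison`.
#' @export
two_sample_t <- function(a, b, var_equal = TRUE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  df <- length(a) + length(b) - 2
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b))
      return(stat_result("two-sample t (pooled)", 0, df, 1,
                         "zero variance, equal means"))
    return(stat_result("two-sample t (pooled)",
                       sign(mean(a) - mean(b)) * Inf, df, 0,
                       "zero variance, unequal means (infinite t)"))
  }
  ht <- stats::t.test(a, b, var.equal = var_equal)
  stat_result(if (var_equal) "two-sample t (pooled)" else "Welch t",
              unname(ht$statistic), unname(ht$parameter), ht$p.value,
              "two-sided two-sample comparison")
}

stat_result <- function(method, statistic, df, p_value, comparison = "") {
  structure(list(method = method, statistic = statistic, df = df,
                 p_value = p_value, comparison = comparison),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g\n", x$method,
              x$statistic, paste(signif(x$df, 4), collapse = ", "),
              x$p_value))
  if (nzchar(x$comparison)) cat(" ", x$comparison, "\n")
  invisible(x)
}

#' One-way repeated-measures ANOVA with Bonferroni post-hoc tests
#'
#' Within-subject one-way ANOVA across energy conditions (subjects = cells,
#' F on (k - 1, (k - 1)(n - 1)) degrees of freedom), followed by paired t
#' tests between conditions with Bonferroni correction (p multiplied by the
#' number of performed comparisons, capped at 1). By default only adjacent
#' condition pairs are compared.
#'
#' @param mat Complete numeric matrix, subjects (rows) x conditions
#'   (columns); column names label the conditions.
#' @param pairs `"adjacent"` (default) or `"all"`.
#' @return List of class `rm_anova`: `anova` (a `stat_result`) and
#'   `pairwise` (data frame with raw and Bonferroni-adjusted p values).
#' @export
rm_anova_bonferroni <- function(mat, pairs = c("adjacent", "all")) {
  pairs <- match.arg(pairs)
  stopifnot(is.matrix(mat), nrow(mat) >= 2, ncol(mat) >= 2)
  if (any(!is.finite(mat))) stop("matrix must be complete (no imputation)")
  n <- nrow(mat); k <- ncol(mat)
  cond_names <- colnames(mat)
  if (is.null(cond_names)) cond_names <- paste0("c", seq_len(k))

  d <- data.frame(y = as.vector(mat),
                  subject = factor(rep(seq_len(n), times = k)),
                  cond = factor(rep(cond_names, each = n),
                                levels = cond_names))
  ss_cond <- n * sum((colMeans(mat) - mean(mat))^2)
  if (ss_cond < .Machine$double.eps * sum(mat^2 + 1)) {
    an <- stat_result("repeated-measures ANOVA", 0,
                      c(k - 1, (k - 1) * (n - 1)), 1,
                      "no condition effect (zero between-condition SS)")
  } else {
    fit <- stats::aov(y ~ cond + Error(subject / cond), data = d)
    tab <- summary(fit)[["Error: subject:cond"]][[1]]
    an <- stat_result("repeated-measures ANOVA",
                      tab["cond", "F value"],
                      c(tab["cond", "Df"], tab["Residuals", "Df"]),
                      tab["cond", "Pr(>F)"],
                      "within-subject condition effect")
  }

  idx <- if (pairs == "adjacent")
    cbind(seq_len(k - 1), 2:k)
  else
    t(utils::combn(k, 2))
  pw <- do.call(rbind, lapply(seq_len(nrow(idx)), function(r) {
    i <- idx[r, 1]; j <- idx[r, 2]
    dd <- mat[, j] - mat[, i]
    if (stats::sd(dd) == 0) {
      tt <- if (mean(dd) == 0) c(0, 1) else c(sign(mean(dd)) * Inf, 0)
    } else {
      ht <- stats::t.test(mat[, j], mat[, i], paired = TRUE)
      tt <- c(unname(ht$statistic), ht$p.value)
    }
    data.frame(comparison = paste(cond_names[j], "vs", cond_names[i]),
               statistic = tt[1], df = n - 1, p_value = tt[2])
  }))
  pw$p_adjusted <- pmin(1, pw$p_value * nrow(pw))
  structure(list(anova = an, pairwise = pw), class = "rm_anova")
}
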