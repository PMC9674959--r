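#' Normalize variant uptake against wild-type and empty-vector controls
#'
#' Converts a background-subtracted uptake measurement to percent of
#' wild-type function: `100 * (variant - EV) / (WT - EV)`, where EV is the
#' empty-vector background and WT the reference transporter measured in the
#' same batch. Values below 0 or above 100 are retained: a variant can sit
#' below background noise or transport more than wild type.
#'
#' @param variant_mean,wt_mean,ev_mean uptake values (counts per ug
#'   protein); `variant_mean` may be a vector.
#' @return percent-of-WT function, same length as `variant_mean`.
#' @export
normalize_uptake <- function(variant_mean, wt_mean, ev_mean) {
  stopifnot(is.finite(wt_mean), is.finite(ev_mean))
  if (wt_mean <= ev_mean) {
    stop("degenerate controls: WT uptake (", wt_mean,
         ") must exceed empty-vector background (", ev_mean, ")",
         call. = FALSE)
  }
  100 * (variant_mean - ev_mean) / (wt_mean - ev_mean)
}

#' Summarize replicate measurements into mean and SEM
#'
#' Technical wells are averaged within each biological replicate first;
#' mean and SEM are then computed across the biological-replicate means.
#' With a single biological replicate the SEM is undefined and returned as
#' `NA` with a warning.
#'
#' @param values numeric measurements (one per well).
#' @param bio_rep biological-replicate id per value.
#' @return list with `mean`, `sem`, `n_bio` and the per-replicate means
#'   `bio_means`.
#' @export
summarize_replicates <- function(values, bio_rep) {
  stopifnot(length(values) == length(bio_rep), all(is.finite(values)))
  bio_means <- tapply(values, bio_rep, mean)
  n <- length(bio_means)
  if (n == 1L) {
    warning("single biological replicate: SEM undefined", call. = FALSE)
    sem <- NA_real_
  } else {
    sem <- stats::sd(bio_means) / sqrt(n)
  }
  list(mean = mean(bio_means), sem = sem, n_bio = n,
       bio_means = as.numeric(bio_means))
}

#' Two-sample test of a variant against wild type with Bonferroni control
#'
#' Two-sided two-sample t test of the variant's biological-replicate values
#' against wild type's, significant when p is below `0.05 / n_tests`
#' (Bonferroni over the study's variant count; 150 variants give
#' alpha = 3.3e-4). The classical equal-variance Student test is the
#' default; Welch is available via `var_equal = FALSE`.
#'
#' @param variant_reps,wt_reps numeric replicate values (>= 2 each).
#' @param n_tests number of tests used for the Bonferroni correction.
#' @param var_equal assume equal variances (Student) or not (Welch).
#' @return list with `p_value`, `significant`, `alpha`.
#' @export
test_vs_wt <- function(variant_reps, wt_reps, n_tests = 1L,
                       var_equal = TRUE) {
  if (length(variant_reps) < 2L || length(wt_reps) < 2L) {
    stop("need at least 2 replicates on each side", call. = FALSE)
  }
  alpha <- 0.05 / n_tests
  if (stats::sd(variant_reps) == 0 && stats::sd(wt_reps) == 0) {
    # degenerate zero-variance samples (e.g. noiseless simulation)
    p <- if (isTRUE(all.equal(mean(variant_reps), mean(wt_reps)))) 1 else 0
  } else {
    p <- stats::t.test(variant_reps, wt_reps, var.equal = var_equal)$p.value
  }
  list(p_value = p, significant = p < alpha, alpha = alpha)
}

#' Call loss of function from percent-of-WT function
#'
#' A variant is loss-of-function when its function is strictly below the
#' threshold (default 20% of wild type, the level associated with
#' susceptibility to carnitine transporter deficiency). A variant at
#' exactly the threshold is not LOF.
#'
#' @param function_pct percent-of-WT function (vectorized).
#' @param threshold LOF threshold in percent of WT.
#' @return logical vector.
#' @export
call_lof <- function(function_pct, threshold = 20) {
  function_pct < threshold
}

#' Read a raw uptake-assay table
#'
#' Tab-separated with columns `variant`, `batch`, `bio_rep`, `tech_rep`,
#' `uptake_counts_per_ug`; control rows use the reserved labels `WT` and
#' `EV`.
#'
#' @param path path to the TSV file.
#' @return data.frame.
#' @export
read_assay_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  required <- c("variant", "batch", "bio_rep", "tech_rep",
                "uptake_counts_per_ug")
  if (!all(required %in% names(df))) {
    stop("assay table needs columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Characterize variants from raw uptake replicates
#'
#' Runs the full first-stage pipeline on a raw assay table. Technical wells
#' are averaged within each batch and biological replicate; each
#' per-replicate mean (variant and WT alike) is then normalized against its
#' batch's control means (WT and EV biological-replicate means averaged at
#' batch level), so each biological replicate yields one percent-of-WT
#' value and WT itself reads 100 +/- replicate noise. Per-variant
#' normalized values are summarized into mean +/- SEM, tested against the
#' batch's normalized WT replicates, and called LOF below `lof_threshold`.
#'
#' @param assay data.frame from [read_assay_tsv()].
#' @param lof_threshold percent-of-WT LOF threshold.
#' @param n_tests Bonferroni divisor; defaults to the number of non-control
#'   variants in the table.
#' @param var_equal passed to [test_vs_wt()].
#' @return data.frame with one row per variant: `label`, `function_pct`,
#'   `sem`, `n_bio`, `p_value`, `significant`, `lof`.
#' @export
characterize_assay <- function(assay, lof_threshold = 20, n_tests = NULL,
                               var_equal = TRUE) {
  labels <- setdiff(unique(assay$variant), c("WT", "EV"))
  if (is.null(n_tests)) n_tests <- length(labels)

  # per-replicate mean (technical wells averaged) for one label in a batch
  rep_means <- function(lab, batch) {
    rows <- assay$variant == lab & assay$batch == batch
    if (!any(rows)) {
      stop("batch ", batch, " lacks ", lab, " wells", call. = FALSE)
    }
    as.numeric(tapply(assay$uptake_counts_per_ug[rows],
                      assay$bio_rep[rows], mean))
  }

  batches <- unique(assay$batch)
  wt_bar <- vapply(batches, function(b) mean(rep_means("WT", b)), numeric(1))
  ev_bar <- vapply(batches, function(b) mean(rep_means("EV", b)), numeric(1))
  names(wt_bar) <- names(ev_bar) <- as.character(batches)
  wt_norm <- lapply(batches, function(b) {
    normalize_uptake(rep_means("WT", b), wt_bar[[as.character(b)]],
                     ev_bar[[as.character(b)]])
  })
  names(wt_norm) <- as.character(batches)

  out <- lapply(labels, function(lab) {
    vbatches <- unique(assay$batch[assay$variant == lab])
    reps <- unlist(lapply(vbatches, function(b) {
      normalize_uptake(rep_means(lab, b), wt_bar[[as.character(b)]],
                       ev_bar[[as.character(b)]])
    }))
    s <- summarize_replicates(reps, seq_along(reps))
    wt_ref <- unlist(wt_norm[as.character(vbatches)])
    tt <- if (length(reps) >= 2L && length(wt_ref) >= 2L) {
      test_vs_wt(reps, wt_ref, n_tests = n_tests, var_equal = var_equal)
    } else {
      list(p_value = NA_real_, significant = NA)
    }
    data.frame(label = lab, function_pct = s$mean, sem = s$sem,
               n_bio = s$n_bio, p_value = tt$p_value,
               significant = tt$significant,
               lof = call_lof(s$mean, lof_threshold),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Read a characterized-variant table
#'
#' @param path tab-separated file with at least columns `variant` and
#'   `function_pct`; optional `sem`, `p_value`, `localization`, `group` and
#'   per-population allele-frequency columns (`af_*`).
#' @return data.frame with duplicate variant labels rejected.
#' @export
read_characterized_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("variant", "function_pct") %in% names(df))) {
    stop("characterized table needs columns variant, function_pct",
         call. = FALSE)
  }
  if (anyDuplicated(df$variant)) {
    stop("duplicate variant label(s) in characterized table", call. = FALSE)
  }
  df
}

#' Summarize variant function by ancestry group
#'
#' Per-group median, interquartile range, n, and count/fraction below the
#' LOF threshold; one-way ANOVA across groups with Tukey HSD post hoc
#' pairwise comparisons. Groups with fewer than 2 variants are excluded
#' from the omnibus test with a warning.
#'
#' @param function_pct percent-of-WT function per variant.
#' @param group group label per variant.
#' @param lof_threshold percent-of-WT LOF threshold.
#' @return list with `groups` (per-group summary data.frame), `anova`
#'   (F statistic, df, p), `tukey` (pairwise comparisons data.frame).
#' @export
group_summary <- function(function_pct, group, lof_threshold = 20) {
  stopifnot(length(function_pct) == length(group))
  group <- as.character(group)
  tab <- data.frame(fn = function_pct, group = group)
  per <- do.call(rbind, lapply(split(tab$fn, tab$group), function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(n = length(v), median = q[2], q25 = q[1], q75 = q[3],
               iqr = q[3] - q[1], n_lof = sum(call_lof(v, lof_threshold)),
               frac_lof = mean(call_lof(v, lof_threshold)))
  }))
  per <- data.frame(group = rownames(per), per, row.names = NULL,
                    stringsAsFactors = FALSE)
  per <- per[order(-per$median), ]

  small <- per$group[per$n < 2L]
  if (length(small) > 0L) {
    warning("excluding group(s) with n < 2 from omnibus test: ",
            paste(small, collapse = ", "), call. = FALSE)
    tab <- tab[!(tab$group %in% small), , drop = FALSE]
  }
  tab$group <- factor(tab$group)
  fit <- stats::aov(fn ~ group, data = tab)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      p_adj = tk[, "p adj"], row.names = NULL,
                      stringsAsFactors = FALSE)
  list(groups = per,
       anova = list(F = an[1, "F value"], df = unname(an[, "Df"]),
                    p = an[1, "Pr(>F)"]),
       tukey = tukey)
}

#' Games-Howell post hoc pairwise comparisons
#'
#' Pairwise comparisons of group means that assume neither equal variances
#' nor equal sample sizes: each pair uses a Welch-type standard error and
#' degrees of freedom, with p-values from the studentized range
#' distribution over the full number of groups.
#'
#' @param values numeric observations.
#' @param group group label per observation.
#' @return data.frame with columns `group1`, `group2`, `diff`, `se`, `t`,
#'   `df`, `p_adj`.
#' @export
games_howell <- function(values, group) {
  group <- factor(group)
  k <- nlevels(group)
  stopifnot(k >= 2L)
  sp <- split(values, group)
  n <- vapply(sp, length, integer(1))
  m <- vapply(sp, mean, numeric(1))
  v <- vapply(sp, stats::var, numeric(1))
  pairs <- utils::combn(levels(group), 2)
  out <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se2 <- v[i] / n[i] + v[j] / n[j]
    tstat <- abs(m[i] - m[j]) / sqrt(se2)
    df <- se2^2 / ((v[i] / n[i])^2 / (n[i] - 1) + (v[j] / n[j])^2 / (n[j] - 1))
    p <- stats::ptukey(tstat * sqrt(2), nmeans = k, df = df,
                       lower.tail = FALSE)
    data.frame(group1 = i, group2 = j, diff = m[i] - m[j],
               se = sqrt(se2), t = tstat, df = df, p_adj = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Summarize variant function by subcellular localization class
#'
#' Class counts and per-class median function; Welch's ANOVA (no
#' equal-variance assumption) across classes with Games-Howell post hoc
#' pairwise comparisons. Classes with fewer than 2 variants are excluded
#' with a warning.
#'
#' @param function_pct percent-of-WT function per variant.
#' @param localization class per variant (membrane / mixed / intracellular).
#' @return list with `classes` (counts and medians), `welch_anova`
#'   (F, df, p), `games_howell` (pairwise data.frame).
#' @export
localization_summary <- function(function_pct, localization) {
  stopifnot(length(function_pct) == length(localization))
  localization <- as.character(localization)
  counts <- table(localization)
  per <- do.call(rbind, lapply(split(function_pct, localization), function(v) {
    data.frame(n = length(v), median = stats::median(v))
  }))
  per <- data.frame(class = rownames(per), per, row.names = NULL,
                    stringsAsFactors = FALSE)

  small <- per$class[per$n < 2L]
  keep <- !(localization %in% small)
  if (length(small) > 0L) {
    warning("excluding class(es) with n < 2: ",
            paste(small, collapse = ", "), call. = FALSE)
  }
  fn <- function_pct[keep]
  cls <- factor(localization[keep])
  w <- stats::oneway.test(fn ~ cls, var.equal = FALSE)
  gh <- games_howell(fn, cls)
  list(classes = per,
       welch_anova = list(F = unname(w$statistic),
                          df = unname(w$parameter), p = w$p.value),
       games_howell = gh)
}
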