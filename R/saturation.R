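#' Enumerate every possible missense variant of a protein
#'
#' All 19 single-residue substitutions at every position, ordered by
#' (position, alternate residue alphabetically); 19 * L rows in total
#' (10,583 for a 557-residue transporter).
#'
#' @param seq a [protein_sequence()].
#' @return data.frame with columns `label`, `pos`, `ref`, `alt`.
#' @export
enumerate_missense <- function(seq) {
  stopifnot(inherits(seq, "protein_sequence"))
  L <- length(seq)
  ref <- rep(seq$residues, each = 19L)
  pos <- rep(seq_len(L), each = 19L)
  alt <- unlist(lapply(seq$residues, function(r) setdiff(aa_alphabet, r)),
                use.names = FALSE)
  data.frame(label = format_hgvs_p(pos, ref, alt), pos = pos, ref = ref,
             alt = alt, stringsAsFactors = FALSE)
}

#' Map LOF probability to a normalized functional score
#'
#' A piecewise-linear calibration that places the model's decision cutoff
#' at 0.5: scores above 0.5 predict function above the 20%-of-WT
#' threshold (closer to 1 = higher confidence), scores below 0.5 predict
#' LOF (closer to 0 = higher confidence). `p = 0` maps to 1, `p = cutoff`
#' to 0.5, `p = 1` to 0; the map is continuous and strictly decreasing,
#' so classifying by `s > 0.5` is exactly classifying by `p < cutoff`.
#'
#' @param p LOF probability in `[0, 1]` (vectorized).
#' @param cutoff model decision cutoff, strictly inside (0, 1).
#' @return normalized functional score in `[0, 1]`.
#' @export
normalize_score <- function(p, cutoff) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || !is.finite(cutoff) ||
      cutoff <= 0 || cutoff >= 1) {
    stop("cutoff must lie strictly inside (0, 1)", call. = FALSE)
  }
  stopifnot(all(p >= 0 & p <= 1))
  ifelse(p <= cutoff,
         0.5 + 0.5 * (cutoff - p) / cutoff,
         0.5 - 0.5 * (p - cutoff) / (1 - cutoff))
}

#' Build the saturation prediction table
#'
#' @param variants enumeration from [enumerate_missense()].
#' @param p_lof per-variant LOF probabilities from the trained classifier.
#' @param cutoff the classifier's binarizing cutoff.
#' @return data.frame of class `saturation_table` with columns `label`,
#'   `pos`, `ref`, `alt`, `p_lof`, `functional_score`, `predicted_class`.
#' @export
saturation_table <- function(variants, p_lof, cutoff) {
  stopifnot(nrow(variants) == length(p_lof))
  s <- normalize_score(p_lof, cutoff)
  out <- data.frame(variants, p_lof = p_lof, functional_score = s,
                    predicted_class = ifelse(s > 0.5, "functional", "LOF"),
                    stringsAsFactors = FALSE)
  class(out) <- c("saturation_table", "data.frame")
  out
}

#' Per-residue and global summary of a saturation table
#'
#' Per-position mean and SD of the normalized functional score over the 19
#' substitutions at that position, plus the global count and fraction of
#' variants scoring below 0.5 (predicted severe LOF).
#'
#' @param tab a [saturation_table()] (must be complete: 19 rows per
#'   position).
#' @return list with `per_residue` (data.frame: pos, mean, sd) and
#'   `n_lof`, `frac_lof`, `n_total`.
#' @export
saturation_summary <- function(tab) {
  counts <- table(tab$pos)
  if (any(counts != 19L)) {
    stop("incomplete saturation table: every position needs 19 rows",
         call. = FALSE)
  }
  s <- split(tab$functional_score, tab$pos)
  per <- data.frame(
    pos = as.integer(names(s)),
    mean = vapply(s, mean, numeric(1)),
    sd = vapply(s, stats::sd, numeric(1)),
    row.names = NULL
  )
  per <- per[order(per$pos), ]
  n_lof <- sum(tab$functional_score < 0.5)
  list(per_residue = per, n_lof = n_lof,
       frac_lof = n_lof / nrow(tab), n_total = nrow(tab))
}

#' Export the saturation table as a position x substitution score matrix
#'
#' Rows are positions 1..L, columns the 20 amino acids in alphabetical
#' one-letter order; reference cells are `NA` (rendered white/missing in a
#' heatmap).
#'
#' @param tab a [saturation_table()].
#' @return numeric matrix L x 20 of functional scores.
#' @export
saturation_matrix <- function(tab) {
  L <- max(tab$pos)
  m <- matrix(NA_real_, nrow = L, ncol = 20,
              dimnames = list(seq_len(L), aa_alphabet))
  m[cbind(tab$pos, match(tab$alt, aa_alphabet))] <- tab$functional_score
  m
}

#' Minimum carrier-frequency estimate for one population
#'
#' Pools the population allele frequencies of the LOF variants into
#' `q = sum(AF)` and converts to an expected heterozygous-carrier
#' frequency. The default uses the Hardy-Weinberg heterozygote frequency
#' `2q(1-q)`; the simpler `2q` approximation is available, and the two
#' differ negligibly at the q <= 0.003 seen for rare variants. Variants
#' with no allele frequency recorded in the population contribute 0,
#' which is what makes the estimate a minimum.
#'
#' @param lof_variants character vector of LOF variant labels.
#' @param afs data.frame with columns `variant`, `population`,
#'   `allele_frequency`.
#' @param population population to estimate for.
#' @param formula `"hw"` for 2q(1-q) or `"2q"`.
#' @return list with `q`, `carrier_freq`, `ratio` (text "1:N", `NA` when
#'   the carrier frequency is 0), `n_variants_with_af`.
#' @export
carrier_frequency <- function(lof_variants, afs, population,
                              formula = c("hw", "2q")) {
  formula <- match.arg(formula)
  stopifnot(all(c("variant", "population", "allele_frequency") %in%
                  names(afs)))
  sub <- afs[afs$population == population &
               afs$variant %in% lof_variants, , drop = FALSE]
  q <- sum(sub$allele_frequency)
  if (q >= 1) stop("pooled allele frequency q must be < 1", call. = FALSE)
  if (any(sub$allele_frequency < 0 | sub$allele_frequency >= 1)) {
    stop("allele frequencies must lie in [0, 1)", call. = FALSE)
  }
  cf <- if (formula == "hw") 2 * q * (1 - q) else 2 * q
  ratio <- if (cf > 0) paste0("1:", round(1 / cf)) else NA_character_
  list(q = q, carrier_freq = cf, ratio = ratio,
       n_variants_with_af = nrow(sub))
}
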