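#' Pearson chi-square goodness of fit of genotype counts to a segregation class
#'
#' Tests observed `(AA, AB, BB)` counts against an expected call distribution.
#' Only classes with positive expected probability enter the statistic, with
#' degrees of freedom `(number of nonzero expected classes) - 1`. Observing a
#' call whose expected probability is zero makes the class incompatible:
#' `chi2 = Inf`, `p = 0`. An all-missing locus (zero counts) is flagged
#' (`NA` statistic) rather than an error.
#'
#' @param counts Numeric vector of observed counts for `AA`, `AB`, `BB` (in
#'   that order, or named).
#' @param expected Expected probabilities for the three calls; must have at
#'   least one positive entry. Entries are renormalised over AA/AB/BB.
#' @return List with `chi2`, `df`, `p_value`.
#' @examples
#' chi2_goodness_of_fit(c(30, 90, 44), c(0.25, 0.5, 0.25))
#' @export
chi2_goodness_of_fit <- function(counts, expected) {
  if (!is.null(names(counts))) counts <- counts[c("AA", "AB", "BB")]
  if (!is.null(names(expected))) expected <- expected[c("AA", "AB", "BB")]
  counts <- as.numeric(counts)
  expected <- as.numeric(expected)
  stopifnot(length(counts) == 3L, length(expected) == 3L,
            all(counts >= 0), all(expected >= 0))
  if (sum(expected) <= 0) stop("at least one expected class must be nonzero")
  expected <- expected / sum(expected)
  n <- sum(counts)
  if (n == 0) return(list(chi2 = NA_real_, df = NA_integer_,
                          p_value = NA_real_))
  pos <- expected > 0
  df <- sum(pos) - 1L
  if (any(!pos & counts > 0)) {
    return(list(chi2 = Inf, df = df, p_value = 0))
  }
  e <- n * expected[pos]
  chi2 <- sum((counts[pos] - e)^2 / e)
  p <- if (df == 0L) 1 else stats::pchisq(chi2, df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p_value = p)
}

# Candidate class variants evaluated by classify_locus. Several classes have
# more than one orientation (which homozygote is absent/fixed); each variant
# is tested and the best fit represents the class.
.class_variants <- list(
  codominant_1_2_1   = list(c(1, 2, 1) / 4),
  dominant_AB_BB_3_1 = list(c(0, 3, 1) / 4),
  dominant_AB_AA_3_1 = list(c(1, 3, 0) / 4),
  one_to_one         = list(c(1, 1, 0) / 2, c(0, 1, 1) / 2),
  monomorphic        = list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
)

#' Classify one locus by its segregation pattern
#'
#' Fits the observed genotype counts against the candidate S1/F1 segregation
#' classes (1:2:1 codominant, 0:3:1 dominant in either orientation, 1:1,
#' monomorphic) and assigns the compatible class with the largest
#' goodness-of-fit p-value. A 1:2:1 locus is a candidate subgenome-specific
#' locus; a 3:1 locus indicates a homoeologous (multi-subgenome) target.
#'
#' Filtering follows the mapping workflow: a locus passes when its missing
#' count is at most `max_missing` (default 20) and its best-class fit is not
#' rejected at `min_p` (default 0.01). The `distorted` flag marks segregation
#' distortion, best-class `p < alpha` (default 0.05).
#'
#' Genotyping error tolerance: real call matrices contain rare miscalls, and
#' a single stray `AA` would otherwise make every zero-`AA` class
#' incompatible. Calls observed in a class with zero expectation are treated
#' as miscalls and excluded from the fit as long as they make up at most
#' `offclass_tol` of the scored calls (default 3\%); beyond that the class is
#' incompatible (`p = 0`). The strict zero-tolerance behaviour of
#' [chi2_goodness_of_fit] is recovered with `offclass_tol = 0`.
#'
#' @param counts Counts `c(AA, AB, BB, missing)` (the 4th element defaults to
#'   0 if absent); may be named.
#' @param alpha Significance level for the distortion flag.
#' @param min_p Minimum goodness-of-fit p-value to retain a locus.
#' @param max_missing Maximum tolerated missing calls.
#' @param offclass_tol Maximum fraction of scored calls tolerated in
#'   zero-expectation classes before a class is declared incompatible.
#' @return One-row data.frame: `n_AA, n_AB, n_BB, n_missing, class, chi2,
#'   p_value, distorted, passes_filters`.
#' @examples
#' classify_locus(c(41, 82, 41, 0))  # codominant 1:2:1
#' classify_locus(c(0, 123, 41, 0))  # dominant 3:1 (AB:BB)
#' @export
classify_locus <- function(counts, alpha = 0.05, min_p = 0.01,
                           max_missing = 20, offclass_tol = 0.03) {
  if (!is.null(names(counts)) && all(c("AA", "AB", "BB") %in% names(counts))) {
    miss <- if ("missing" %in% names(counts)) counts[["missing"]] else 0
    counts <- c(counts[["AA"]], counts[["AB"]], counts[["BB"]], miss)
  }
  if (length(counts) == 3L) counts <- c(counts, 0)
  stopifnot(length(counts) == 4L, all(counts >= 0))
  obs <- as.numeric(counts[1:3])
  n_missing <- as.numeric(counts[4])

  if (sum(obs) == 0) {
    return(data.frame(n_AA = 0, n_AB = 0, n_BB = 0, n_missing = n_missing,
                      class = NA_character_, chi2 = NA_real_,
                      p_value = NA_real_, distorted = NA,
                      passes_filters = FALSE, stringsAsFactors = FALSE))
  }

  best <- list(class = "other", chi2 = Inf, p = -1)
  for (cls in names(.class_variants)) {
    for (ev in .class_variants[[cls]]) {
      off <- ev == 0 & obs > 0
      if (any(off)) {
        if (sum(obs[off]) > offclass_tol * sum(obs)) next  # incompatible
        use <- obs
        use[off] <- 0                         # tolerated miscalls excluded
        fit <- chi2_goodness_of_fit(use, ev)
      } else {
        fit <- chi2_goodness_of_fit(obs, ev)
      }
      if (fit$p_value > best$p ||
          (fit$p_value == best$p && fit$chi2 < best$chi2)) {
        best <- list(class = cls, chi2 = fit$chi2, p = fit$p_value)
      }
    }
  }
  if (best$p < 0) best <- list(class = "other", chi2 = NA_real_, p = 0)

  data.frame(n_AA = obs[1], n_AB = obs[2], n_BB = obs[3],
             n_missing = n_missing, class = best$class, chi2 = best$chi2,
             p_value = best$p, distorted = best$p < alpha,
             passes_filters = n_missing <= max_missing & best$p >= min_p,
             stringsAsFactors = FALSE)
}

#' Classify every locus of a genotype matrix
#'
#' @param genotypes Character matrix of calls (loci x individuals, NA =
#'   missing) or a `sim_population`.
#' @inheritParams classify_locus
#' @return data.frame with one row per locus (column `locus` first), as in
#'   [classify_locus].
#' @export
classify_matrix <- function(genotypes, alpha = 0.05, min_p = 0.01,
                            max_missing = 20, offclass_tol = 0.03) {
  if (inherits(genotypes, "sim_population")) genotypes <- genotypes$genotypes
  stopifnot(is.matrix(genotypes))
  if (nrow(genotypes) == 0L) {
    return(data.frame(locus = character(), n_AA = numeric(),
                      n_AB = numeric(), n_BB = numeric(),
                      n_missing = numeric(), class = character(),
                      chi2 = numeric(), p_value = numeric(),
                      distorted = logical(), passes_filters = logical(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(nrow(genotypes)), function(i) {
    x <- genotypes[i, ]
    classify_locus(c(sum(x == "AA", na.rm = TRUE),
                     sum(x == "AB", na.rm = TRUE),
                     sum(x == "BB", na.rm = TRUE),
                     sum(is.na(x))),
                   alpha = alpha, min_p = min_p, max_missing = max_missing,
                   offclass_tol = offclass_tol)
  })
  out <- do.call(rbind, rows)
  out <- cbind(locus = rownames(genotypes) %||% sprintf("locus%d",
                                                        seq_len(nrow(out))),
               out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarise locus classifications
#'
#' Tabulates counts and percentages per segregation class over a classified
#' matrix (or classifies a matrix first). Percentages are over classified
#' loci and sum to 100.
#'
#' @param x A classification data.frame from [classify_matrix], a genotype
#'   matrix, or a `sim_population`.
#' @param ... Passed to [classify_matrix] when `x` is a matrix.
#' @return data.frame: class, n, percent.
#' @export
classification_report <- function(x, ...) {
  if (!is.data.frame(x)) x <- classify_matrix(x, ...)
  if (nrow(x) == 0L) {
    return(data.frame(class = character(), n = integer(),
                      percent = numeric(), stringsAsFactors = FALSE))
  }
  cls <- ifelse(is.na(x$class), "unclassified", x$class)
  tab <- table(cls)
  out <- data.frame(class = names(tab), n = as.integer(tab),
                    percent = 100 * as.numeric(tab) / sum(tab),
                    stringsAsFactors = FALSE)
  out[order(-out$n), , drop = FALSE]
}
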