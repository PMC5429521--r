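#' Allele configurations of an allo-octoploid locus
#'
#' A locus in an allo-octoploid is described by the allele carried on each of
#' the 8 parental homologs, written as an 8-character string over the alphabet
#' `A`, `B`, `O` (null, i.e. the marker target is absent from that homolog).
#' Characters are grouped into 4 subgenome pairs: positions 1-2 are the two
#' homologs of subgenome 1, positions 3-4 subgenome 2, and so on. Within a
#' subgenome the locus is either present on both homologs or absent from both,
#' so a valid pair is either `OO` or two non-`O` symbols. A configuration must
#' carry at least one non-null allele.
#'
#' Examples: `"ABOOOOOO"` is a subgenome-specific heterozygous locus (present
#' only in subgenome 1); `"ABBBOOOO"` is a homoeologous locus, heterozygous in
#' subgenome 1 and fixed for `B` in subgenome 2.
#'
#' @param x A length-1 character string of 8 symbols over `{A,B,O}`.
#' @return An object of class `allele_config`: the validated string with the
#'   per-subgenome pairs in attribute `pairs` (a 2 x 4 character matrix).
#' @examples
#' cfg <- allele_config("ABBBOOOO")
#' is_subgenome_specific(cfg)
#' @export
allele_config <- function(x) {
  if (inherits(x, "allele_config")) return(x)
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop("configuration must be a single character string", call. = FALSE)
  }
  x <- toupper(x)
  if (nchar(x) != 8L) {
    stop(sprintf("configuration '%s' must have exactly 8 symbols (got %d)",
                 x, nchar(x)), call. = FALSE)
  }
  sym <- strsplit(x, "")[[1L]]
  bad <- setdiff(unique(sym), c("A", "B", "O"))
  if (length(bad)) {
    stop(sprintf("configuration '%s' contains invalid symbols: %s",
                 x, paste(bad, collapse = ", ")), call. = FALSE)
  }
  pairs <- matrix(sym, nrow = 2L, ncol = 4L)
  for (s in 1:4) {
    n_null <- sum(pairs[, s] == "O")
    if (n_null == 1L) {
      stop(sprintf(paste0("configuration '%s': subgenome %d mixes a null with",
                          " a non-null allele (a locus is present in a",
                          " subgenome or absent from it)"), x, s),
           call. = FALSE)
    }
  }
  if (all(sym == "O")) {
    stop("configuration must carry at least one non-null allele",
         call. = FALSE)
  }
  structure(x, class = "allele_config", pairs = pairs)
}

#' @export
print.allele_config <- function(x, ...) {
  pairs <- attr(x, "pairs")
  cat("<allele_config> ", unclass(x), "\n", sep = "")
  cat("  subgenomes: ",
      paste(apply(pairs, 2L, paste, collapse = ""), collapse = " | "),
      "\n", sep = "")
  invisible(x)
}

#' Gamete distribution of a configuration under disomic inheritance
#'
#' Each subgenome forms a bivalent at meiosis and contributes exactly one of
#' its two homolog alleles, chosen with probability 1/2 independently of the
#' other subgenomes (homoeologous chromosomes never pair). The 2^4 equally
#' likely homolog choices are enumerated exactly; gametes are labelled by the
#' 4-symbol string of per-subgenome alleles.
#'
#' @param config An [allele_config] or a string coercible to one.
#' @return A named numeric vector of gamete probabilities (names are 4-symbol
#'   gamete strings over `{A,B,O}`); sums to 1 exactly (dyadic rationals).
#' @examples
#' gamete_distribution("ABBBOOOO")
#' @export
gamete_distribution <- function(config) {
  config <- allele_config(config)
  pairs <- attr(config, "pairs")
  # all 2^4 homolog choices, probability 1/16 each
  choice <- as.matrix(expand.grid(1:2, 1:2, 1:2, 1:2))
  gam <- apply(choice, 1L, function(ch) {
    paste(pairs[cbind(ch, 1:4)], collapse = "")
  })
  tab <- table(gam)
  out <- as.numeric(tab) / 16
  names(out) <- names(tab)
  out
}

#' Expected offspring call distribution for a mating
#'
#' Convolves the two parental gamete distributions and collapses each
#' offspring's full allele complement (8 homologs across the 4 subgenomes) to
#' the biallelic genotype call an array reports: any `A` and any `B` anywhere
#' gives `AB`, only `A` gives `AA`, only `B` gives `BB`, and no allele at all
#' gives a null phenotype (structurally impossible for valid configurations,
#' where a present subgenome is present on both homologs). Allele dosage is
#' ignored: `AAAB` and `AB` are the same call. Selfing is the
#' `maternal = paternal` case.
#'
#' @param maternal,paternal Parental configurations (strings or
#'   [allele_config]); `paternal` defaults to `maternal` (selfing).
#' @return Named numeric vector `c(AA=, AB=, BB=, null=)` summing to 1.
#' @examples
#' expected_segregation("ABOOOOOO")             # 1:2:1
#' expected_segregation("ABBBOOOO")             # 0:3:1 (AB:BB)
#' expected_segregation("AAOOOOOO", "ABOOOOOO") # 1:1 (AA:AB)
#' @export
expected_segregation <- function(maternal, paternal = maternal) {
  gm <- gamete_distribution(maternal)
  gp <- gamete_distribution(paternal)
  out <- c(AA = 0, AB = 0, BB = 0, null = 0)
  for (i in seq_along(gm)) {
    for (j in seq_along(gp)) {
      sym <- c(strsplit(names(gm)[i], "")[[1L]],
               strsplit(names(gp)[j], "")[[1L]])
      has_a <- any(sym == "A")
      has_b <- any(sym == "B")
      call <- if (has_a && has_b) "AB" else if (has_a) "AA"
              else if (has_b) "BB" else "null"
      out[call] <- out[call] + gm[i] * gp[j]
    }
  }
  out
}

#' Is a configuration subgenome-specific?
#'
#' A subgenome-specific locus has its marker target present in exactly one of
#' the four subgenomes; such loci segregate disomically (1:2:1 when
#' heterozygous) in an S1 population.
#'
#' @inheritParams gamete_distribution
#' @return `TRUE` iff exactly one subgenome pair is non-null.
#' @export
is_subgenome_specific <- function(config) {
  config <- allele_config(config)
  pairs <- attr(config, "pairs")
  sum(pairs[1L, ] != "O") == 1L
}

# Canonical expected call distributions of the recognised segregation classes
# (probabilities over AA, AB, BB; class names follow the observed pattern).
.segregation_classes <- list(
  codominant_1_2_1    = c(AA = 0.25, AB = 0.50, BB = 0.25),
  dominant_AB_BB_3_1  = c(AA = 0.00, AB = 0.75, BB = 0.25),
  dominant_AB_AA_3_1  = c(AA = 0.25, AB = 0.75, BB = 0.00),
  one_to_one          = c(AA = 0.50, AB = 0.50, BB = 0.00),
  monomorphic         = c(AA = 1.00, AB = 0.00, BB = 0.00)
)

#' Name the segregation class implied by an expected call distribution
#'
#' Maps an expected `(AA, AB, BB, null)` distribution (e.g. the output of
#' [expected_segregation]) to one of the canonical class names:
#' `codominant_1_2_1`, `dominant_AB_BB_3_1`, `dominant_AB_AA_3_1`,
#' `one_to_one`, `monomorphic`, or `other`. The two 1:1 orientations
#' (AA:AB and AB:BB) both map to `one_to_one`.
#'
#' @param p Numeric vector with components `AA`, `AB`, `BB` (a `null`
#'   component, if present, must be 0 for any named class to match).
#' @param tol Numerical tolerance on the comparison.
#' @return A class name string.
#' @export
segregation_class <- function(p, tol = 1e-9) {
  stopifnot(all(c("AA", "AB", "BB") %in% names(p)))
  if ("null" %in% names(p) && p[["null"]] > tol) return("other")
  q <- p[c("AA", "AB", "BB")]
  eq <- function(a, b) all(abs(a - b) <= tol)
  if (eq(q, c(0.25, 0.5, 0.25))) return("codominant_1_2_1")
  if (eq(q, c(0, 0.75, 0.25))) return("dominant_AB_BB_3_1")
  if (eq(q, c(0.25, 0.75, 0))) return("dominant_AB_AA_3_1")
  if (eq(q, c(0.5, 0.5, 0)) || eq(q, c(0, 0.5, 0.5))) return("one_to_one")
  if (any(vapply(seq_len(3L), function(i) {
    e <- c(0, 0, 0); e[i] <- 1; eq(q, e)
  }, logical(1L)))) return("monomorphic")
  "other"
}
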